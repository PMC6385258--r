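#' Normalize a 3D point-spread function
#'
#' @param psf non-negative 3D array.
#' @return `psf3d` object: the array scaled to unit sum.
#' @export
normalize_psf <- function(psf) {
  if (any(psf < 0)) stop_bad_arg("PSF must be non-negative")
  s <- sum(psf)
  if (s <= 0) stop_bad_arg("PSF must have positive mass")
  structure(psf / s, class = c("psf3d", class(psf)))
}

#' Build a separable Gaussian 3D PSF
#'
#' Pixel-integrated separable Gaussian kernel matching an
#' [optics_config()]; the analytic counterpart of a measured bead PSF.
#'
#' @param optics an [optics_config()].
#' @param half_xy,half_z kernel half-sizes (pixels / planes).
#' @return a unit-sum `psf3d` array.
#' @export
gaussian_psf3d <- function(optics, half_xy = 4, half_z = 6) {
  px <- gauss_profile(2 * half_xy + 1, half_xy + 1, optics$psf_sigma_xy_px)
  pz <- gauss_profile(2 * half_z + 1, half_z + 1, optics$psf_sigma_z_planes)
  normalize_psf(outer(outer(px, px), pz))
}

# OTF of `psf` centred for circular convolution on a grid of size `d`.
psf_otf <- function(psf, d) {
  dp <- dim(psf)
  if (any(dp > d)) stop_bad_arg("PSF larger than the (padded) image")
  k <- array(0, dim = d)
  k[seq_len(dp[1]), seq_len(dp[2]), seq_len(dp[3])] <- psf
  # shift the kernel centre to the origin
  ctr <- (dp - 1) %/% 2
  for (ax in 1:3) {
    idx <- c(seq(ctr[ax] + 1, d[ax]), seq_len(ctr[ax]))
    k <- switch(ax, k[idx, , , drop = FALSE], k[, idx, , drop = FALSE],
                k[, , idx, drop = FALSE])
  }
  fft(k)
}

#' Richardson-Lucy 3D deconvolution
#'
#' Standard multiplicative Richardson-Lucy iteration with a fixed PSF:
#' `est <- est * conv(obs / conv(est, psf), psf_flipped)`. The image is
#' reflectively padded by the PSF half-width so edge flux is handled
#' symmetrically; non-negativity is preserved by construction and total
#' flux of interior emitters is conserved. The default of 60 iterations is
#' the setting used for all stacks in this workflow. An optional Tikhonov
#' damping factor regularizes the update for very noisy data.
#'
#' @param stack non-negative 3D array.
#' @param psf a [normalize_psf()]/[gaussian_psf3d()] kernel (normalized if
#'   not already).
#' @param iterations iteration count (default 60).
#' @param damp Tikhonov damping lambda >= 0 (0 = plain Richardson-Lucy).
#' @return deconvolved 3D array, same dimensions as `stack`.
#' @export
richardson_lucy <- function(stack, psf, iterations = 60, damp = 0) {
  if (any(stack < 0)) stack <- pmax(stack, 0)
  if (!inherits(psf, "psf3d")) psf <- normalize_psf(psf)
  d0 <- dim(stack); dp <- dim(psf)
  if (any(dp > d0)) stop_bad_arg("PSF larger than the image stack")
  pad <- (dp - 1) %/% 2
  obs <- pad_reflect3(stack, pad)
  d <- dim(obs)
  otf <- psf_otf(unclass(psf), d)
  otf_conj <- Conj(otf) # correlation kernel = flipped PSF
  est <- array(mean(obs), dim = d)
  eps <- .Machine$double.eps
  for (it in seq_len(iterations)) {
    blur <- pmax(conv3_circular(est, otf), eps)
    ratio <- obs / blur
    upd <- conv3_circular(ratio, otf_conj)
    est <- est * upd
    if (damp > 0) est <- est / (1 + damp * est)
    est[est < 0] <- 0
  }
  est[pad[1] + seq_len(d0[1]), pad[2] + seq_len(d0[2]),
      pad[3] + seq_len(d0[3]), drop = FALSE]
}

#' Estimate a PSF from imaged beads
#'
#' Extracts a window around each isolated bead spot, subtracts the local
#' background (median of the window shell), aligns windows on their
#' rounded centroids, averages, clips negatives and normalizes to unit sum.
#'
#' @param bead_stack 3D array of sub-diffraction beads.
#' @param spots matrix or data.frame of bead centroids (`x`, `y`, `z`), or
#'   `NULL` to auto-detect with [detect_spots_3d()].
#' @param half_xy,half_z extraction half-window (pixels / planes).
#' @return a unit-sum `psf3d` array.
#' @export
psf_from_beads <- function(bead_stack, spots = NULL, half_xy = 4, half_z = 6) {
  if (is.null(spots)) {
    spots <- detect_spots_3d(bead_stack)
    if (nrow(spots) == 0) stop_bad_arg("no beads found")
  }
  spots <- as.matrix(spots)
  if (all(c("x", "y", "z") %in% colnames(spots)))
    spots <- spots[, c("x", "y", "z"), drop = FALSE]
  else spots <- spots[, 1:3, drop = FALSE]
  d <- dim(bead_stack)
  acc <- array(0, dim = c(2 * half_xy + 1, 2 * half_xy + 1, 2 * half_z + 1))
  n_used <- 0
  for (i in seq_len(nrow(spots))) {
    c0 <- round_half_up(spots[i, ])
    if (c0[1] <= half_xy || c0[1] > d[1] - half_xy ||
        c0[2] <= half_xy || c0[2] > d[2] - half_xy ||
        c0[3] <= half_z || c0[3] > d[3] - half_z) next
    w <- bead_stack[(c0[1] - half_xy):(c0[1] + half_xy),
                    (c0[2] - half_xy):(c0[2] + half_xy),
                    (c0[3] - half_z):(c0[3] + half_z)]
    shell <- c(w[1, , ], w[dim(w)[1], , ], w[, 1, ], w[, dim(w)[2], ])
    w <- w - stats::median(shell)
    acc <- acc + pmax(w, 0)
    n_used <- n_used + 1
  }
  if (n_used == 0) stop_bad_arg("no beads with a complete extraction window")
  normalize_psf(acc / n_used)
}
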