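#' Detect diffraction-limited spots in a 2D frame
#'
#' Detection / estimation / deflation in the style of multiple-target
#' tracing: (i) a generalized-likelihood-ratio test of a Gaussian peak of
#' known PSF width against a flat background is evaluated in a sliding
#' window at every pixel, thresholded at the requested false-alarm
#' probability; (ii) each detected local maximum is refined by nonlinear
#' least squares to a sub-pixel Gaussian (amplitude, position, flat
#' offset); (iii) the fitted peak is subtracted and the detection pass
#' repeated on the residual until nothing exceeds the threshold or
#' `max_deflations` rounds have run. Spots within 1 px of the frame border
#' are flagged and carry no intensity.
#'
#' @param frame finite numeric matrix.
#' @param psf_sigma lateral Gaussian PSF width (pixels).
#' @param alarm_rate per-pixel false-alarm probability of the GLRT.
#' @param max_deflations maximum deflation rounds.
#' @param window_half GLRT window half-size (default `ceiling(3 * sigma)`).
#' @return data.frame of spot records sorted by detection strength:
#'   `x`, `y` (sub-pixel), `xr`, `yr` (rounded half-up), `strength` (GLRT
#'   statistic), `amplitude`, `flag` (`""` or `"border"`).
#' @export
detect_spots_2d <- function(frame, psf_sigma = 0.7, alarm_rate = 1e-5,
                            max_deflations = 10, window_half = NULL) {
  if (!all(is.finite(frame))) stop_bad_arg("frame contains non-finite pixels")
  d <- dim(frame)
  if (is.null(window_half)) window_half <- max(2L, ceiling(3 * psf_sigma))
  w <- 2L * window_half + 1L
  n_w <- w * w
  g <- outer(gauss_profile(w, window_half + 1, psf_sigma),
             gauss_profile(w, window_half + 1, psf_sigma))
  gt <- g - mean(g)
  gt_ss <- sum(gt^2)
  thr <- stats::qchisq(1 - alarm_rate, df = 1)
  box <- matrix(1, w, w)
  out <- list()
  residual <- frame
  for (round in seq_len(max_deflations)) {
    s1 <- conv2_same(residual, box[w:1, w:1])
    s2 <- conv2_same(residual^2, box[w:1, w:1])
    sg <- conv2_same(residual, gt[w:1, w:1])
    rss0 <- pmax(s2 - s1^2 / n_w, 0)
    amp <- sg / gt_ss
    rss1 <- pmax(rss0 - amp^2 * gt_ss, .Machine$double.eps)
    stat <- n_w * log(pmax(rss0, .Machine$double.eps) / rss1)
    stat[amp <= 0] <- 0
    stat[rss0 <= 0] <- 0
    # exclude a margin where the test window is clipped
    m <- window_half
    mask <- matrix(FALSE, d[1], d[2])
    if (d[1] > 2 * m && d[2] > 2 * m)
      mask[(m + 1):(d[1] - m), (m + 1):(d[2] - m)] <- TRUE
    cand <- which(stat > thr & mask, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    # local maxima among candidates (8-neighbourhood)
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      x <- cand[i, 1]; y <- cand[i, 2]
      nb <- stat[max(1, x - 1):min(d[1], x + 1), max(1, y - 1):min(d[2], y + 1)]
      stat[x, y] >= max(nb)
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    ord <- order(stat[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    found_any <- FALSE
    for (i in seq_len(nrow(cand))) {
      x0 <- cand[i, 1]; y0 <- cand[i, 2]
      if (stat[x0, y0] <= thr) next
      fitw <- window_half
      xs <- max(1, x0 - fitw):min(d[1], x0 + fitw)
      ys <- max(1, y0 - fitw):min(d[2], y0 + fitw)
      sub <- residual[xs, ys]
      fit <- fit_gauss2d(sub, x_init = x0 - xs[1] + 1, y_init = y0 - ys[1] + 1,
                         sigma = psf_sigma)
      if (is.null(fit) || fit$amp <= 0) next
      x_hat <- xs[1] - 1 + fit$x
      y_hat <- ys[1] - 1 + fit$y
      # subtract the fitted peak (without its offset) from the residual
      residual <- add_spot_2d(residual, x_hat, y_hat, psf_sigma, -fit$flux)
      border <- x_hat < 2 || y_hat < 2 || x_hat > d[1] - 1 || y_hat > d[2] - 1
      out[[length(out) + 1]] <- data.frame(
        x = x_hat, y = y_hat,
        xr = round_half_up(x_hat), yr = round_half_up(y_hat),
        strength = stat[x0, y0], amplitude = fit$amp,
        flag = if (border) "border" else "")
      found_any <- TRUE
    }
    if (!found_any) break
  }
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), xr = integer(0),
                      yr = integer(0), strength = numeric(0),
                      amplitude = numeric(0), flag = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$strength, decreasing = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Least-squares sub-pixel Gaussian fit on a small window: model
# offset + flux * pixel-integrated Gaussian(x, y, sigma fixed).
fit_gauss2d <- function(sub, x_init, y_init, sigma) {
  nx <- nrow(sub); ny <- ncol(sub)
  fn <- function(p) {
    mdl <- p[4] + p[3] * outer(gauss_profile(nx, p[1], sigma),
                               gauss_profile(ny, p[2], sigma))
    as.numeric(sub - mdl)
  }
  p0 <- c(x_init, y_init, max(sum(sub) - length(sub) * stats::median(sub), 1),
          stats::median(sub))
  fit <- tryCatch(minpack.lm::nls.lm(p0, fn = fn,
                                     lower = c(0.5, 0.5, 0, -Inf),
                                     upper = c(nx + 0.5, ny + 0.5, Inf, Inf),
                                     control = minpack.lm::nls.lm.control(maxiter = 60)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  peak_mass <- (stats::pnorm(0.5, 0, sigma) - stats::pnorm(-0.5, 0, sigma))^2
  list(x = p[1], y = p[2], flux = p[3], amp = p[3] * peak_mass, offset = p[4])
}

#' Detect spots in a deconvolved 3D stack
#'
#' Surface-mode detection: voxels above `median + threshold_k * MAD` are
#' grouped into 26-connected components; components of at least
#' `min_voxels` voxels become spots with intensity-weighted centroids.
#' Large components (many emitters coalesced in an endosome-like body) are
#' returned as single spots and resolved later by intensity calibration.
#' Spots whose 3 x 3 x 11 calibration window would clip the stack border
#' (1 px laterally, 5 planes axially) are flagged `"border"`.
#'
#' @param stack deconvolved 3D array.
#' @param threshold_k MAD multiplier above the median (default 6).
#' @param min_voxels minimum component size (default 4).
#' @return data.frame: `x`, `y`, `z` (sub-voxel), `xr`, `yr`, `zr`
#'   (rounded), `strength` (summed above-threshold intensity), `n_voxels`,
#'   `flag`.
#' @export
detect_spots_3d <- function(stack, threshold_k = 6, min_voxels = 4) {
  d <- dim(stack)
  med <- stats::median(stack)
  mad_ <- stats::mad(stack)
  thr <- med + threshold_k * max(mad_, .Machine$double.eps)
  above <- which(stack > thr)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      xr = integer(0), yr = integer(0), zr = integer(0),
                      strength = numeric(0), n_voxels = integer(0),
                      flag = character(0))
  if (!length(above)) return(empty)
  coords <- arrayInd(above, d)
  # connected components by BFS over the above-threshold voxel set
  key <- (coords[, 3] - 1) * (d[1] * d[2]) + (coords[, 2] - 1) * d[1] + coords[, 1]
  lookup <- new.env(hash = TRUE, size = length(key))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  labels <- integer(length(above))
  nbh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbh <- nbh[rowSums(abs(nbh)) > 0, ]
  comp <- 0L
  for (i in seq_along(above)) {
    if (labels[i] > 0) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      cj <- coords[j, ]
      for (k in seq_len(nrow(nbh))) {
        cn <- cj + nbh[k, ]
        if (any(cn < 1) || any(cn > d)) next
        kk <- as.character((cn[3] - 1) * (d[1] * d[2]) + (cn[2] - 1) * d[1] + cn[1])
        idx <- lookup[[kk]]
        if (!is.null(idx) && labels[idx] == 0) {
          labels[idx] <- comp
          queue <- c(queue, idx)
        }
      }
    }
  }
  recs <- lapply(seq_len(comp), function(cc) {
    sel <- labels == cc
    if (sum(sel) < min_voxels) return(NULL)
    cc_coords <- coords[sel, , drop = FALSE]
    wts <- stack[above[sel]] - med
    ctr <- colSums(cc_coords * wts) / sum(wts)
    xr <- round_half_up(ctr)
    border <- xr[1] < 2 || xr[2] < 2 || xr[3] < 6 ||
      xr[1] > d[1] - 1 || xr[2] > d[2] - 1 || xr[3] > d[3] - 5
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               xr = xr[1], yr = xr[2], zr = xr[3],
               strength = sum(wts), n_voxels = sum(sel),
               flag = if (border) "border" else "")
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(empty)
  res <- do.call(rbind, recs)
  # two components rounding to the same voxel: keep the stronger
  dup <- duplicated(res[, c("xr", "yr", "zr")])
  if (any(dup)) {
    res <- res[order(res$strength, decreasing = TRUE), ]
    res <- res[!duplicated(res[, c("xr", "yr", "zr")]), ]
  }
  res <- res[order(res$strength, decreasing = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge per-plane 2D detections into 3D spots
#'
#' Detections sharing the same rounded `(x, y)` position in adjacent
#' z-planes are chained into one spot whose `z` is the mean of the member
#' plane indices.
#'
#' @param spots data.frame with columns `xr`, `yr`, `plane` (integer plane
#'   index), e.g. stacked [detect_spots_2d()] outputs.
#' @return data.frame with one row per merged spot: `xr`, `yr`, `z`
#'   (mean plane), `n_planes`.
#' @export
merge_z <- function(spots) {
  if (is.null(spots) || nrow(spots) == 0)
    return(data.frame(xr = integer(0), yr = integer(0), z = numeric(0),
                      n_planes = integer(0)))
  stopifnot(all(c("xr", "yr", "plane") %in% names(spots)))
  out <- list()
  for (grp in split(spots, paste(spots$xr, spots$yr))) {
    planes <- sort(unique(grp$plane))
    run_id <- cumsum(c(1, diff(planes) > 1))
    for (run in split(planes, run_id)) {
      out[[length(out) + 1]] <- data.frame(
        xr = grp$xr[1], yr = grp$yr[1], z = mean(run),
        n_planes = length(run))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$xr, res$yr, res$z), , drop = FALSE]
  rownames(res) <- NULL
  res
}
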