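#' Integrated 3 x 3 x 11 spot intensity in a deconvolved stack
#'
#' Sums the 3 x 3 x 11 voxel window centred at the rounded spot centroid
#' and subtracts the mean background window sum. The window must fit
#' entirely inside the stack; clipped windows raise a border error so the
#' caller can flag and exclude the spot.
#'
#' @param stack deconvolved 3D array.
#' @param centroid `(x, y, z)` centroid; rounded half-up.
#' @param background_mean mean 3 x 3 x 11 window sum of background regions
#'   (see [estimate_background()]).
#' @return background-subtracted integrated intensity (counts).
#' @export
spot_intensity_3dd <- function(stack, centroid, background_mean = 0) {
  c0 <- round_half_up(centroid[1:3])
  d <- dim(stack)
  if (c0[1] < 2 || c0[2] < 2 || c0[3] < 6 ||
      c0[1] > d[1] - 1 || c0[2] > d[2] - 1 || c0[3] > d[3] - 5)
    stop_bad_arg("3x3x11 window clipped by the stack border at (",
                 paste(c0, collapse = ", "), ")")
  sum(stack[(c0[1] - 1):(c0[1] + 1), (c0[2] - 1):(c0[2] + 1),
            (c0[3] - 5):(c0[3] + 5)]) - background_mean
}

#' Estimate mean background window sums
#'
#' Samples windows centred on voxels at least `margin` pixels from every
#' detected spot (and, when a cell mask is supplied, restricted to it) and
#' returns the mean window sum for each requested window size. This is the
#' background term subtracted by [spot_intensity_3dd()] and
#' [extract_trace()]-based measurements.
#'
#' @param stack 3D array (or 2D matrix for the 3 x 3 case).
#' @param spots data.frame of detections with columns `xr`, `yr` (and `zr`
#'   for 3D), or `NULL` for none.
#' @param mask optional logical array: candidate background voxels.
#' @param window window size, `c(3, 3, 11)` (3D) or `c(3, 3)` (2D).
#' @param margin exclusion radius around spots (pixels; default 3).
#' @param n_windows number of sampled windows (default 500); an error is
#'   raised when fewer than 100 valid centres exist.
#' @param seed sampling seed.
#' @return mean background window sum (counts).
#' @export
estimate_background <- function(stack, spots = NULL, mask = NULL,
                                window = c(3, 3, 11), margin = 3,
                                n_windows = 500, seed = 1L) {
  d <- dim(stack)
  is3d <- length(d) == 3L
  if (!is3d) { stack <- array(stack, dim = c(d, 1L)); d <- dim(stack); window <- c(window[1:2], 1) }
  if (!is.null(mask)) {
    if (!any(mask)) stop_bad_arg("background mask is empty")
    stopifnot(all(dim(mask) == if (length(dim(mask)) == 2) d[1:2] else d))
    if (length(dim(mask)) == 2) mask <- array(mask, dim = d)
  }
  half <- (window - 1) / 2
  ok_x <- seq(1 + half[1], d[1] - half[1])
  ok_y <- seq(1 + half[2], d[2] - half[2])
  ok_z <- seq(1 + half[3], d[3] - half[3])
  grid <- expand.grid(x = ok_x, y = ok_y, z = ok_z)
  if (!is.null(mask)) grid <- grid[mask[as.matrix(grid)], , drop = FALSE]
  if (!is.null(spots) && nrow(spots) > 0) {
    sx <- spots$xr; sy <- spots$yr
    sz <- if ("zr" %in% names(spots)) spots$zr else rep(1, nrow(spots))
    # the exclusion zone keeps the sampled window itself clear of the spot:
    # margin is edge-to-edge, so add the window half-extent per axis
    mx <- margin + half
    keep <- rep(TRUE, nrow(grid))
    for (i in seq_along(sx)) {
      keep <- keep & (abs(grid$x - sx[i]) > mx[1] |
                      abs(grid$y - sy[i]) > mx[2] |
                      abs(grid$z - sz[i]) > mx[3])
    }
    grid <- grid[keep, , drop = FALSE]
  }
  if (nrow(grid) < 100)
    stop_bad_arg("insufficient background: only ", nrow(grid),
                 " candidate windows (need >= 100)")
  take <- with_seed(seed,
                    grid[sample.int(nrow(grid), min(n_windows, nrow(grid))), ,
                         drop = FALSE])
  sums <- vapply(seq_len(nrow(take)), function(i) {
    cx <- take$x[i]; cy <- take$y[i]; cz <- take$z[i]
    sum(stack[(cx - half[1]):(cx + half[1]),
              (cy - half[2]):(cy + half[2]),
              (cz - half[3]):(cz + half[3])])
  }, numeric(1))
  mean(sums)
}

#' Single-emitter intensity calibration
#'
#' Averages the deconvolved 3D intensities of spots accepted as single
#' quantum dots into the calibration standard used to convert every spot
#' intensity into a molecule count.
#'
#' @param intensities vector of single-QD `I_spot_3DD` values.
#' @return a `calibration` object: `mean_I_1QD_3DD`, `n_single`,
#'   `dispersion` (sd; 0 for a single contributor).
#' @export
calibrate_single_qd <- function(intensities) {
  intensities <- as.numeric(intensities)
  if (!length(intensities)) stop_bad_arg("no single-QD intensities supplied")
  m <- mean(intensities)
  if (m <= 0) stop_bad_arg("mean single-QD intensity must be positive")
  structure(list(mean_I_1QD_3DD = m, n_single = length(intensities),
                 dispersion = if (length(intensities) > 1) stats::sd(intensities) else 0),
            class = "calibration")
}

#' Quantum dots per spot
#'
#' Divides a spot's calibrated 3D intensity by the mean single-QD
#' intensity. Negative intensities (background overshoot) clamp to zero
#' with a warning.
#'
#' @param I_spot_3dd background-subtracted spot intensity (vectorized).
#' @param cal a [calibrate_single_qd()] object.
#' @return real-valued quantum-dot count(s).
#' @export
qds_per_spot <- function(I_spot_3dd, cal) {
  if (cal$mean_I_1QD_3DD <= 0) stop_bad_arg("calibration mean must be positive")
  n <- I_spot_3dd / cal$mean_I_1QD_3DD
  if (any(n < 0)) {
    warning("negative calibrated count clamped to 0 (background overshoot)")
    n[n < 0] <- 0
  }
  n
}

#' Count molecules in one cell
#'
#' Sums calibrated per-spot quantum-dot counts over all spots assigned to a
#' cell; with monovalent labeling this is the number of ligand molecules
#' bound to the cell.
#'
#' @param spots data.frame with a column `I_spot_3dd` (and optionally spot
#'   coordinates, carried through).
#' @param cal a [calibrate_single_qd()] object.
#' @return a `cell_result`: `spots` (with `n_qd_spot` added), `N_cell`
#'   (real), `N_cell_int` (rounded).
#' @export
count_cell <- function(spots, cal) {
  if (is.null(spots) || nrow(spots) == 0) {
    return(structure(list(spots = spots, N_cell = 0, N_cell_int = 0L),
                     class = "cell_result"))
  }
  spots$n_qd_spot <- qds_per_spot(spots$I_spot_3dd, cal)
  n <- sum(spots$n_qd_spot)
  structure(list(spots = spots, N_cell = n,
                 N_cell_int = as.integer(round_half_up(n))),
            class = "cell_result")
}

#' Detector-normalized autofluorescence emission spectrum
#'
#' Per spectral channel, the background-corrected mean cell pixel intensity
#' is divided by the integrated detector quantum efficiency across the
#' channel band, then the whole table is normalized to the 562 nm channel.
#'
#' @param cell_means mean cell-pixel intensity per channel.
#' @param background_means mean background-pixel intensity per channel.
#' @param channels data.frame with columns `lambda_em` (nm) and `phi_int`
#'   (integrated quantum efficiency over the channel band), one row per
#'   channel; must include a 562 nm channel.
#' @return data.frame: `lambda_em`, `I_AF` (detector-normalized),
#'   `I_AF_rel` (relative to 562 nm).
#' @export
autofluorescence_spectrum <- function(cell_means, background_means, channels) {
  stopifnot(length(cell_means) == nrow(channels),
            length(background_means) == nrow(channels))
  check_positive(channels$phi_int, "phi_int")
  i562 <- which(channels$lambda_em == 562)
  if (!length(i562)) stop_bad_arg("a 562 nm reference channel is required")
  iaf <- (cell_means - background_means) / channels$phi_int
  ref <- iaf[i562[1]]
  data.frame(lambda_em = channels$lambda_em, I_AF = iaf,
             I_AF_rel = if (ref != 0) iaf / ref else rep(NA_real_, length(iaf)))
}

#' Autofluorescence spot intensity at one centroid
#'
#' Quantum-efficiency-corrected, background-subtracted 3 x 3 window sum on
#' a cell region containing no detected quantum dots: the single-spot-level
#' autofluorescence competing with probe signal in that channel.
#'
#' @param frame 2D image.
#' @param centroid `(x, y)`; rounded half-up.
#' @param background_mean mean background 3 x 3 window sum.
#' @param quantum_efficiency detector quantum efficiency at the emission
#'   wavelength, in (0, 1].
#' @return corrected intensity (counts).
#' @export
autofluorescence_spot_intensity <- function(frame, centroid, background_mean,
                                            quantum_efficiency = 1) {
  if (quantum_efficiency <= 0 || quantum_efficiency > 1)
    stop_bad_arg("quantum_efficiency must lie in (0, 1]")
  x0 <- round_half_up(centroid[1]); y0 <- round_half_up(centroid[2])
  d <- dim(frame)
  if (x0 < 2 || y0 < 2 || x0 > d[1] - 1 || y0 > d[2] - 1)
    stop_bad_arg("3x3 window clipped by the frame border")
  (sum(frame[(x0 - 1):(x0 + 1), (y0 - 1):(y0 + 1)]) - background_mean) /
    quantum_efficiency
}

#' Area under the ROC curve for spot detection
#'
#' Rank-based (Mann-Whitney) AUROC with mid-rank tie handling: the
#' probability that a randomly chosen signal intensity exceeds a randomly
#' chosen background intensity.
#'
#' @param signal signal intensities.
#' @param background background intensities.
#' @return AUROC in [0, 1].
#' @export
detection_auroc <- function(signal, background) {
  if (!length(signal) || !length(background))
    stop_bad_arg("both intensity lists must be non-empty")
  r <- rank(c(signal, background))
  n1 <- length(signal); n2 <- length(background)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
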