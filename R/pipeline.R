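config_schema <- list(
  paths = c("movie", "stack", "psf", "mask", "truth", "membrane", "nucleus"),
  optics = c("pixel_size_nm", "z_spacing_nm", "psf_sigma_xy_px",
             "psf_sigma_z_planes", "exposure_ms", "camera_gain",
             "read_noise_sd", "quantum_efficiency"),
  detection = c("threshold_k", "min_voxels", "alarm_rate", "max_deflations"),
  fitting = c("n_bin", "min_frames", "min_singles", "n_starts"),
  deconvolution = c("iterations", "damp"),
  geometry = c("alpha_radius", "threshold"),
  kinetics = c("preset", "egf0", "t"),
  seed = NULL, output_dir = NULL, exposure_ms_movie = NULL,
  exposure_ms_stack = NULL, xy_offset = NULL
)

#' Read and validate a run configuration
#'
#' Loads a YAML run configuration, rejects unknown keys, applies defaults,
#' and checks that all referenced input files exist before any computation
#' starts.
#'
#' @param path YAML file (or a pre-built list for programmatic use).
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop_bad_arg("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (blk in names(config_schema)) {
    if (!is.null(config_schema[[blk]]) && !is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), config_schema[[blk]])
      if (length(bad))
        stop_bad_arg("unknown keys in '", blk, "': ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- tempfile("qdc3dm_run_")
  for (p in cfg$paths[c("movie", "stack", "psf")]) {
    if (!is.null(p) && is.character(p) && !file.exists(p))
      stop_bad_arg("input file does not exist: ", p)
  }
  defaults <- list(
    detection = list(threshold_k = 6, min_voxels = 4, alarm_rate = 1e-5,
                     max_deflations = 10),
    fitting = list(n_bin = 100, min_frames = 100, min_singles = 10, n_starts = 8),
    deconvolution = list(iterations = 60, damp = 0),
    geometry = list(alpha_radius = 50, threshold = 0.8))
  for (blk in names(defaults))
    for (k in names(defaults[[blk]]))
      if (is.null(cfg[[blk]][[k]])) cfg[[blk]][[k]] <- defaults[[blk]][[k]]
  cfg
}

#' Run the three-step counting pipeline end to end
#'
#' Executes the full calibrated counting scheme on one field of view:
#' deconvolve the 3D stack, detect 3D spots, extract 3 x 3 blinking traces
#' from the 2D movie at the spot positions, classify single quantum dots,
#' average their deconvolved intensities into the calibration standard,
#' and convert every spot intensity to a molecule count. Optionally scores
#' internalization against a membrane surface. All artifacts (per-spot
#' CSV, per-cell JSON summary, run log) are written to the output
#' directory and are fully determined by the configuration.
#'
#' @param config a [read_run_config()] result, a YAML path, or a list
#'   with elements `movie`, `stack`, `psf` given as in-memory arrays.
#' @param movie,stack,psf optional in-memory inputs overriding the
#'   configured paths (arrays; `psf` a `psf3d`).
#' @param membrane_points,nucleus optional membrane point cloud and
#'   nucleus centroid enabling internalization scoring.
#' @return a results bundle: `calibration`, `spots` (per-spot table with
#'   `n_qd_spot`), `cell` ([count_cell()] result), `internalization`
#'   (or `NULL`), `config`, `log`.
#' @export
run_qdc3dm <- function(config, movie = NULL, stack = NULL, psf = NULL,
                       membrane_points = NULL, nucleus = NULL) {
  cfg <- read_run_config(config)
  log <- list(package_version = as.character(utils::packageVersion("qdc3dm")),
              r_version = R.version.string, seed = cfg$seed,
              started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (is.null(movie)) movie <- read_image_tiff(cfg$paths$movie)
  if (is.null(stack)) stack <- read_image_tiff(cfg$paths$stack)
  if (is.null(psf)) psf <- normalize_psf(read_image_tiff(cfg$paths$psf))
  exp_m <- cfg$exposure_ms_movie %||% NA_real_
  exp_s <- cfg$exposure_ms_stack %||% NA_real_
  if (!is.na(exp_m) && !is.na(exp_s) && exp_m != exp_s)
    warning("movie and stack exposure times differ (", exp_m, " vs ", exp_s,
            " ms); calibration and counting should share acquisition settings")

  dec <- richardson_lucy(stack, psf, iterations = cfg$deconvolution$iterations,
                         damp = cfg$deconvolution$damp)
  spots <- detect_spots_3d(dec, threshold_k = cfg$detection$threshold_k,
                           min_voxels = cfg$detection$min_voxels)
  log$n_spots_detected <- nrow(spots)
  spots <- spots[spots$flag != "border", , drop = FALSE]
  bg <- estimate_background(dec, spots, window = c(3, 3, 11),
                            seed = derive_seed(cfg$seed, "bg"))
  spots$I_spot_3dd <- vapply(seq_len(nrow(spots)), function(i)
    spot_intensity_3dd(dec, c(spots$x[i], spots$y[i], spots$z[i]), bg),
    numeric(1))

  d2 <- dim(movie)
  singles <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (spots$xr[i] < 2 || spots$yr[i] < 2 ||
        spots$xr[i] > d2[1] - 1 || spots$yr[i] > d2[2] - 1) next
    tr <- extract_trace(movie, c(spots$xr[i], spots$yr[i]),
                        exposure_ms = exp_m)
    if (length(tr$values) < cfg$fitting$min_frames) next
    cls <- classify_single_qd(tr, seed = derive_seed(cfg$seed, paste0("cls", i)),
                              n_bin = cfg$fitting$n_bin,
                              min_frames = cfg$fitting$min_frames)
    singles[i] <- cls$is_single
  }
  spots$is_single <- singles
  n_single <- sum(singles & spots$I_spot_3dd > 0)
  log$n_single_qd <- n_single
  if (n_single < cfg$fitting$min_singles)
    stop_bad_arg("calibration failure in single-QD identification: only ",
                 n_single, " accepted single QDs (need >= ",
                 cfg$fitting$min_singles, ")")
  cal <- calibrate_single_qd(spots$I_spot_3dd[singles & spots$I_spot_3dd > 0])
  cell <- count_cell(spots, cal)
  internal <- NULL
  if (!is.null(membrane_points) && !is.null(nucleus)) {
    zs <- if (!is.null(cfg$optics))
      cfg$optics$z_spacing_nm / cfg$optics$pixel_size_nm else 1
    surf <- build_surface(membrane_points,
                          alpha_radius = cfg$geometry$alpha_radius,
                          z_scale = zs)
    rho <- vapply(seq_len(nrow(cell$spots)), function(i)
      relative_distance(c(cell$spots$x[i], cell$spots$y[i], cell$spots$z[i]),
                        nucleus, surf), numeric(1))
    internal <- internalized_fraction(cell$spots$n_qd_spot, rho,
                                      threshold = cfg$geometry$threshold,
                                      nucleus = nucleus)
  }
  log$background_mean_3x3x11 <- bg
  log$calibration_mean <- cal$mean_I_1QD_3DD
  log$N_cell <- cell$N_cell
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cell$spots, file.path(cfg$output_dir, "spots.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(N_cell = cell$N_cell, N_cell_int = cell$N_cell_int,
         calibration = cal[c("mean_I_1QD_3DD", "n_single", "dispersion")],
         internal_fraction = if (!is.null(internal)) internal$fraction else NULL,
         log = log),
    file.path(cfg$output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  structure(list(calibration = cal, spots = cell$spots, cell = cell,
                 internalization = internal, config = cfg, log = log),
            class = "qdc3dm_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a results bundle
#'
#' Human-readable tables: per-cell molecule counts, calibration
#' diagnostics, and internalization fractions when present.
#'
#' @param bundles one `qdc3dm_result` or a list of them.
#' @return data.frame with one row per cell (printed as a side effect is
#'   left to the caller). Empty input gives an empty data.frame with a
#'   warning.
#' @export
qdc_report <- function(bundles) {
  if (inherits(bundles, "qdc3dm_result")) bundles <- list(bundles)
  if (!length(bundles)) {
    warning("empty results bundle; nothing to report")
    return(data.frame(cell = integer(0), N_cell = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    data.frame(cell = i,
               N_cell = b$cell$N_cell,
               N_cell_int = b$cell$N_cell_int,
               n_spots = nrow(b$spots),
               n_single_qd = b$calibration$n_single,
               cal_mean_I = b$calibration$mean_I_1QD_3DD,
               cal_dispersion = b$calibration$dispersion,
               internal_fraction = if (!is.null(b$internalization))
                 b$internalization$fraction else NA_real_)
  }))
}
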