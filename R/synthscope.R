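#' Microscope optics and camera configuration
#'
#' Bundles the acquisition parameters of the (synthetic) wide-field
#' microscope: sampling, the separable Gaussian point-spread function, and
#' the camera noise model. Defaults describe a 100x/1.45NA objective with a
#' back-illuminated EMCCD (160 nm pixels) acquiring near-infrared emission at
#' 250 nm z-spacing, the axial sampling used throughout for volumetric
#' stacks.
#'
#' @param pixel_size_nm lateral pixel size in the sample plane (nm).
#' @param z_spacing_nm axial plane spacing (nm); default 250.
#' @param psf_sigma_xy_px lateral Gaussian PSF width (pixels).
#' @param psf_sigma_z_planes axial Gaussian PSF width (planes).
#' @param exposure_ms camera exposure per frame (ms).
#' @param camera_gain conversion gain (counts per detected photon).
#' @param read_noise_sd Gaussian read noise (counts, per pixel per frame).
#' @param quantum_efficiency detector quantum efficiency `Phi` at the
#'   emission wavelength, in (0, 1]. Measured counts are `Phi` times the
#'   arriving photon flux; intensity calibration divides it back out.
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_nm = 160, z_spacing_nm = 250,
                          psf_sigma_xy_px = 0.7, psf_sigma_z_planes = 1.4,
                          exposure_ms = 100, camera_gain = 1,
                          read_noise_sd = 2, quantum_efficiency = 0.9) {
  check_positive(pixel_size_nm, "pixel_size_nm")
  check_positive(z_spacing_nm, "z_spacing_nm")
  check_positive(psf_sigma_xy_px, "psf_sigma_xy_px")
  check_positive(psf_sigma_z_planes, "psf_sigma_z_planes")
  check_positive(exposure_ms, "exposure_ms")
  check_positive(camera_gain, "camera_gain")
  check_positive(read_noise_sd, "read_noise_sd", strict = FALSE)
  if (quantum_efficiency <= 0 || quantum_efficiency > 1)
    stop_bad_arg("quantum_efficiency must lie in (0, 1]")
  structure(list(pixel_size_nm = pixel_size_nm, z_spacing_nm = z_spacing_nm,
                 psf_sigma_xy_px = psf_sigma_xy_px,
                 psf_sigma_z_planes = psf_sigma_z_planes,
                 exposure_ms = exposure_ms, camera_gain = camera_gain,
                 read_noise_sd = read_noise_sd,
                 quantum_efficiency = quantum_efficiency),
            class = "optics_config")
}

#' Simulate quantum-dot blinking state sequences
#'
#' Each quantum dot switches between an emitting ("on") and dark ("off")
#' state as a two-state Markov chain sampled once per frame. The long-run
#' on-fraction is `k_on_blink / (k_on_blink + k_off_blink)`.
#'
#' @param n_qd number of quantum dots.
#' @param n_frames number of frames (>= 1).
#' @param p_on initial on-probability; defaults to the stationary
#'   on-fraction of the chain (0.5 when both switch rates are zero).
#' @param k_on_blink per-frame probability of an off -> on transition.
#' @param k_off_blink per-frame probability of an on -> off transition.
#' @param seed integer seed.
#' @return binary matrix (`n_qd` x `n_frames`), 1 = on.
#' @export
simulate_blinking_states <- function(n_qd, n_frames, p_on = NULL,
                                     k_on_blink = 0.3, k_off_blink = 0.3,
                                     seed = 1L) {
  if (n_frames < 1) stop_bad_arg("n_frames must be >= 1")
  check_probability(k_on_blink, "k_on_blink")
  check_probability(k_off_blink, "k_off_blink")
  if (is.null(p_on)) {
    p_on <- if (k_on_blink + k_off_blink > 0)
      k_on_blink / (k_on_blink + k_off_blink) else 0.5
  }
  check_probability(p_on, "p_on")
  with_seed(seed, {
    s <- matrix(0L, n_qd, n_frames)
    if (n_qd == 0L) return(s)
    state <- as.integer(stats::runif(n_qd) < p_on)
    s[, 1L] <- state
    if (n_frames > 1L) {
      for (t in 2L:n_frames) {
        u <- stats::runif(n_qd)
        state <- ifelse(state == 1L,
                        as.integer(u >= k_off_blink),
                        as.integer(u < k_on_blink))
        s[, t] <- state
      }
    }
    s
  })
}

#' Define a point emitter with ground truth
#'
#' @param position numeric length-2 or length-3 sub-pixel position
#'   `(x, y[, z])` in pixel / plane units (1-based array coordinates).
#' @param n_qd integer number of quantum dots at this position (>= 1).
#' @param brightness_per_qd expected photons emitted per quantum dot per
#'   frame while on (PSF integrates to this total).
#' @param states optional precomputed binary on/off matrix
#'   (`n_qd` x frames); simulated at render time when `NULL`.
#' @param id emitter label.
#' @return an `emitter_truth` object.
#' @export
emitter <- function(position, n_qd = 1L, brightness_per_qd = 500,
                    states = NULL, id = NA_character_) {
  check_positive(brightness_per_qd, "brightness_per_qd")
  if (n_qd < 1) stop_bad_arg("n_qd must be >= 1")
  if (!is.null(states) && !all(states %in% c(0L, 1L)))
    stop_bad_arg("states must be a 0/1 matrix")
  structure(list(position = as.numeric(position), n_qd = as.integer(n_qd),
                 brightness_per_qd = brightness_per_qd, states = states,
                 id = id),
            class = "emitter_truth")
}

#' Assemble a synthetic scene with ground truth
#'
#' @param emitters list of [emitter()] objects.
#' @param dims image dimensions `c(nx, ny)` or `c(nx, ny, nz)`.
#' @param autofluorescence mean diffuse background (counts per pixel):
#'   a scalar, or an array matching `dims` laterally.
#' @param nucleus_centroid optional `(x, y, z)` nucleus position.
#' @param membrane_points optional `n x 3` membrane-stain point cloud.
#' @param blink_kinetics list with `k_on`, `k_off`, `p_on` governing
#'   per-frame blinking in 2D movies when emitters carry no precomputed
#'   state sequences. The default 50% duty cycle gives the clean two-level
#'   traces that identify single quantum dots.
#' @param blink_kinetics_3d per-plane blinking for volumetric stacks.
#'   `NULL` (default) selects a sticky chain with stationary on-fraction
#'   0.9: volumetric acquisition uses thick-shell quantum dots under low
#'   excitation and brief per-plane exposure, so dark plane runs occur but
#'   are short.
#' @param seed master scene seed; all render randomness derives from it.
#' @return a `scene_truth` object.
#' @export
scene <- function(emitters, dims, autofluorescence = 0,
                  nucleus_centroid = NULL, membrane_points = NULL,
                  blink_kinetics = list(k_on = 0.3, k_off = 0.3, p_on = NULL),
                  blink_kinetics_3d = NULL,
                  seed = 1L) {
  stopifnot(is.list(emitters))
  if (is.null(blink_kinetics_3d))
    blink_kinetics_3d <- list(k_on = 0.45, k_off = 0.05, p_on = NULL)
  structure(list(emitters = emitters, dims = as.integer(dims),
                 autofluorescence = autofluorescence,
                 nucleus_centroid = nucleus_centroid,
                 membrane_points = membrane_points,
                 blink_kinetics = blink_kinetics,
                 blink_kinetics_3d = blink_kinetics_3d,
                 seed = as.integer(seed)),
            class = "scene_truth")
}

# Pixel-integrated 1D Gaussian line profile centred at `center` (1-based).
gauss_profile <- function(n, center, sigma) {
  e <- seq(0.5, n + 0.5)
  diff(stats::pnorm(e, mean = center, sd = sigma))
}

#' Analytic PSF mass inside a centred window
#'
#' Fraction of a unit-normalised separable Gaussian PSF falling inside a
#' window of `c(wx, wy[, wz])` whole pixels centred on the emitter.
#' Used as the independent oracle for intensity-calibration tests.
#'
#' @param optics an [optics_config()].
#' @param window window size in pixels/planes, length 2 or 3.
#' @param offset sub-pixel emitter offset from the window centre.
#' @return scalar mass in (0, 1).
#' @export
psf_window_mass <- function(optics, window = c(3, 3, 11), offset = NULL) {
  if (is.null(offset)) offset <- rep(0, length(window))
  sig <- c(optics$psf_sigma_xy_px, optics$psf_sigma_xy_px,
           optics$psf_sigma_z_planes)[seq_along(window)]
  m <- 1
  for (i in seq_along(window)) {
    h <- window[i] / 2
    m <- m * (stats::pnorm(h, offset[i], sig[i]) - stats::pnorm(-h, offset[i], sig[i]))
  }
  m
}

# Add `flux` photons of a 2D Gaussian at (x, y) into matrix `img` (in place
# value-return). Truncated at +-6 sigma for speed; profile is pixel-integrated.
add_spot_2d <- function(img, x, y, sigma, flux) {
  nx <- nrow(img); ny <- ncol(img)
  r <- ceiling(6 * sigma)
  xs <- max(1, floor(x - r)):min(nx, ceiling(x + r))
  ys <- max(1, floor(y - r)):min(ny, ceiling(y + r))
  if (!length(xs) || !length(ys)) return(img)
  px <- diff(stats::pnorm(c(xs[1] - 0.5, xs + 0.5), x, sigma))
  py <- diff(stats::pnorm(c(ys[1] - 0.5, ys + 0.5), y, sigma))
  img[xs, ys] <- img[xs, ys] + flux * outer(px, py)
  img
}

expand_af <- function(af, dims) {
  if (length(af) == 1L) return(array(af, dim = dims))
  if (length(dims) == 2L) {
    stopifnot(all(dim(af) == dims))
    return(af)
  }
  if (length(dim(af)) == 2L) return(array(rep(af, dims[3]), dim = dims))
  stopifnot(all(dim(af) == dims))
  af
}

apply_camera <- function(expected, optics, noiseless = FALSE) {
  expected <- pmax(expected, 0) * optics$quantum_efficiency
  if (noiseless) return(expected * optics$camera_gain)
  counts <- array(stats::rpois(length(expected), expected), dim = dim(expected))
  counts * optics$camera_gain +
    stats::rnorm(length(expected), 0, optics$read_noise_sd)
}

emitter_states <- function(scene_obj, em, i, n_steps, seed) {
  if (!is.null(em$states)) {
    stopifnot(ncol(em$states) >= n_steps)
    return(em$states[, seq_len(n_steps), drop = FALSE])
  }
  bk <- scene_obj$blink_kinetics
  simulate_blinking_states(em$n_qd, n_steps, p_on = bk$p_on,
                           k_on_blink = bk$k_on, k_off_blink = bk$k_off,
                           seed = derive_seed(seed, paste0("blink", i)))
}

#' Render a 2D time-series movie of blinking emitters
#'
#' Each frame is the sum over emitters of (number of on-QDs) x brightness x
#' pixel-integrated 2D Gaussian PSF, plus diffuse autofluorescence, passed
#' through a Poisson shot-noise / Gaussian read-noise camera model.
#'
#' @param scene a [scene()] with 2D (or 3D; z ignored) emitter positions.
#' @param optics an [optics_config()].
#' @param n_frames number of frames.
#' @param seed render seed; defaults to the scene seed.
#' @param noiseless render expected counts without camera noise.
#' @return list with `movie` (array `nx x ny x n_frames`) and `truth`
#'   (per-emitter on/off state matrices and positions).
#' @export
render_timeseries <- function(scene, optics, n_frames, seed = scene$seed,
                              noiseless = FALSE) {
  dims <- scene$dims[1:2]
  states <- lapply(seq_along(scene$emitters), function(i)
    emitter_states(scene, scene$emitters[[i]], i, n_frames, seed))
  af <- expand_af(scene$autofluorescence, dims)
  movie <- array(0, dim = c(dims, n_frames))
  with_seed(derive_seed(seed, "camera2d"), {
    for (t in seq_len(n_frames)) {
      frame <- af
      for (i in seq_along(scene$emitters)) {
        em <- scene$emitters[[i]]
        n_on <- sum(states[[i]][, t])
        if (n_on > 0)
          frame <- add_spot_2d(frame, em$position[1], em$position[2],
                               optics$psf_sigma_xy_px,
                               n_on * em$brightness_per_qd)
      }
      movie[, , t] <- apply_camera(frame, optics, noiseless)
    }
  })
  truth <- list(positions = t(vapply(scene$emitters,
                                     function(e) e$position[1:2], numeric(2))),
                n_qd = vapply(scene$emitters, `[[`, integer(1), "n_qd"),
                states = states)
  list(movie = movie, truth = truth)
}

#' Render a 3D volumetric stack of blinking emitters
#'
#' As [render_timeseries()] but with a separable 3D Gaussian PSF; the on/off
#' state is resampled per z-plane, so a quantum dot may be dark in some
#' slices of the stack, exactly as during sequential plane acquisition.
#'
#' @param scene a [scene()] with 3D emitter positions.
#' @param optics an [optics_config()].
#' @param n_planes number of z planes.
#' @param seed render seed; defaults to the scene seed.
#' @param noiseless render expected counts without camera noise.
#' @param blinking apply per-plane blinking using the scene's
#'   `blink_kinetics_3d` (set `FALSE` for always-on).
#' @return list with `stack` (array `nx x ny x n_planes`) and `truth`.
#' @export
render_stack3d <- function(scene, optics, n_planes, seed = scene$seed,
                           noiseless = FALSE, blinking = TRUE) {
  dims <- c(scene$dims[1:2], n_planes)
  sc_blink <- scene
  sc_blink$blink_kinetics <- scene$blink_kinetics_3d %||%
    list(k_on = 0.45, k_off = 0.05, p_on = NULL)
  states <- lapply(seq_along(scene$emitters), function(i) {
    em <- scene$emitters[[i]]
    if (blinking) emitter_states(sc_blink, em, i, n_planes,
                                 derive_seed(seed, "z"))
    else matrix(1L, em$n_qd, n_planes)
  })
  af <- expand_af(scene$autofluorescence, dims)
  stack <- array(0, dim = dims)
  expected <- af
  for (i in seq_along(scene$emitters)) {
    em <- scene$emitters[[i]]
    zw <- gauss_profile(n_planes, em$position[3], optics$psf_sigma_z_planes)
    for (z in seq_len(n_planes)) {
      n_on <- sum(states[[i]][, z])
      if (n_on > 0 && zw[z] > 0)
        expected[, , z] <- add_spot_2d(expected[, , z], em$position[1],
                                       em$position[2], optics$psf_sigma_xy_px,
                                       n_on * em$brightness_per_qd * zw[z])
    }
  }
  stack <- with_seed(derive_seed(seed, "camera3d"),
                     apply_camera(expected, optics, noiseless))
  truth <- list(positions = t(vapply(scene$emitters,
                                     function(e) e$position[1:3], numeric(3))),
                n_qd = vapply(scene$emitters, `[[`, integer(1), "n_qd"),
                states = states)
  list(stack = stack, truth = truth)
}

#' Generate a patterned synthetic cell with bound-ligand ground truth
#'
#' Emulates a micropatterned cell: a closed ellipsoidal membrane point cloud,
#' a nucleus at the cell centre, and bound EGF spots drawn from the
#' ligand-receptor binding model. Each ligand is placed internal (relative
#' radial distance drawn below 0.8) with probability `internal_fraction_true`
#' and on the membrane surface otherwise; the truth table records each
#' spot's label.
#'
#' @param params [kinetic_params()] defining the stimulation condition.
#' @param receptor [receptor_distribution()] of per-cell receptor numbers.
#' @param pattern numeric `c(semi_x, semi_y, semi_z)` ellipsoid semi-axes in
#'   pixel units (z in plane units after axial rescale).
#' @param internal_fraction_true probability a ligand is internalized.
#' @param center cell centre `(x, y, z)`.
#' @param n_membrane_points membrane-stain points to sample on the surface.
#' @param n_spots override the model-drawn number of bound ligands.
#' @param seed integer seed.
#' @return a [scene()] whose `truth` element carries spot positions,
#'   internal/external labels and the drawn ligand count.
#' @export
generate_cell_fixture <- function(params, receptor,
                                  pattern = c(20, 14, 10),
                                  internal_fraction_true = 0.5,
                                  center = c(32, 32, 16),
                                  n_membrane_points = 400,
                                  n_spots = NULL, seed = 1L) {
  check_probability(internal_fraction_true, "internal_fraction_true")
  if (any(pattern <= 0)) stop_bad_arg("pattern semi-axes must be positive")
  with_seed(derive_seed(seed, "cell"), {
    # uniform directions; ellipsoidal mapping for membrane + spots
    rand_dirs <- function(n) {
      v <- matrix(stats::rnorm(3 * n), ncol = 3)
      v / sqrt(rowSums(v^2))
    }
    mem <- rand_dirs(n_membrane_points)
    membrane <- sweep(sweep(mem, 2, pattern, `*`), 2, center, `+`)
    if (is.null(n_spots))
      n_spots <- sample_cells(params, receptor, n_cells = 1L,
                              seed = derive_seed(seed, "nbound"))
    n_spots <- as.integer(n_spots)
    internal <- stats::runif(n_spots) < internal_fraction_true
    dirs <- rand_dirs(n_spots)
    # internal spots: relative radius in (0.1, 0.75); external: on surface
    rho <- ifelse(internal, stats::runif(n_spots, 0.1, 0.75), 1)
    pos <- sweep(sweep(dirs * rho, 2, pattern, `*`), 2, center, `+`)
    emitters <- lapply(seq_len(n_spots), function(i)
      emitter(pos[i, ], n_qd = 1L, brightness_per_qd = 2000,
              id = sprintf("egf%03d", i)))
    sc <- scene(emitters,
                dims = ceiling(center + pattern + 8),
                autofluorescence = 20,
                nucleus_centroid = center,
                membrane_points = membrane, seed = seed)
    sc$truth <- list(n_bound = n_spots, positions = pos,
                     internal = internal, rho_true = rho)
    sc
  })
}

#' Write a rendered movie or stack as a multi-page TIFF
#'
#' Pages are frames (movies) or z-planes (stacks). Camera counts are stored
#' in 32-bit samples over the 16-bit dynamic range of an EMCCD (counts /
#' 65536), giving lossless round trips to ~1e-5 counts; values beyond
#' 65535 counts are clamped with a warning.
#'
#' @param img 3D array (`x` by `y` by page) of camera counts.
#' @param path output file.
#' @export
write_image_tiff <- function(img, path) {
  if (any(img >= 65536)) {
    warning("counts above the 16-bit camera range clamped at 65535")
    img <- pmin(img, 65535)
  }
  img <- pmax(img, 0)
  pages <- lapply(seq_len(dim(img)[3]), function(k) img[, , k] / 65536)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a 3D array
#'
#' Inverts the count scaling of [write_image_tiff()]; pages become the
#' third array dimension.
#'
#' @param path TIFF file.
#' @return numeric 3D array of camera counts.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65536
  arr
}

#' Write an emitter ground-truth table as CSV
#'
#' @param truth the `truth` element returned by a render function or
#'   [generate_cell_fixture()].
#' @param path output CSV.
#' @export
write_truth_csv <- function(truth, path) {
  pos <- truth$positions
  df <- data.frame(id = seq_len(nrow(pos)),
                   x = pos[, 1], y = pos[, 2],
                   z = if (ncol(pos) >= 3) pos[, 3] else NA_real_)
  if (!is.null(truth$n_qd)) df$n_qd <- truth$n_qd
  if (!is.null(truth$internal)) df$label <- ifelse(truth$internal, "internal", "external")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
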