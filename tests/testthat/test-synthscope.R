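test_that("blinking chains honour absorbing states and stationarity", {
  expect_equal(simulate_blinking_states(3, 50, p_on = 1, k_on_blink = 0.3,
                                        k_off_blink = 0, seed = 1),
               matrix(1L, 3, 50))
  expect_equal(simulate_blinking_states(3, 50, p_on = 0, k_on_blink = 0,
                                        k_off_blink = 0.3, seed = 1),
               matrix(0L, 3, 50))
  s <- simulate_blinking_states(1, 1e4, k_on_blink = 0.3, k_off_blink = 0.3,
                                seed = 42)
  expect_lt(abs(mean(s) - 0.5), 0.02)
  # stationarity within 3 standard errors at an asymmetric rate pair
  s2 <- simulate_blinking_states(20, 5000, k_on_blink = 0.2, k_off_blink = 0.05,
                                 seed = 7)
  p <- 0.2 / 0.25
  se <- sqrt(p * (1 - p) / length(s2)) * 3 # iid bound x3; chain mixes fast
  expect_lt(abs(mean(s2) - p), max(3 * se, 0.02))
  expect_error(simulate_blinking_states(1, 10, k_on_blink = 1.2),
               "probability")
})

test_that("time-series rendering matches the analytic PSF model", {
  opt <- test_optics(read_noise_sd = 0)
  empty <- scene(list(), dims = c(16, 16), autofluorescence = 0, seed = 1)
  m0 <- render_timeseries(empty, opt, 3)$movie
  expect_true(all(m0 == 0))
  # one always-on QD, noiseless: 3x3 sum equals brightness x PSF mass x QE
  sc <- scene(list(emitter(c(8, 8), 1, brightness_per_qd = 600)),
              dims = c(15, 15), autofluorescence = 0,
              blink_kinetics = always_on, seed = 2)
  r <- render_timeseries(sc, opt, 2, noiseless = TRUE)
  expected <- 600 * psf_window_mass(opt, c(3, 3)) * opt$quantum_efficiency
  tr <- extract_trace(r$movie, c(8, 8))
  expect_equal(tr$values, rep(expected, 2), tolerance = 1e-6)
  # two independently blinking QDs: noiseless trace takes ~3 discrete levels
  sc2 <- scene(list(emitter(c(8, 8), 2, brightness_per_qd = 600)),
               dims = c(15, 15), autofluorescence = 0, seed = 3)
  r2 <- render_timeseries(sc2, opt, 200, noiseless = TRUE)
  tr2 <- extract_trace(r2$movie, c(8, 8))
  lv <- sort(unique(round(tr2$values / expected)))
  expect_true(all(lv %in% 0:2))
  expect_equal(length(lv), 3L)
  n_on <- colSums(r2$truth$states[[1]])
  expect_equal(round(tr2$values / expected), n_on, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("3D stacks conserve photons and are seed-deterministic", {
  opt <- test_optics(read_noise_sd = 0)
  sc <- scene(list(emitter(c(12, 14, 16), 1, brightness_per_qd = 900)),
              dims = c(25, 25), autofluorescence = 0,
              blink_kinetics = always_on, seed = 5)
  r <- render_stack3d(sc, opt, 31, noiseless = TRUE, blinking = FALSE)
  expected <- 900 * psf_window_mass(opt, c(3, 3, 11)) * opt$quantum_efficiency
  expect_equal(spot_intensity_3dd(r$stack, c(12, 14, 16), 0), expected,
               tolerance = 1e-5)
  # photon conservation pre-noise: total expected signal = brightness x QE
  expect_equal(sum(r$stack), 900 * opt$quantum_efficiency, tolerance = 1e-6)
  # near-delta PSF concentrates the emitter in one voxel
  opt_d <- test_optics(psf_sigma_xy_px = 0.05, psf_sigma_z_planes = 0.05,
                       read_noise_sd = 0)
  rd <- render_stack3d(sc, opt_d, 31, noiseless = TRUE, blinking = FALSE)
  expect_gt(max(rd$stack) / sum(rd$stack), 0.999)
  # determinism: identical seed + config -> identical noisy arrays
  noisy1 <- render_stack3d(sc, test_optics(), 31)$stack
  noisy2 <- render_stack3d(sc, test_optics(), 31)$stack
  expect_identical(noisy1, noisy2)
  noisy3 <- render_stack3d(sc, test_optics(), 31, seed = 99)$stack
  expect_false(identical(noisy1, noisy3))
})

test_that("cell fixtures honour the requested internalization truth", {
  p <- kinetic_params("4C", egf0 = 0.3e-9, t = 300)
  rd <- receptor_distribution()
  sc0 <- generate_cell_fixture(p, rd, internal_fraction_true = 0,
                               n_spots = 40, seed = 3)
  expect_true(all(!sc0$truth$internal))
  expect_true(all(abs(sc0$truth$rho_true - 1) < 1e-12))
  sc1 <- generate_cell_fixture(p, rd, internal_fraction_true = 1,
                               n_spots = 40, seed = 3)
  expect_true(all(sc1$truth$internal))
  expect_error(generate_cell_fixture(p, rd, pattern = c(0, 5, 5), seed = 1),
               "positive")
})

test_that("fixture ligand counts follow the binding model", {
  p <- kinetic_params("4C", egf0 = 0.3e-9, t = 300)
  rd <- receptor_distribution()
  ns <- vapply(1:200, function(s)
    generate_cell_fixture(p, rd, n_spots = NULL, seed = s)$truth$n_bound,
    integer(1))
  # closed-form two-state mean ~ 88.8 at these conditions; gamma spread is
  # wide (cv ~ 0.55) so compare the mean over 200 cells loosely
  expect_lt(abs(mean(ns) - mean_bound(p, 1e5)) / mean_bound(p, 1e5), 0.1)
})

test_that("TIFF round trips and truth CSVs preserve the scene", {
  opt <- test_optics()
  sc <- scene(list(emitter(c(6, 7, 5), 2, brightness_per_qd = 400)),
              dims = c(12, 12), autofluorescence = 10, seed = 8)
  r <- render_stack3d(sc, opt, 9)
  path <- tempfile(fileext = ".tif")
  write_image_tiff(r$stack, path)
  back <- read_image_tiff(path)
  expect_equal(back, pmax(r$stack, 0), tolerance = 1e-4)
  csv <- tempfile(fileext = ".csv")
  write_truth_csv(r$truth, csv)
  tab <- read.csv(csv)
  expect_equal(tab$x, 6)
  expect_equal(tab$n_qd, 2L)
})
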