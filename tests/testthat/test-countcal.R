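test_that("window intensities subtract background exactly", {
  st <- array(3, dim = c(20, 20, 20))
  expect_equal(spot_intensity_3dd(st, c(10, 10, 10), 99 * 3), 0)
  delta <- array(0, dim = c(20, 20, 20)); delta[10, 10, 10] <- 42
  expect_equal(spot_intensity_3dd(delta, c(10, 10, 10), 0), 42)
  expect_error(spot_intensity_3dd(st, c(10, 10, 3), 0), "border")
  # rendered QD over a flat offset: background subtraction recovers flux
  opt <- test_optics(read_noise_sd = 0)
  sc <- scene(list(emitter(c(15, 15, 12), 1, brightness_per_qd = 2000)),
              dims = c(30, 30), autofluorescence = 25,
              blink_kinetics = always_on, seed = 2)
  r <- render_stack3d(sc, opt, 24, noiseless = TRUE, blinking = FALSE)$stack
  bg <- 99 * 25 * opt$quantum_efficiency
  expected <- 2000 * psf_window_mass(opt, c(3, 3, 11)) * opt$quantum_efficiency
  expect_lt(abs(spot_intensity_3dd(r, c(15, 15, 12), bg) - expected) / expected,
            0.05)
})

test_that("background estimation masks out detected spots", {
  st <- array(4, dim = c(24, 24, 20))
  expect_equal(estimate_background(st, NULL, n_windows = 200), 99 * 4)
  st2 <- st; st2[12, 12, 10] <- 1e6
  sp <- data.frame(xr = 12, yr = 12, zr = 10)
  b <- estimate_background(st2, sp, n_windows = 200)
  expect_lt(abs(b - 99 * 4) / (99 * 4), 0.01)
  expect_error(estimate_background(st, mask = array(FALSE, dim = c(24, 24, 20))),
               "empty")
  expect_error(estimate_background(array(1, dim = c(4, 4, 12))), "insufficient")
})

test_that("single-QD calibration averages contributing intensities", {
  cal <- calibrate_single_qd(c(900, 900, 900))
  expect_equal(cal$mean_I_1QD_3DD, 900)
  expect_equal(cal$dispersion, 0)
  expect_equal(cal$n_single, 3L)
  expect_error(calibrate_single_qd(numeric(0)), "no single")
  expect_equal(qds_per_spot(900, cal), 1)
  expect_equal(qds_per_spot(2700, cal), 3)
  expect_warning(n <- qds_per_spot(-10, cal), "overshoot")
  expect_equal(n, 0)
})

test_that("72 isolated emitters calibrate to the analytic intensity", {
  opt <- test_optics()
  em <- grid_emitters(72, c(150, 150), 16, brightness = 2000,
                      z_range = c(13, 17), seed = 12)
  sc <- scene(em, dims = c(150, 150), autofluorescence = 20,
              blink_kinetics = always_on, seed = 13)
  st <- render_stack3d(sc, opt, 30, blinking = FALSE)$stack
  bg <- estimate_background(st, data.frame(
    xr = vapply(em, function(e) round(e$position[1]), numeric(1)),
    yr = vapply(em, function(e) round(e$position[2]), numeric(1)),
    zr = vapply(em, function(e) round(e$position[3]), numeric(1))),
    n_windows = 300, seed = 3)
  I <- vapply(em, function(e)
    spot_intensity_3dd(st, e$position, bg), numeric(1))
  cal <- calibrate_single_qd(I)
  # analytic oracle: window mass evaluated at each emitter's sub-pixel
  # offset from its rounded window centre
  expected <- mean(vapply(em, function(e)
    2000 * opt$quantum_efficiency *
      psf_window_mass(opt, c(3, 3, 11),
                      offset = e$position - floor(e$position + 0.5)),
    numeric(1)))
  expect_lt(abs(cal$mean_I_1QD_3DD - expected) / expected, 0.03)
  expect_equal(cal$n_single, 72L)
})

test_that("cell totals sum calibrated spot counts", {
  cal <- calibrate_single_qd(c(1000, 1000))
  empty <- count_cell(data.frame(I_spot_3dd = numeric(0)), cal)
  expect_equal(empty$N_cell, 0)
  cell <- count_cell(data.frame(I_spot_3dd = c(1000, 1000, 2000)), cal)
  expect_equal(cell$N_cell, 4)
  expect_equal(cell$N_cell_int, 4L)
  expect_equal(cell$spots$n_qd_spot, c(1, 1, 2))
})

test_that("autofluorescence spectra normalize to the 562 nm channel", {
  ch <- data.frame(lambda_em = c(562, 600, 732), phi_int = c(20, 18, 8))
  sp <- autofluorescence_spectrum(c(120, 90, 40), c(20, 18, 12), ch)
  expect_equal(sp$I_AF_rel[1], 1)
  expect_equal(autofluorescence_spectrum(c(50, 50, 50), c(50, 50, 50), ch)$I_AF,
               c(0, 0, 0))
  # halving the detector efficiency doubles raw values, not the ratios
  ch2 <- ch; ch2$phi_int <- ch$phi_int / 2
  sp2 <- autofluorescence_spectrum(c(120, 90, 40), c(20, 18, 12), ch2)
  expect_equal(sp2$I_AF, 2 * sp$I_AF)
  expect_equal(sp2$I_AF_rel, sp$I_AF_rel)
  expect_error(autofluorescence_spectrum(c(1, 2), c(0, 0),
                                         data.frame(lambda_em = c(600, 732),
                                                    phi_int = c(1, 1))),
               "562")
})

test_that("autofluorescence spot intensities scale with 1/Phi", {
  fr <- matrix(10, 15, 15)
  expect_equal(autofluorescence_spot_intensity(fr, c(8, 8), 90, 1), 0)
  fr2 <- matrix(12, 15, 15)
  a1 <- autofluorescence_spot_intensity(fr2, c(8, 8), 90, 1)
  expect_equal(autofluorescence_spot_intensity(fr2, c(8, 8), 90, 0.5), 2 * a1)
  # diffuse field: mean window sum approaches 9 x field mean / Phi
  set.seed(5)
  fr3 <- matrix(rpois(100 * 100, 30), 100, 100)
  vals <- vapply(1:200, function(i) {
    xy <- sample(3:98, 2)
    autofluorescence_spot_intensity(fr3, xy, 0, 0.9)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 9 * 30 / 0.9) / (9 * 30 / 0.9), 0.05)
})

test_that("AUROC equals the pairwise-comparison probability", {
  expect_equal(detection_auroc(11:20, 1:10), 1)
  set.seed(11)
  a <- sample(1:10, 120, TRUE); b <- sample(1:10, 90, TRUE)
  expect_lt(abs(detection_auroc(a, b) - 0.5), 0.05)
  # brute-force oracle with mid-rank tie credit, lists <= 200
  brute <- mean(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  expect_equal(detection_auroc(a, b), brute)
  expect_error(detection_auroc(numeric(0), 1:3), "non-empty")
})
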