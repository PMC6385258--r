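test_that("closed-form bound ligand matches limits and the ODE oracle", {
  p0 <- kinetic_params("4C", egf0 = 0, t = 300)
  expect_equal(mean_bound(p0, 1e5), 0)
  # irreversible limit: N_R (1 - exp(-k_on EGF0 t))
  pirr <- kinetic_params(preset = NULL, egf0 = 1e-9, t = 600,
                         k_on = 1e5, k_off = 0, k_int = 0)
  expect_equal(mean_bound(pirr, 5e4), 5e4 * (1 - exp(-1e5 * 1e-9 * 600)),
               tolerance = 1e-12)
  # 4C, 0.3 nM, 300 s, 1e5 receptors: frozen independent two-state value
  p4 <- kinetic_params("4C", egf0 = 0.3e-9, t = 300)
  expect_equal(mean_bound(p4, 1e5), 88.8202, tolerance = 1e-4)
  # closed form vs numerical integration on both presets
  for (p in list(p4, kinetic_params("37C", egf0 = 1e-9, t = 300))) {
    o <- mean_bound_ode(p, 1e5)
    expect_lt(abs(mean_bound(p, 1e5) - o$bound) / o$bound, 1e-8)
    # receptor-copy conservation: free + bound + internalized = N_R
    expect_lt(abs(sum(o$states) - 1e5) / 1e5, 1e-8)
  }
  expect_error(kinetic_params("4C", t = -5), "time")
})

test_that("discretized receptor distribution reproduces gamma moments", {
  rd <- receptor_distribution(a = 3.34, mean_NR = 1e5)
  pmf <- receptor_pmf(rd, 2000)
  expect_equal(sum(pmf$p), 1, tolerance = 1e-12)
  m <- sum(pmf$N_R * pmf$p)
  expect_lt(abs(m - rd$a * rd$b) / (rd$a * rd$b), 1e-3)
  cv <- sqrt(sum((pmf$N_R - m)^2 * pmf$p)) / m
  expect_lt(abs(cv - 1 / sqrt(3.34)) / (1 / sqrt(3.34)), 5e-3)
  # concentration limit: large shape kills the relative spread
  rd2 <- receptor_pmf(receptor_distribution(a = 5e4, mean_NR = 1e5), 2000)
  m2 <- sum(rd2$N_R * rd2$p)
  expect_lt(sqrt(sum((rd2$N_R - m2)^2 * rd2$p)) / m2, 0.01)
  expect_error(receptor_pmf(rd, 50), "n_nodes")
})

test_that("population mixture obeys Poisson and total-variance laws", {
  p <- kinetic_params("4C", egf0 = 0.3e-9, t = 300)
  # degenerate receptor distribution -> pure Poisson, cv = 1/sqrt(mean)
  rd_deg <- receptor_distribution(a = 1e6, mean_NR = 1e5)
  bd_deg <- population_distribution(p, rd_deg)
  expect_equal(bd_deg$cv, 1 / sqrt(bd_deg$mean), tolerance = 1e-3)
  # law of total variance against the lambda grid
  bd <- population_distribution(p, receptor_distribution())
  g <- bd$lambda_grid
  el <- sum(g$p * g$lambda)
  vtot <- el + sum(g$p * (g$lambda - el)^2)
  expect_lt(abs(bd$sd^2 - vtot) / vtot, 1e-6)
  expect_lt(abs(bd$mean - el) / el, 1e-9)
  expect_equal(sum(bd$pmf$p), 1, tolerance = 1e-9)
  expect_error(population_distribution(p, receptor_distribution(), n_max = 20),
               "support")
})

test_that("intrinsic noise share shrinks with ligand concentration", {
  rd <- receptor_distribution()
  cvs <- vapply(c(0.03e-9, 0.3e-9, 3e-9), function(c0)
    population_distribution(kinetic_params("4C", egf0 = c0, t = 300), rd)$cv,
    numeric(1))
  expect_true(all(diff(cvs) < 0))
})

test_that("sampled cells agree with the analytic mixture", {
  p <- kinetic_params("4C", egf0 = 0.03e-9, t = 300)
  rd <- receptor_distribution()
  s1 <- sample_cells(p, rd, 1e5, seed = 11)
  s2 <- sample_cells(p, rd, 1e5, seed = 11)
  expect_identical(s1, s2)
  expect_identical(sample_cells(p, rd, 0, seed = 1), integer(0))
  bd <- population_distribution(p, rd)
  expect_lt(abs(sd(s1) / mean(s1) - bd$cv) / bd$cv, 0.02)
})

test_that("saturation binding isotherms normalize and refit exactly", {
  conc <- c(0.05, 0.2, 1, 3.1, 10, 40, 120) * 1e-9
  kd <- 3.1e-9; bmax <- 100
  p_true <- bmax * conc / (kd + conc)
  scalefac <- 250
  iso <- percent_max_bound(conc, I_tot = p_true * scalefac + 30,
                           I_ns = rep(30, 7))
  expect_equal(iso$P[7], 100)
  # a condition with no specific binding normalizes to zero percent
  iso0 <- percent_max_bound(conc, I_tot = c(30, p_true[-1] * scalefac + 30),
                            I_ns = rep(30, 7))
  expect_equal(iso0$P[1], 0)
  expect_error(percent_max_bound(conc, rep(30, 7), rep(30, 7)),
               "no specific binding")
  # half-maximum at c = K_D (relative to the Langmuir asymptote)
  fit <- fit_kd(iso)
  expect_lt(abs(fit$K_D - kd) / kd, 1e-6)
  p_at_kd <- fit$B_max * fit$K_D / (fit$K_D + fit$K_D)
  expect_equal(p_at_kd, fit$B_max / 2)
  # noisy recovery: 5% noise, 7 concentrations, seeded replicates
  errs <- vapply(1:30, function(s) {
    set.seed(400 + s)
    noisy <- iso
    noisy$P <- noisy$P * (1 + rnorm(7, 0, 0.05))
    abs(fit_kd(noisy)$K_D - kd) / kd
  }, numeric(1))
  expect_lt(median(errs), 0.15)
  expect_warning(fit_kd(data.frame(conc = c(1, 2, 3, 4) * 1e-12,
                                   P = c(0.03, 0.061, 0.092, 0.13))),
                 "concentration range")
})
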