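#' Extract a 3x3 intensity time trace at a spot centroid
#'
#' Sums the 3x3 pixel window centred at the rounded centroid in every frame
#' of a 2D movie, the raw material for blinking-based quantization.
#'
#' @param movie 3D array (`x` by `y` by frame).
#' @param centroid `(x, y)` spot centroid; rounded half-up to integer pixels.
#' @param exposure_ms exposure time carried with the trace (ms).
#' @return a `time_trace` object with fields `values`, `n_frames`,
#'   `exposure_ms`, `centroid`.
#' @export
extract_trace <- function(movie, centroid, exposure_ms = NA_real_) {
  x0 <- round_half_up(centroid[1]); y0 <- round_half_up(centroid[2])
  d <- dim(movie)
  if (x0 < 2 || y0 < 2 || x0 > d[1] - 1 || y0 > d[2] - 1)
    stop_bad_arg("3x3 window clipped by the frame border at (", x0, ", ", y0, ")")
  vals <- apply(movie[(x0 - 1):(x0 + 1), (y0 - 1):(y0 + 1), , drop = FALSE],
                3, sum)
  structure(list(values = as.numeric(vals), n_frames = d[3],
                 exposure_ms = exposure_ms, centroid = c(x0, y0)),
            class = "time_trace")
}

#' Bin a time trace into an intensity histogram
#'
#' @param trace a [extract_trace()] result or numeric vector.
#' @param n_bin number of equal-width bins (default 100).
#' @return a `trace_histogram` with `edges`, `mids`, `counts`, `n_bin`.
#' @export
trace_histogram <- function(trace, n_bin = 100) {
  v <- if (inherits(trace, "time_trace")) trace$values else as.numeric(trace)
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bin + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bin),
                     nbins = n_bin)
  structure(list(edges = edges, mids = (edges[-1] + edges[-(n_bin + 1)]) / 2,
                 counts = counts, n_bin = n_bin, n = length(v)),
            class = "trace_histogram")
}

# Skew-normal density (location xi, scale omega, shape alpha); alpha = 0
# reduces to the Gaussian. Mean is xi + omega * delta * sqrt(2/pi).
dskewnorm <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

skewnorm_mean <- function(xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  xi + omega * delta * sqrt(2 / pi)
}

# Model bin counts for a parameter vector. Components: first is the
# symmetric noise Gaussian; the rest are signal peaks, skew-normal when
# `skew` is TRUE (only used for the two-component single-emitter fit).
# par layout per component: mu, log_sigma, log_w [, alpha for skewed signal]
mixture_model_counts <- function(par, hist, n_comp, skew) {
  stride <- 3L
  mus <- par[seq(1, by = stride, length.out = n_comp)]
  sigmas <- exp(par[seq(2, by = stride, length.out = n_comp)])
  w <- exp(par[seq(3, by = stride, length.out = n_comp)])
  alpha <- if (skew) par[stride * n_comp + 1] else 0
  w <- w / sum(w)
  dens <- matrix(0, hist$n_bin, n_comp)
  bw <- diff(hist$edges[1:2])
  for (k in seq_len(n_comp)) {
    if (skew && k > 1) {
      dens[, k] <- dskewnorm(hist$mids, mus[k], sigmas[k], alpha) * bw
    } else {
      dens[, k] <- (stats::pnorm(hist$edges[-1], mus[k], sigmas[k]) -
                    stats::pnorm(hist$edges[-(hist$n_bin + 1)], mus[k], sigmas[k]))
    }
  }
  list(counts = hist$n * as.numeric(dens %*% w),
       per_comp = sweep(dens, 2, hist$n * w, `*`),
       mu = mus, sigma = sigmas, w = w, alpha = alpha)
}

#' Akaike information criterion for a histogram mixture fit
#'
#' `AIC = n_bin * ln(RSS / n_bin) + 2 (3 n_gauss - 1)`: the least-squares
#' log-likelihood term over histogram bins plus a penalty of three
#' parameters (mean, width, area) per component, with one area constrained
#' by the total.
#'
#' @param n_bin number of histogram bins.
#' @param rss residual sum of squares of the fit.
#' @param n_gauss number of mixture components (noise included).
#' @return AIC value.
#' @export
aic_mixture <- function(n_bin, rss, n_gauss) {
  if (!is.numeric(rss) || rss <= 0) stop_bad_arg("RSS must be positive")
  check_positive(n_bin, "n_bin"); check_positive(n_gauss, "n_gauss")
  n_bin * log(rss / n_bin) + 2 * (3 * n_gauss - 1)
}

# Evaluate the four acceptance criteria for a fitted mixture:
# (1) fit-data correlation >= 0.98
# (2) every component holds >= 8% of the total area
# (3) pairwise overlap coefficient of unit-normalized densities <= 75%
# (4) component area within 20% of the histogram mass on the bins where the
#     component has maximum responsibility
mixture_criteria <- function(mod, hist, corr_min = 0.98, area_min = 0.08,
                             overlap_max = 0.75, region_tol = 0.20) {
  corr <- suppressWarnings(stats::cor(mod$counts, hist$counts))
  if (!is.finite(corr)) corr <- 0
  c1 <- corr >= corr_min
  c2 <- all(mod$w >= area_min)
  n_comp <- length(mod$w)
  grid <- seq(min(hist$edges) - 3 * max(mod$sigma),
              max(hist$edges) + 3 * max(mod$sigma), length.out = 1024)
  gw <- diff(grid[1:2])
  dens <- vapply(seq_len(n_comp), function(k) {
    d <- if (mod$alpha != 0 && k > 1)
      dskewnorm(grid, mod$mu[k], mod$sigma[k], mod$alpha)
    else stats::dnorm(grid, mod$mu[k], mod$sigma[k])
    s <- sum(d * gw)
    if (!is.finite(s) || s <= 0) rep(NA_real_, length(grid)) else d / s
  }, numeric(length(grid)))
  c3 <- TRUE
  if (anyNA(dens)) {
    # a component degenerated below grid resolution: unresolvable overlap
    c3 <- FALSE
  } else if (n_comp > 1) {
    for (i in seq_len(n_comp - 1)) for (j in (i + 1):n_comp) {
      ov <- sum(pmin(dens[, i], dens[, j])) * gw
      if (ov > overlap_max) c3 <- FALSE
    }
  }
  resp <- max.col(mod$per_comp, ties.method = "first")
  c4 <- TRUE
  for (k in seq_len(n_comp)) {
    data_mass <- sum(hist$counts[resp == k])
    comp_mass <- hist$n * mod$w[k]
    if (data_mass == 0 ||
        abs(comp_mass - data_mass) / max(data_mass, comp_mass) > region_tol)
      c4 <- FALSE
  }
  list(pass = c(corr = c1, area = c2, overlap = c3, region = c4), corr = corr)
}

#' Least-squares Gaussian-mixture fit of a trace histogram
#'
#' Fits the binned intensity distribution of a blinking trace to a sum of
#' `n_gauss` components: one symmetric background (noise) Gaussian plus
#' `n_gauss - 1` signal peaks. For the two-component fit the signal peak is
#' a skew-normal (location/scale/shape); larger models use symmetric peaks.
#' Multiple seeded starts from quantile-spaced means are run and the
#' best-RSS solution kept; the four acceptance criteria (fit correlation,
#' minimum component area, maximum pairwise overlap, area-vs-data-region
#' agreement) are evaluated on the winner.
#'
#' @param hist a [trace_histogram()].
#' @param n_gauss number of components, 2 to 5.
#' @param seed integer seed for the multi-start jitter.
#' @param n_starts number of random starts (default 8).
#' @param skew_signal fit a skewed signal component (two-component fits
#'   only; default `n_gauss == 2`).
#' @return a `mixture_fit`: `components` data.frame (mu, sigma, area, skew),
#'   `rss`, `aic`, `corr`, `criteria_pass` (4 logicals), `n_gauss`,
#'   `converged`.
#' @export
fit_mixture <- function(hist, n_gauss, seed = 1L, n_starts = 8,
                        skew_signal = (n_gauss == 2)) {
  if (!(n_gauss %in% 2:5)) stop_bad_arg("n_gauss must be in 2..5")
  v_q <- hist$mids[rep(seq_len(hist$n_bin), pmax(hist$counts, 0))]
  if (length(v_q) < 10) stop_bad_arg("histogram is empty")
  rng <- range(hist$mids)
  span <- diff(rng)
  best <- NULL
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    qs <- seq(0.05, 0.95, length.out = n_gauss)
    mus <- stats::quantile(v_q, qs, names = FALSE) +
      stats::rnorm(n_gauss, 0, span / 30)
    sig <- rep(span / (6 * n_gauss), n_gauss) * stats::runif(n_gauss, 0.5, 2)
    par <- as.numeric(rbind(mus, log(sig), log(rep(1 / n_gauss, n_gauss))))
    if (skew_signal) par <- c(par, stats::rnorm(1, 0, 1))
    par
  }))
  resid_fn <- function(par) {
    mod <- mixture_model_counts(par, hist, n_gauss, skew_signal)
    hist$counts - mod$counts
  }
  for (par0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(components = NULL, rss = NA_real_, aic = NA_real_,
                          corr = NA_real_, criteria_pass = rep(FALSE, 4),
                          n_gauss = n_gauss, converged = FALSE),
                     class = "mixture_fit"))
  }
  mod <- mixture_model_counts(best$par, hist, n_gauss, skew_signal)
  ord <- order(mod$mu)
  crit <- mixture_criteria(mod, hist)
  comp <- data.frame(mu = mod$mu[ord], sigma = mod$sigma[ord],
                     area = mod$w[ord],
                     skew = ifelse(skew_signal & ord > 1, mod$alpha, 0))
  # report the mean of the skewed component, not its location parameter
  comp$mean <- ifelse(comp$skew != 0,
                      skewnorm_mean(comp$mu, comp$sigma, comp$skew), comp$mu)
  rss <- max(best$rss, .Machine$double.eps)
  structure(list(components = comp, rss = rss,
                 aic = aic_mixture(hist$n_bin, rss, n_gauss),
                 corr = crit$corr, criteria_pass = crit$pass,
                 n_gauss = n_gauss, converged = TRUE,
                 n_bin = hist$n_bin),
            class = "mixture_fit")
}

#' Count quantum dots in a blinking trace
#'
#' Fits the trace histogram with 2 to 5 mixture components; among fits
#' passing all four acceptance criteria, the minimum-AIC model wins and the
#' quantum-dot count is the number of components minus one (the background
#' noise component). Returns status `"unresolved"` if no model passes.
#'
#' @param trace a [extract_trace()] result or numeric vector.
#' @param seed integer seed.
#' @param n_bin histogram bins (default 100).
#' @param min_frames minimum trace length for fitting (default 100).
#' @return list with `n_qd` (NA when unresolved), `status`, `best_fit`,
#'   and `fits` (all candidate models).
#' @export
count_qds_in_trace <- function(trace, seed = 1L, n_bin = 100, min_frames = 100) {
  v <- if (inherits(trace, "time_trace")) trace$values else as.numeric(trace)
  if (length(v) < min_frames)
    stop_bad_arg("trace shorter than the configured floor of ", min_frames)
  h <- trace_histogram(v, n_bin)
  fits <- lapply(2:5, function(k)
    fit_mixture(h, k, seed = derive_seed(seed, paste0("mix", k)),
                skew_signal = FALSE))
  ok <- vapply(fits, function(f) f$converged && all(f$criteria_pass), logical(1))
  if (!any(ok))
    return(list(n_qd = NA_integer_, status = "unresolved",
                best_fit = NULL, fits = fits))
  aics <- vapply(fits, function(f) if (f$converged) f$aic else Inf, numeric(1))
  aics[!ok] <- Inf
  best <- which.min(aics) # ties break toward fewer components
  list(n_qd = (2:5)[best] - 1L, status = "ok",
       best_fit = fits[[best]], fits = fits)
}

#' Classify a trace as a single quantum dot
#'
#' Single emitters show a two-level trace: a background noise Gaussian plus
#' one skewed-Gaussian signal peak. A trace is accepted as single when the
#' two-component fit passes all four criteria, a criteria-passing
#' three-component model does not beat it under AIC, and the two components
#' are separated by at least the sum of their widths. The criteria are
#' deliberately stringent: rejecting true singles is preferred over
#' admitting multiplets into the calibration pool.
#'
#' @param trace a [extract_trace()] result or numeric vector.
#' @param seed integer seed.
#' @param n_bin histogram bins.
#' @param min_frames minimum trace length.
#' @return list with `is_single`, `fit` (the two-component model), and
#'   `reason` describing a rejection.
#' @export
classify_single_qd <- function(trace, seed = 1L, n_bin = 100, min_frames = 100) {
  v <- if (inherits(trace, "time_trace")) trace$values else as.numeric(trace)
  if (length(v) < min_frames)
    stop_bad_arg("trace shorter than the configured floor of ", min_frames)
  h <- trace_histogram(v, n_bin)
  f2 <- fit_mixture(h, 2, seed = derive_seed(seed, "single2"), skew_signal = TRUE)
  if (!f2$converged || !all(f2$criteria_pass))
    return(list(is_single = FALSE, fit = f2, reason = "two-component criteria failed"))
  sep <- diff(f2$components$mean) >= sum(f2$components$sigma)
  if (!sep)
    return(list(is_single = FALSE, fit = f2, reason = "levels not separated"))
  f3 <- fit_mixture(h, 3, seed = derive_seed(seed, "single3"), skew_signal = FALSE)
  if (f3$converged && all(f3$criteria_pass) && f3$aic < f2$aic)
    return(list(is_single = FALSE, fit = f2, reason = "three-component model preferred"))
  list(is_single = TRUE, fit = f2, reason = "")
}

#' Single-emitter intensity from a two-component fit
#'
#' The intrinsic single-emitter brightness is the separation between the
#' signal and background levels, corrected for detector quantum efficiency:
#' `(mu2 - mu1) / Phi`.
#'
#' @param fit a two-component [fit_mixture()] result accepted by
#'   [classify_single_qd()].
#' @param quantum_efficiency detector quantum efficiency `Phi` in (0, 1].
#' @return intensity in photon-equivalent counts.
#' @export
single_emitter_intensity <- function(fit, quantum_efficiency = 1) {
  if (quantum_efficiency <= 0 || quantum_efficiency > 1)
    stop_bad_arg("quantum_efficiency must lie in (0, 1]")
  if (is.null(fit$components) || nrow(fit$components) < 2)
    stop_bad_arg("fit must have a background and a signal component")
  (fit$components$mean[2] - fit$components$mean[1]) / quantum_efficiency
}
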