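# Shared synthetic-scene builders for the test suite. All fixtures are
# generated in code from fixed seeds; nothing is loaded from disk.

always_on <- list(k_on = 0, k_off = 0, p_on = 1)

test_optics <- function(...) optics_config(...)

# One emitter centred in a 9x9 field; returns its 3x3 blinking time trace.
make_qd_trace <- function(n_qd, seed, n_frames = 4000, brightness = 500,
                          background = 50) {
  sc <- scene(list(emitter(c(5, 5), n_qd = n_qd,
                           brightness_per_qd = brightness)),
              dims = c(9, 9), autofluorescence = background, seed = seed)
  r <- render_timeseries(sc, test_optics(), n_frames)
  list(trace = extract_trace(r$movie, c(5, 5)), states = r$truth$states[[1]])
}

# n points uniformly distributed on a sphere.
sphere_points <- function(n, radius = 20, center = c(30, 30, 30), seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  sweep(v * radius, 2, center, `+`)
}

# Well-separated single-QD emitters on a jittered grid inside `dims`;
# `margin` is the clearance kept to the field border.
grid_emitters <- function(n, dims, margin = 8, n_qd = 1L, brightness = 2000,
                          z_range = NULL, jitter = 2, seed = 1) {
  set.seed(seed)
  k <- ceiling(sqrt(n))
  g <- expand.grid(x = seq(margin, dims[1] - margin, length.out = k),
                   y = seq(margin, dims[2] - margin, length.out = k))
  stopifnot(nrow(g) >= n)
  g <- g[seq_len(n), ]
  lapply(seq_len(n), function(i) {
    pos <- c(g$x[i] + stats::runif(1, -jitter, jitter),
             g$y[i] + stats::runif(1, -jitter, jitter))
    if (!is.null(z_range)) pos <- c(pos, stats::runif(1, z_range[1], z_range[2]))
    emitter(pos, n_qd = if (length(n_qd) > 1) n_qd[i] else n_qd,
            brightness_per_qd = brightness)
  })
}
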