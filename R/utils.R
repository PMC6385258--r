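#' @keywords internal
"_PACKAGE"

# Matlab-style rounding: halves always move away from zero toward +Inf here
# (all image coordinates are positive), unlike base round()'s banker rounding.
round_half_up <- function(x) floor(x + 0.5)

#' Derive a stage seed from a master seed
#'
#' All stochastic stages draw their RNG state from one master seed plus a
#' stage label, so that a single integer reproduces an entire run while
#' stages remain statistically independent of one another.
#'
#' @param seed master integer seed.
#' @param key character stage label (or integer offset).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key = "") {
  h <- 0
  for (ch in utf8ToInt(paste0(key))) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Evaluate expr under a temporary RNG state; global .Random.seed restored.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_bad_arg(name, " must be a probability in [0, 1]")
  invisible(p)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && (if (strict) all(x > 0) else all(x >= 0))
  if (!ok) stop_bad_arg(name, " must be ", if (strict) "strictly positive" else "non-negative",
                        " and finite")
  invisible(x)
}

# 2D "same" convolution (correlation with the flipped kernel) via FFT with
# zero padding; x is a matrix, k a small odd-sized kernel matrix.
conv2_same <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  nr <- dx[1] + dk[1] - 1L
  nc <- dx[2] + dk[2] - 1L
  xp <- matrix(0, nr, nc); xp[seq_len(dx[1]), seq_len(dx[2])] <- x
  kp <- matrix(0, nr, nc); kp[seq_len(dk[1]), seq_len(dk[2])] <- k
  full <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / (nr * nc)
  r0 <- (dk[1] - 1L) %/% 2L
  c0 <- (dk[2] - 1L) %/% 2L
  full[r0 + seq_len(dx[1]), c0 + seq_len(dx[2]), drop = FALSE]
}

# Circular 3D convolution of equally sized arrays via FFT.
conv3_circular <- function(x, otf) {
  Re(fft(fft(x) * otf, inverse = TRUE)) / length(x)
}

# Reflective padding of a 3D array by (px, py, pz) voxels on each side.
pad_reflect3 <- function(a, p) {
  d <- dim(a)
  ref <- function(n, pad) {
    i <- c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
    pmin(pmax(i, 1L), n)
  }
  a[ref(d[1], p[1]), ref(d[2], p[2]), ref(d[3], p[3]), drop = FALSE]
}
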