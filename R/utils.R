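# Internal helpers shared across the simulator and the reconstruction chain.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic sub-seed derived from a (seed, index) pair; stays < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647)
}

# FFT frequencies in cycles per sample, matching the ordering of stats::fft.
fft_freq <- function(n) {
  # ordering 0, 1, ..., ceil(n/2)-1, -floor(n/2), ..., -1 (fractions of n)
  c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L) / n
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT along the third dimension of a 3D array, returned as a matrix with one
# column per lateral pixel (rows index the transform axis).
fft_along_k <- function(arr) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(3, 1, 2)), nrow = d[3])
  stats::mvfft(m)
}

# Complex circular Gaussian field, unit variance per pixel (E|z|^2 = 1).
complex_gaussian <- function(nx, ny) {
  matrix(complex(
    real = stats::rnorm(nx * ny, sd = sqrt(0.5)),
    imaginary = stats::rnorm(nx * ny, sd = sqrt(0.5))
  ), nx, ny)
}

wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # convention (-pi, pi]: map -pi to +pi
  out[out == -pi] <- pi
  out
}

# 2D median filter with replicate padding (odd square window).
median_filter2 <- function(x, size = 9L) {
  stopifnot(size %% 2 == 1)
  h <- (size - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr + 2 * h) - h, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * h) - h, 1L), nc)
  xp <- x[ri, ci, drop = FALSE]
  n <- nr * nc
  stack <- matrix(0, n, size * size)
  col <- 0L
  for (dc in 0:(size - 1L)) {
    for (dr in 0:(size - 1L)) {
      col <- col + 1L
      stack[, col] <- xp[dr + seq_len(nr), dc + seq_len(nc)]
    }
  }
  matrix(apply(stack, 1L, stats::median), nr, nc)
}

# Full width at half maximum of a sampled 1D profile, by linear interpolation
# of the half-maximum crossings around the (parabolically refined) peak.
profile_fwhm <- function(y, x = seq_along(y)) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(i0, 2L)) {
    if (y[i - 1] <= half) {
      left <- x[i - 1] + (x[i] - x[i - 1]) * (half - y[i - 1]) / (y[i] - y[i - 1])
      break
    }
  }
  for (i in seq(i0, length(y) - 1L)) {
    if (y[i + 1] <= half) {
      right <- x[i] + (x[i + 1] - x[i]) * (half - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("profile does not fall below half maximum on both sides", call. = FALSE)
  }
  right - left
}

# Standardized fourth central moment (kurtosis, non-excess) of a numeric vector.
kurtosis <- function(x) {
  x <- as.numeric(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) return(NaN)
  mean((x - m)^4) / v^2
}

shannon_entropy <- function(intensity) {
  s <- sum(intensity)
  if (s <= 0) stop("zero-energy image", call. = FALSE)
  p <- intensity / s
  p <- p[p > 0]
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
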