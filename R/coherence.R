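#' Linearize a 2D detector grid into a single pixel index
#'
#' Maps pixel \eqn{(x_n, y_m)} to \eqn{\chi_j = n + mN} (0-based), the
#' enumeration used to arrange the coherence matrix, together with its
#' inverse.
#'
#' @param nx,ny Grid dimensions (N columns of x, M of y).
#' @return An object of class `"pixel_linearization"` with functions
#'   `forward(n, m)` and `inverse(chi)` plus `K = nx * ny`.
#' @examples
#' lin <- linearize(4, 4)
#' lin$forward(2, 1)   # 6
#' lin$inverse(6)      # c(2, 1)
#' @export
linearize <- function(nx, ny) {
  stopifnot(nx >= 1, ny >= 1)
  forward <- function(n, m) {
    stopifnot(all(n >= 0 & n < nx), all(m >= 0 & m < ny))
    n + m * nx
  }
  inverse <- function(chi) {
    stopifnot(all(chi >= 0 & chi < nx * ny))
    cbind(n = chi %% nx, m = chi %/% nx)
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 K = as.integer(nx * ny), forward = forward, inverse = inverse),
            class = "pixel_linearization")
}

#' Build the scattering coherence matrix G
#'
#' For an ensemble of complex field frames (one per mask realization,
#' standing in for the time ensemble of a stationary, ergodic field), the
#' mutual coherence between linearized pixels j and k is
#' \deqn{\gamma_{jk} = \sum_t E_j^*(t) E_k(t) \Big/
#'   \sqrt{\sum_t |E_j(t)|^2 \sum_t |E_k(t)|^2},}
#' a K x K Hermitian matrix with unit diagonal for pixels carrying energy.
#' Pixels with zero energy are flagged in `masked` and their rows/columns set
#' to zero (data masking, not genuine loss of coherence).
#'
#' @param fields Either a 3D complex array (nx, ny, T) or a list of complex
#'   matrices; T >= 2 ensemble members (>= 8 recommended).
#' @param roi Optional region of interest: a list with integer vectors `x`
#'   and `y` (1-based pixel indices); default is the full frame. The ROI size
#'   K = |x| * |y| must not exceed `max_K`.
#' @param tau Ensemble lag; only `tau = 0` is analyzed (accepted and recorded
#'   for provenance).
#' @param max_K Guard against accidental full-frame matrices (default 4096).
#' @return An object of class `"coherence_matrix"`: `gamma` (K x K complex),
#'   `masked` (logical K), `roi`, `tau`, `linearization`.
#' @export
build_G <- function(fields, roi = NULL, tau = 0, max_K = 4096) {
  if (is.list(fields)) {
    fields <- array(unlist(fields), dim = c(dim(fields[[1]]), length(fields)))
  }
  d <- dim(fields)
  if (length(d) != 3 || d[3] < 2) {
    stop("need an ensemble of at least 2 field frames", call. = FALSE)
  }
  x <- roi$x %||% seq_len(d[1])
  y <- roi$y %||% seq_len(d[2])
  if (!length(x) || !length(y)) stop("empty roi", call. = FALSE)
  K <- length(x) * length(y)
  if (K > max_K) {
    stop(sprintf("ROI gives K = %d > max_K = %d; restrict the ROI", K, max_K),
         call. = FALSE)
  }
  Tn <- d[3]
  # E: T x K, rows = ensemble members, columns = linearized ROI pixels
  E <- matrix(aperm(fields[x, y, , drop = FALSE], c(3, 1, 2)), nrow = Tn)
  if (tau != 0) {
    # lagged ensemble product <E*(t) E(t+tau)>; wraps are dropped
    keep <- seq_len(Tn - abs(tau))
    E1 <- E[keep, , drop = FALSE]
    E2 <- E[keep + abs(tau), , drop = FALSE]
    G <- t(Conj(E1)) %*% E2
  } else {
    G <- t(Conj(E)) %*% E
  }
  energy <- Re(diag(t(Conj(E)) %*% E))
  masked <- energy <= 0
  norm <- sqrt(energy)
  norm[masked] <- 1
  gamma <- G / outer(norm, norm)
  gamma[masked, ] <- 0
  gamma[, masked] <- 0
  structure(list(gamma = gamma, masked = masked,
                 roi = list(x = x, y = y), tau = tau,
                 linearization = linearize(length(x), length(y))),
            class = "coherence_matrix")
}

#' @export
print.coherence_matrix <- function(x, ...) {
  cat(sprintf("<coherence_matrix> K=%d (masked %d), tau=%g, diagonality=%.3g\n",
              nrow(x$gamma), sum(x$masked), x$tau,
              tryCatch(diagonality(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Diagonal dominance of a coherence matrix
#'
#' Mean on-diagonal magnitude divided by mean off-diagonal magnitude over
#' unmasked pixels. A perfectly diagonal matrix returns `Inf`; a uniform
#' matrix returns 1. Larger values indicate stronger crosstalk suppression.
#'
#' @param G A [build_G()] result.
#' @return Scalar in `[0, Inf]`.
#' @export
diagonality <- function(G) {
  stopifnot(inherits(G, "coherence_matrix"))
  ok <- !G$masked
  if (!any(ok)) stop("all pixels are masked", call. = FALSE)
  g <- Mod(G$gamma[ok, ok, drop = FALSE])
  K <- nrow(g)
  if (K < 2) stop("need K >= 2 unmasked pixels", call. = FALSE)
  diag_mean <- mean(diag(g))
  off_mean <- (sum(g) - sum(diag(g))) / (K^2 - K)
  if (off_mean == 0) Inf else diag_mean / off_mean
}

#' Fit modified-Rician statistics to normalized intensities
#'
#' The intensity of a deterministic field of strength \eqn{I_d} superposed
#' with circular Gaussian crosstalk noise of variance \eqn{\sigma_n^2}
#' follows the non-central exponential (modified Rician) law
#' \deqn{p(I) = \frac{1}{\sigma^2}
#'   \exp\!\left(-\frac{I + I_d}{\sigma^2}\right)
#'   I_0\!\left(\frac{2\sqrt{I I_d}}{\sigma^2}\right),}
#' which reduces to the fully developed speckle (exponential) law as
#' \eqn{I_d \to 0}. Parameters are estimated by maximum likelihood with a
#' moment-based start.
#'
#' @param intensities Numeric vector of normalized intensities
#'   \eqn{I/\langle I \rangle}, all >= 0, length >= 200.
#' @param roi Optional annotation describing where the samples came from.
#' @return An object of class `"rician_fit"`: `i_det`, `sigma_n2`, `loglik`,
#'   `n_samples`, `converged`.
#' @examples
#' set.seed(1)
#' x <- Mod(complex(real = stats::rnorm(500, sd = sqrt(.05)) + sqrt(.9),
#'                  imaginary = stats::rnorm(500, sd = sqrt(.05))))^2
#' fit_rician(x)
#' @export
fit_rician <- function(intensities, roi = NULL) {
  I <- as.numeric(intensities)
  if (length(I) < 200) stop("need at least 200 samples", call. = FALSE)
  if (any(I < 0)) stop("negative intensities", call. = FALSE)
  m1 <- mean(I); v <- stats::var(I)
  disc <- m1^2 - v
  sigma2_0 <- if (disc > 0) m1 - sqrt(disc) else m1
  id_0 <- max(m1 - sigma2_0, 1e-6)
  nll <- function(par) {
    id <- par[1]^2
    s2 <- exp(par[2])
    z <- 2 * sqrt(I * id) / s2
    # log I0(z) via the exponentially scaled Bessel function; fall back to
    # the large-argument asymptote where the scaled value underflows
    bs <- besselI(z, 0, expon.scaled = TRUE)
    logI0 <- ifelse(bs > 0, z + log(bs), z - 0.5 * log(2 * pi * pmax(z, 1)))
    v <- -sum(-log(s2) - (I + id) / s2 + logI0)
    if (!is.finite(v)) .Machine$double.xmax / 2 else v
  }
  fit <- stats::optim(c(sqrt(id_0), log(sigma2_0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(i_det = fit$par[1]^2, sigma_n2 = exp(fit$par[2]),
                 loglik = -fit$value, n_samples = length(I),
                 converged = fit$convergence == 0, roi = roi),
            class = "rician_fit")
}

#' @export
print.rician_fit <- function(x, ...) {
  cat(sprintf("<rician_fit> I_d=%.4g sigma_n2=%.4g loglik=%.4g n=%d%s\n",
              x$i_det, x$sigma_n2, x$loglik, x$n_samples,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
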