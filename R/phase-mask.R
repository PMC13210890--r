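#' Generate one realization of a spatial phase mask
#'
#' Produces the phase pattern \eqn{\Delta\varphi(x, y)} that a spatial-phase
#' modulator imposes on the illumination cross-section. Four kinds are
#' supported, mirroring the hardware families used for spatio-temporal
#' coherence manipulation:
#'
#' * `"slm"` — piecewise-constant random tiles (tile edge =
#'   `correlation_length` px), phase uniform on \eqn{(-\pi, \pi]}, as a
#'   liquid-crystal spatial light modulator displays;
#' * `"membrane"` — a smooth random surface: Gaussian white noise low-pass
#'   filtered to `correlation_length`, rescaled so the peak-to-valley
#'   excursion is at least \eqn{2\pi}, then wrapped;
#' * `"fiber_modes"` — a random superposition of `n_modes` speckle-like
#'   patterns with i.i.d. uniform modal phases, the passive multimode-fiber
#'   mechanism; the emerging phase is the argument of the summed field;
#' * `"flat"` — zeros (coherent illumination; the no-modulation control).
#'
#' Masks generated with different seeds are uncorrelated: the ensemble
#' correlation \eqn{|\langle e^{i\Delta\varphi_1} e^{-i\Delta\varphi_2}
#' \rangle|} over the pixel population is small (see
#' [mask_correlation()]).
#'
#' @param config An [optical_config()] fixing the grid.
#' @param kind One of `"slm"`, `"membrane"`, `"fiber_modes"`, `"flat"`.
#' @param seed Integer; fixed seed gives a bit-identical mask.
#' @param correlation_length Spatial correlation scale in pixels (>= 1, and at
#'   most `min(nx, ny)`).
#' @param n_modes For `"fiber_modes"`: number of independent guided modes
#'   superposed (see [guided_mode_count()] for the physical value).
#' @return An object of class `"phase_mask"` with fields `phase` (nx x ny,
#'   wrapped to \eqn{(-\pi, \pi]}), `kind`, `seed`, `correlation_length`.
#' @examples
#' cfg <- optical_config(nx = 32, ny = 32, n_k = 16)
#' m1 <- generate_phase_mask(cfg, "slm", seed = 0, correlation_length = 2)
#' m2 <- generate_phase_mask(cfg, "slm", seed = 1, correlation_length = 2)
#' mask_correlation(m1, m2) # small for uncorrelated masks
#' @export
generate_phase_mask <- function(config, kind = c("slm", "membrane",
                                                 "fiber_modes", "flat"),
                                seed = 0, correlation_length = 4,
                                n_modes = 256) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "optical_config"))
  nx <- config$nx; ny <- config$ny
  if (correlation_length < 1) stop("correlation_length must be >= 1 px", call. = FALSE)
  if (correlation_length > min(nx, ny)) {
    stop("correlation_length exceeds the detector grid", call. = FALSE)
  }
  phase <- switch(kind,
    flat = matrix(0, nx, ny),
    slm = with_seed(seed, {
      tx <- ceiling(nx / correlation_length)
      ty <- ceiling(ny / correlation_length)
      tiles <- matrix(stats::runif(tx * ty, -pi, pi), tx, ty)
      ix <- ceiling(seq_len(nx) / correlation_length)
      iy <- ceiling(seq_len(ny) / correlation_length)
      tiles[ix, iy, drop = FALSE]
    }),
    membrane = with_seed(seed, {
      g <- matrix(stats::rnorm(nx * ny), nx, ny)
      fx <- fft_freq(nx); fy <- fft_freq(ny)
      f2 <- outer(fx^2, fy^2, "+")
      sigma_f <- 1 / (2 * pi * correlation_length)
      h <- exp(-f2 / (2 * sigma_f^2))
      s <- Re(ifft2(fft2(g) * h))
      ptv <- max(s) - min(s)
      s <- s * (4 * pi / ptv)               # peak-to-valley 4*pi >= 2*pi
      wrap_phase(s - mean(s))
    }),
    fiber_modes = with_seed(seed, {
      # superpose n_modes random speckle patterns with uniform modal phases;
      # each mode is a smooth random complex field at the mask correlation scale
      fx <- fft_freq(nx); fy <- fft_freq(ny)
      f2 <- outer(fx^2, fy^2, "+")
      sigma_f <- 1 / (2 * pi * correlation_length)
      h <- exp(-f2 / (2 * sigma_f^2))
      total <- matrix(0 + 0i, nx, ny)
      for (m in seq_len(n_modes)) {
        mode <- ifft2(fft2(complex_gaussian(nx, ny)) * h)
        total <- total + mode * exp(1i * stats::runif(1, -pi, pi))
      }
      wrap_phase(Arg(total))
    })
  )
  structure(list(phase = phase, kind = kind, seed = as.integer(seed),
                 correlation_length = correlation_length,
                 n_modes = if (kind == "fiber_modes") as.integer(n_modes) else NA_integer_),
            class = "phase_mask")
}

#' Ensemble correlation between two phase masks
#'
#' Computes \eqn{|\langle e^{i\Delta\varphi_1} e^{-i\Delta\varphi_2}\rangle|}
#' over the pixel population by direct summation. Identical masks give 1;
#' uncorrelated masks give values near \eqn{1/\sqrt{n_{px}}}.
#'
#' @param mask1,mask2 Two [generate_phase_mask()] results on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
mask_correlation <- function(mask1, mask2) {
  stopifnot(inherits(mask1, "phase_mask"), inherits(mask2, "phase_mask"))
  if (!all(dim(mask1$phase) == dim(mask2$phase))) {
    stop("masks are on different grids", call. = FALSE)
  }
  Mod(mean(exp(1i * (mask1$phase - mask2$phase))))
}

#' A list of uncorrelated phase masks
#'
#' Convenience wrapper generating `n` masks with consecutive derived seeds.
#'
#' @inheritParams generate_phase_mask
#' @param n Number of masks.
#' @param base_seed Seed for the first mask; mask `i` uses a seed derived
#'   deterministically from `(base_seed, i)`.
#' @return List of `phase_mask` objects.
#' @export
phase_mask_ensemble <- function(config, n, kind = "slm", base_seed = 0,
                                correlation_length = 4, n_modes = 256) {
  lapply(seq_len(n), function(i) {
    generate_phase_mask(config, kind, seed = derive_seed(base_seed, i),
                        correlation_length = correlation_length,
                        n_modes = n_modes)
  })
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("<phase_mask> kind=%s seed=%d corr=%g px (%dx%d)\n",
              x$kind, x$seed, x$correlation_length,
              nrow(x$phase), ncol(x$phase)))
  invisible(x)
}
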