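#' Optical system configuration for a swept-source full-field acquisition
#'
#' Bundles the source sweep, detector geometry, and interferometer parameters
#' used throughout the simulator. The spectral axis is sampled uniformly in
#' wavelength between `lambda_start` and `lambda_end`, as swept lasers tune;
#' the corresponding wavenumber axis \eqn{k_l = 2\pi/\lambda_l} (1/µm) is
#' therefore slightly nonuniform and is resampled to uniform k during
#' reconstruction when needed.
#'
#' @param lambda_start,lambda_end Sweep band edges (nm); `lambda_end` must
#'   exceed `lambda_start`.
#' @param n_k Number of spectral frames recorded across the sweep.
#' @param sweep_rate Source tuning speed (nm/s).
#' @param idle_time Dead time between successive volume sweeps (ms).
#' @param frame_rate Camera frame rate (Hz).
#' @param nx,ny Detector pixel counts.
#' @param pixel_pitch_obj Object-space sampling (µm per pixel).
#' @param na_ill,na_det Illumination and detection numerical apertures;
#'   `0 < na_ill <= na_det < 1`.
#' @param ref_amplitude Reference arm field amplitude (arbitrary units).
#' @param bit_depth Camera quantization depth (bits).
#'
#' @return An object of class `"optical_config"`.
#' @examples
#' cfg <- optical_config(nx = 32, ny = 32, n_k = 64)
#' range(k_axis(cfg))
#' @export
optical_config <- function(lambda_start = 800, lambda_end = 875, n_k = 128,
                           sweep_rate = 8700, idle_time = 0.3,
                           frame_rate = 60000, nx = 128, ny = 128,
                           pixel_pitch_obj = 1.8, na_ill = 0.1, na_det = 0.25,
                           ref_amplitude = 1, bit_depth = 12) {
  if (!(lambda_end > lambda_start && lambda_start > 0)) {
    stop("require lambda_end > lambda_start > 0", call. = FALSE)
  }
  if (n_k < 2) stop("n_k must be >= 2", call. = FALSE)
  if (nx < 8 || ny < 8) stop("nx and ny must be >= 8", call. = FALSE)
  if (!(na_ill > 0 && na_ill <= na_det && na_det < 1)) {
    stop("require 0 < na_ill <= na_det < 1", call. = FALSE)
  }
  if (sweep_rate <= 0) stop("sweep_rate must be positive", call. = FALSE)
  structure(list(
    lambda_start = lambda_start, lambda_end = lambda_end, n_k = as.integer(n_k),
    sweep_rate = sweep_rate, idle_time = idle_time, frame_rate = frame_rate,
    nx = as.integer(nx), ny = as.integer(ny), pixel_pitch_obj = pixel_pitch_obj,
    na_ill = na_ill, na_det = na_det, ref_amplitude = ref_amplitude,
    bit_depth = as.integer(bit_depth)
  ), class = "optical_config")
}

#' Wavenumber axis of a configuration
#'
#' Wavelengths are sampled uniformly across the sweep band and converted to
#' wavenumbers \eqn{k = 2\pi/\lambda} in 1/µm. Because the sweep runs from
#' short to long wavelength the axis is strictly decreasing.
#'
#' @param config An [optical_config()].
#' @return Numeric vector of length `n_k` (1/µm), strictly monotonic.
#' @export
k_axis <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  lambda_nm <- seq(config$lambda_start, config$lambda_end, length.out = config$n_k)
  2 * pi / (lambda_nm / 1000)
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> %g-%g nm in %d frames | %dx%d px @ %g um | NA_ill %g, NA_det %g\n",
    x$lambda_start, x$lambda_end, x$n_k, x$nx, x$ny, x$pixel_pitch_obj,
    x$na_ill, x$na_det
  ))
  invisible(x)
}
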