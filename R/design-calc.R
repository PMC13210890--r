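#' Multimode fiber specification
#'
#' Parameters of the long multimode fiber used as a passive spatial-phase
#' modulator: core radius `a` (µm), numerical aperture, length (m), core
#' index, operating wavelength (nm), and source coherence length (mm).
#'
#' @param core_radius Core radius a (µm).
#' @param na Fiber numerical aperture.
#' @param length Fiber length (m), optional.
#' @param core_index Core refractive index n1, optional (needed for
#'   [min_fiber_length()]).
#' @param wavelength Operating wavelength (nm).
#' @param coherence_length Source coherence length (mm), optional (needed for
#'   [min_fiber_length()]).
#' @return An object of class `"fiber_spec"`.
#' @export
fiber_spec <- function(core_radius = 25, na = 0.22, length = NA_real_,
                       core_index = NA_real_, wavelength = 840,
                       coherence_length = NA_real_) {
  if (core_radius <= 0 || na <= 0 || wavelength <= 0) {
    stop("core_radius, na and wavelength must be positive", call. = FALSE)
  }
  if (!is.na(core_index) && na >= core_index) {
    stop("na must be smaller than the core index", call. = FALSE)
  }
  structure(list(core_radius = core_radius, na = na, length = length,
                 core_index = core_index, wavelength = wavelength,
                 coherence_length = coherence_length),
            class = "fiber_spec")
}

#' Number of guided modes of a step-index multimode fiber
#'
#' Closed form \eqn{N \approx 2\pi^2 a^2 NA^2 / \lambda^2}. For the reference
#' fiber (a = 25 µm, NA = 0.22, λ = 840 nm) this evaluates to about 846
#' guided transverse modes.
#'
#' @param fiber A [fiber_spec()].
#' @return List with `n` (real-valued count) and `n_int` (nearest integer).
#' @examples
#' guided_mode_count(fiber_spec())
#' @export
guided_mode_count <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  lambda_um <- fiber$wavelength / 1000
  n <- 2 * pi^2 * fiber$core_radius^2 * fiber$na^2 / lambda_um^2
  list(n = n, n_int = as.integer(round(n)))
}

#' Crosstalk attenuation from mode averaging
#'
#' Averaging over N uncorrelated spatial modes attenuates crosstalk noise by
#' \eqn{\sqrt N}; with the reference fiber's ~846 modes this is a factor of
#' about 29.
#'
#' @param n_modes Number of independent modes (>= 1).
#' @return \eqn{\sqrt{N}}.
#' @export
crosstalk_attenuation_factor <- function(n_modes) {
  if (any(n_modes < 1)) stop("n_modes must be >= 1", call. = FALSE)
  sqrt(n_modes)
}

#' Depth of field of the illumination
#'
#' Proportionality \eqn{DOF \sim \lambda / NA_{ill}^2}; the prefactor is
#' convention-dependent and defaults to 1.
#'
#' @param lambda Wavelength (nm).
#' @param na_ill Illumination numerical aperture.
#' @param prefactor Dimensionless prefactor (default 1).
#' @return Depth of field (µm).
#' @export
depth_of_field <- function(lambda, na_ill, prefactor = 1) {
  if (na_ill <= 0) stop("na_ill must be positive", call. = FALSE)
  prefactor * (lambda / 1000) / na_ill^2
}

#' Minimum fiber length for modal decorrelation
#'
#' \eqn{L_{min} = 4 l_c \pi^2 a^2 n_1 / \lambda^2}: the length at which
#' intermodal group delay exceeds the source coherence length so that guided
#' modes stop interfering. Degenerate modes share propagation constants, so
#' practical fibers are made several times longer than this bound.
#'
#' @param fiber A [fiber_spec()] with `coherence_length` and `core_index`
#'   set.
#' @return Minimum length (m).
#' @export
min_fiber_length <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (is.na(fiber$coherence_length) || is.na(fiber$core_index)) {
    stop("coherence_length and core_index are required", call. = FALSE)
  }
  lc_um <- fiber$coherence_length * 1000       # mm -> um
  lambda_um <- fiber$wavelength / 1000
  l_um <- 4 * lc_um * pi^2 * fiber$core_radius^2 * fiber$core_index / lambda_um^2
  l_um / 1e6                                    # um -> m
}

#' Sweep timing and dataset sizing
#'
#' Per-volume sweep duration, total duration for `n_volumes` including the
#' inter-volume idle time, and raw dataset size. Sizing uses decimal GB
#' (1e9 bytes) and a 16-bit container for 12-bit camera samples
#' (`bytes_per_voxel = 2`).
#'
#' @param config An [optical_config()].
#' @param n_volumes Number of recorded volumes.
#' @param bytes_per_voxel Stored bytes per voxel (default 2).
#' @return List: `per_volume_ms`, `total_ms`, `data_gb`.
#' @examples
#' sweep_timing(optical_config(nx = 512, ny = 512, n_k = 512), 32)
#' @export
sweep_timing <- function(config, n_volumes = 1, bytes_per_voxel = 2) {
  stopifnot(inherits(config, "optical_config"))
  per_volume_ms <- (config$lambda_end - config$lambda_start) / config$sweep_rate * 1000
  total_ms <- if (n_volumes > 0) {
    n_volumes * per_volume_ms + (n_volumes - 1) * config$idle_time
  } else 0
  data_gb <- n_volumes * as.numeric(config$nx) * config$ny * config$n_k *
    bytes_per_voxel / 1e9
  list(per_volume_ms = per_volume_ms, total_ms = total_ms, data_gb = data_gb)
}
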