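# Depth-profile analysis helpers shared by the pipeline, the examples, and
# the validation suite.

#' Mean magnitude depth profile of a reconstruction
#'
#' Averages |A-scan| laterally at every depth, the standard summary used to
#' check Beer-Lambert attenuation recovery.
#'
#' @param volume A [recon_volume()].
#' @return Data frame with columns `z` (µm) and `amplitude`.
#' @export
depth_profile <- function(volume) {
  stopifnot(inherits(volume, "recon_volume"))
  amp <- apply(Mod(volume$data), 3, mean)
  data.frame(z = volume$z_axis, amplitude = amp)
}

#' En-face plane nearest a requested depth
#'
#' @param volume A [recon_volume()].
#' @param z Depth (µm).
#' @return Complex matrix (nx x ny).
#' @export
enface <- function(volume, z) {
  stopifnot(inherits(volume, "recon_volume"))
  volume$data[, , which.min(abs(volume$z_axis - z))]
}

#' Fit single-exponential attenuation to a depth profile
#'
#' Linear regression of log mean amplitude against depth over the sampled
#' layer depths; under the ballistic model the amplitude decays as
#' \eqn{\exp(-2\mu z)}, so the fitted slope is \eqn{-2\hat\mu}.
#'
#' @param volume A [recon_volume()].
#' @param depths Depths (µm) at which reflecting layers sit; the nearest
#'   depth bin of each is sampled.
#' @return List: `mu` (1/µm), `slope`, `r_squared`, `profile` (data frame of
#'   the sampled points).
#' @export
fit_attenuation <- function(volume, depths) {
  stopifnot(inherits(volume, "recon_volume"), length(depths) >= 3)
  bins <- vapply(depths, function(z) which.min(abs(volume$z_axis - z)), integer(1))
  amp <- vapply(bins, function(b) mean(Mod(volume$data[, , b])), numeric(1))
  if (any(amp <= 0)) stop("zero amplitude at a sampled depth", call. = FALSE)
  z <- volume$z_axis[bins]
  fit <- stats::lm(log(amp) ~ z)
  list(mu = -unname(stats::coef(fit)[2]) / 2,
       slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       profile = data.frame(z = z, amplitude = amp))
}
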