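#' Average interferogram stacks over a mask ensemble
#'
#' Elementwise arithmetic mean of intensity stacks recorded under distinct
#' phase masks. Crosstalk interference terms carry mask-dependent random
#' phases and average toward zero, while the ballistic fringe is
#' mask-invariant and survives; this is the core STOC filtering step.
#'
#' @param stacks Non-empty list of [spectral_stack()] objects sharing grid
#'   and wavenumber axis.
#' @return A single [spectral_stack()] with `mask_id = "integrated"`.
#' @export
average_stacks <- function(stacks) {
  if (!length(stacks)) stop("empty stack list", call. = FALSE)
  ref <- stacks[[1]]
  for (s in stacks) {
    if (!isTRUE(all.equal(s$k_axis, ref$k_axis, tolerance = 1e-12))) {
      stop("stacks have mismatched k_axis", call. = FALSE)
    }
    if (!all(dim(s$data) == dim(ref$data))) {
      stop("stacks have mismatched grids", call. = FALSE)
    }
  }
  out <- ref
  out$data <- Reduce(`+`, lapply(stacks, function(s) s$data)) / length(stacks)
  out$mask_id <- "integrated"
  out            # built from validated inputs; DC-removed stacks may be signed
}

#' Remove the DC component of the spectral fringe
#'
#' Per pixel, along the wavenumber axis: `"mean_subtract"` removes the
#' spectral mean; `"highpass"` applies a zero-phase Gaussian high-pass whose
#' half-amplitude point sits at `cutoff_fraction` of the Nyquist fringe
#' frequency. Both leave the interferometric fringe band untouched and
#' suppress the non-interferometric background.
#'
#' @param stack A [spectral_stack()].
#' @param method `"mean_subtract"` or `"highpass"`.
#' @param cutoff_fraction High-pass cutoff as a fraction of Nyquist, in
#'   (0, 0.5); default 0.02.
#' @return A `spectral_stack`-like object whose data may be negative (class
#'   retained, positivity invariant waived after DC removal).
#' @export
remove_dc <- function(stack, method = c("mean_subtract", "highpass"),
                      cutoff_fraction = 0.02) {
  method <- match.arg(method)
  d <- dim(stack$data)
  n_k <- d[3]
  m <- matrix(aperm(stack$data, c(3, 1, 2)), nrow = n_k)
  if (method == "mean_subtract") {
    out <- sweep(m, 2, colMeans(m))
  } else {
    if (n_k < 4) stop("highpass needs n_k >= 4", call. = FALSE)
    if (cutoff_fraction <= 0 || cutoff_fraction >= 0.5) {
      stop("cutoff_fraction must lie in (0, 0.5)", call. = FALSE)
    }
    f <- abs(fft_freq(n_k)) / 0.5          # fraction of Nyquist
    h <- 1 - exp(-log(2) * (f / cutoff_fraction)^2)
    out <- Re(stats::mvfft(stats::mvfft(m) * h, inverse = TRUE)) / n_k
  }
  res <- stack
  res$data <- aperm(array(out, dim = c(n_k, d[1], d[2])), c(2, 3, 1))
  res$dc_removed <- method
  # skip the constructor: DC-removed data is legitimately signed
  res
}

# RMS of the spectral-fringe band: per-pixel FFT along k, keep bins with
# |frequency| above cutoff_fraction of Nyquist, Parseval-equivalent RMS.
fringe_band_rms <- function(stack, cutoff_fraction = 0.02) {
  d <- dim(stack$data)
  n_k <- d[3]
  F <- fft_along_k(stack$data)
  band <- abs(fft_freq(n_k)) / 0.5 > cutoff_fraction
  if (!any(band)) stop("empty fringe band", call. = FALSE)
  # Parseval: per-sample mean square of the band-limited signal
  sqrt(sum(Mod(F[band, , drop = FALSE])^2) / (n_k^2 * prod(d[1:2])))
}

#' Residual-crosstalk metrics for a mask-averaged acquisition
#'
#' Quantifies how well averaging suppressed the crosstalk while preserving
#' the mirror fringe. All quantities are computed in the spectral fringe band
#' (|fringe frequency| above `cutoff_fraction` of Nyquist), which excludes
#' the DC/autocorrelation terms.
#'
#' @param avg The mask-averaged stack ([average_stacks()] output).
#' @param mirror_only Matched simulation with crosstalk disabled.
#' @param crosstalk_only Matched single-mask crosstalk-only stack (the
#'   "before averaging" reference), or a list of such stacks whose per-stack
#'   fringe RMS is averaged for a steadier reference.
#' @param cutoff_fraction Fringe-band boundary (fraction of Nyquist).
#' @return An `averaging_report` list: `n_masks`, `mirror_fringe_amplitude`,
#'   `residual_crosstalk_rms`, `suppression_factor` (crosstalk fringe RMS
#'   before / after averaging).
#' @export
suppression_metrics <- function(avg, mirror_only, crosstalk_only,
                                cutoff_fraction = 0.02, n_masks = NA_integer_) {
  ct_list <- if (inherits(crosstalk_only, "spectral_stack")) {
    list(crosstalk_only)
  } else crosstalk_only
  for (s in c(list(mirror_only), ct_list)) {
    if (!all(dim(s$data) == dim(avg$data))) {
      stop("stacks have mismatched grids", call. = FALSE)
    }
  }
  residual <- avg
  residual$data <- avg$data - mirror_only$data
  res_rms <- fringe_band_rms(residual, cutoff_fraction)
  before_rms <- mean(vapply(ct_list, fringe_band_rms, numeric(1),
                            cutoff_fraction = cutoff_fraction))
  mirror_amp <- sqrt(2) * fringe_band_rms(mirror_only, cutoff_fraction)
  structure(list(
    n_masks = n_masks,
    mirror_fringe_amplitude = mirror_amp,
    residual_crosstalk_rms = res_rms,
    suppression_factor = if (res_rms > 0) before_rms / res_rms else Inf
  ), class = "averaging_report")
}

#' @export
print.averaging_report <- function(x, ...) {
  cat(sprintf(
    "<averaging_report> n_masks=%s fringe_amp=%.4g residual_rms=%.4g suppression=%.3g\n",
    as.character(x$n_masks), x$mirror_fringe_amplitude,
    x$residual_crosstalk_rms, x$suppression_factor))
  invisible(x)
}
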