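#' Complex volumetric reconstruction
#'
#' Container for the depth-resolved complex reconstruction together with the
#' depth axis and an append-only provenance record of the processing stages
#' applied.
#'
#' @param data nx x ny x nz complex array.
#' @param z_axis Depth axis (µm), length nz.
#' @param provenance List of stage records (name + parameters), append-only.
#' @return An object of class `"recon_volume"`.
#' @export
recon_volume <- function(data, z_axis, provenance = list()) {
  d <- dim(data)
  if (length(d) != 3) stop("data must be 3D (nx, ny, nz)", call. = FALSE)
  if (d[3] != length(z_axis)) stop("z_axis length mismatch", call. = FALSE)
  structure(list(data = data, z_axis = z_axis, provenance = provenance),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<recon_volume> %dx%dx%d, z in [%.1f, %.1f] um, %d stage(s)\n",
              d[1], d[2], d[3], min(x$z_axis), max(x$z_axis),
              length(x$provenance)))
  invisible(x)
}

add_stage <- function(vol, name, params = list()) {
  vol$provenance[[length(vol$provenance) + 1L]] <- c(list(stage = name), params)
  vol
}

# ---- spectral-domain helpers -------------------------------------------------

# Pull a (n_k x npix) spectral matrix plus axis out of a spectral_stack or a
# complex "spectral_field" (as produced by apply_phase_corrector), ordered by
# increasing k and resampled to a uniform wavenumber grid when the sampling
# is nonuniform by more than 0.1%.
spectral_matrix <- function(x) {
  if (inherits(x, "spectral_stack") || inherits(x, "spectral_field")) {
    data <- x$data; ks <- x$k_axis
  } else stop("expected a spectral_stack or spectral_field", call. = FALSE)
  d <- dim(data)
  dk <- diff(ks)
  if (!(all(dk > 0) || all(dk < 0))) stop("non-monotonic k_axis", call. = FALSE)
  if (dk[1] < 0) {
    ks <- rev(ks)
    data <- data[, , rev(seq_len(d[3])), drop = FALSE]
  }
  m <- matrix(aperm(data, c(3, 1, 2)), nrow = d[3])
  dk <- diff(ks)
  if (max(abs(dk - mean(dk))) / mean(dk) > 1e-3) {
    ku <- seq(ks[1], ks[length(ks)], length.out = length(ks))
    m <- resample_matrix(m, ks, ku)
    ks <- ku
  }
  list(m = m, k = ks, nx = d[1], ny = d[2])
}

# Resample every column of m from the (smoothly chirped) source grid ks to
# the target grid kt. The samples are uniform in sweep index, so the signal
# is first oversampled exactly in the index domain by zero-padded FFT
# (band-limited interpolation, valid for fringes below the local Nyquist
# depth), then interpolated locally with a 4-point cubic Lagrange stencil on
# the fine grid — the residual error of the cubic at 1/oversample of Nyquist
# is negligible.
resample_matrix <- function(m, ks, kt, oversample = 8L) {
  n <- length(ks)
  if (oversample > 1L) {
    os <- as.integer(oversample)
    F <- stats::mvfft(as.matrix(m) + 0i)
    nf <- n * os
    Fo <- matrix(0 + 0i, nf, ncol(m))
    if (n %% 2L == 0L) {
      h <- n %/% 2L
      Fo[1:h, ] <- F[1:h, , drop = FALSE]
      Fo[h + 1L, ] <- F[h + 1L, ] / 2
      Fo[nf - h + 1L, ] <- F[h + 1L, ] / 2
      if (h >= 2L) Fo[(nf - h + 2L):nf, ] <- F[(h + 2L):n, , drop = FALSE]
    } else {
      hh <- (n + 1L) %/% 2L
      Fo[1:hh, ] <- F[1:hh, , drop = FALSE]
      Fo[(nf - (n - hh) + 1L):nf, ] <- F[(hh + 1L):n, , drop = FALSE]
    }
    mf <- stats::mvfft(Fo, inverse = TRUE) / n
    idx_fine <- (seq_len(nf) - 1) / os
    keep <- idx_fine <= (n - 1) + 1e-9
    mf <- mf[keep, , drop = FALSE]
    kf <- stats::spline(seq_len(n) - 1, ks, xout = idx_fine[keep])$y
    m <- if (is.complex(m)) mf else Re(mf)
    ks <- kf
    n <- length(ks)
  }
  W <- matrix(0, length(kt), n)
  for (i in seq_along(kt)) {
    j <- findInterval(kt[i], ks)
    j0 <- min(max(j - 1L, 1L), n - 3L)
    idx <- j0:(j0 + 3L)
    xi <- ks[idx]
    for (a in 1:4) {
      w <- 1
      for (b in 1:4) if (b != a) w <- w * (kt[i] - xi[b]) / (xi[a] - xi[b])
      W[i, idx[a]] <- w
    }
  }
  W %*% m
}

# FFT a (n_k x npix) spectral matrix to depth: apodize, zero-pad, transform,
# retain the positive-depth Hermitian half; returns the complex half plus the
# z axis. Hann apodization (amplitude-normalized) suppresses the sidelobe
# leakage of the rectangular sweep window at the cost of a broader axial PSF.
depth_transform <- function(m, k, pad_factor = 1L, window = c("hann", "none")) {
  window <- match.arg(window)
  n_k <- nrow(m)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_k) - 1) / (n_k - 1))
    m <- m * (w / mean(w))
  }
  n_pad <- n_k * as.integer(pad_factor)
  if (n_pad > n_k) m <- rbind(m, matrix(0, n_pad - n_k, ncol(m)))
  F <- stats::mvfft(m)
  nz <- n_pad %/% 2L
  dk <- (k[length(k)] - k[1]) / (length(k) - 1)
  z_axis <- pi * (0:(nz - 1L)) / (n_pad * dk)
  list(F = F[seq_len(nz), , drop = FALSE], z_axis = z_axis)
}

#' Reconstruct depth structure from a spectral stack
#'
#' Per-pixel Fourier transform along the wavenumber axis: the stack is
#' resampled to a uniform k grid when needed (swept sources tune uniformly in
#' wavelength, so k sampling is slightly chirped), zero-padded by
#' `pad_factor` to refine axial sampling, transformed, and only the
#' positive-depth half is retained (Hermitian symmetry of real
#' interferograms). The depth axis step is \eqn{\Delta z = \pi / (N_{pad}
#' \delta k)}.
#'
#' @param stack A DC-removed [spectral_stack()] (or complex
#'   `spectral_field`).
#' @param pad_factor Integer >= 1 zero-padding factor.
#' @param window Spectral apodization: `"hann"` (default; suppresses axial
#'   sidelobe leakage, amplitude-normalized) or `"none"` (rectangular sweep
#'   window).
#' @return A [recon_volume()].
#' @export
reconstruct_depth <- function(stack, pad_factor = 1L, window = c("hann", "none")) {
  window <- match.arg(window)
  if (pad_factor < 1) stop("pad_factor must be >= 1", call. = FALSE)
  sm <- spectral_matrix(stack)
  dt <- depth_transform(sm$m, sm$k, pad_factor, window)
  vol <- recon_volume(
    aperm(array(dt$F, dim = c(nrow(dt$F), sm$nx, sm$ny)), c(2, 3, 1)),
    dt$z_axis
  )
  add_stage(vol, "reconstruct_depth",
            list(pad_factor = as.integer(pad_factor), window = window))
}

# ---- fixed-pattern filtering -------------------------------------------------

#' Estimate a fixed-pattern notch filter
#'
#' Fixed-pattern noise that repeats in every plane of a volume shows up as
#' isolated bright spots in the depth-integrated 2D spatial spectrum. Each
#' plane is 2D-FFT'd, magnitudes are summed along the third axis, a local
#' median filter estimates the smooth background, and frequency pixels whose
#' magnitude exceeds `threshold` times the background (outside a DC guard
#' disk) are flagged and point-symmetrized so that filtering real images
#' keeps them real.
#'
#' @param volume A [spectral_stack()], [recon_volume()], or 3D array with at
#'   least 4 planes along the third dimension.
#' @param threshold Detection multiple over the median background (default 4).
#' @param background_window Median filter window (odd, default 9).
#' @param dc_guard_radius Frequencies within this radius (in FFT bins) of DC
#'   are never flagged (default 3).
#' @return An object of class `"fixed_pattern_filter"` with the logical
#'   `notch_mask` (in unshifted FFT coordinates) and the detection parameters.
#' @export
estimate_fixed_pattern_filter <- function(volume, threshold = 4,
                                          background_window = 9L,
                                          dc_guard_radius = 3) {
  arr <- if (inherits(volume, "spectral_stack") || inherits(volume, "recon_volume")) {
    volume$data
  } else volume
  d <- dim(arr)
  if (is.null(d) || length(d) != 3 || d[3] < 4) {
    stop("need a 3D volume with at least 4 planes", call. = FALSE)
  }
  acc <- matrix(0, d[1], d[2])
  for (l in seq_len(d[3])) acc <- acc + Mod(fft2(arr[, , l]))
  bg <- median_filter2(acc, background_window)
  fx <- fft_freq(d[1]) * d[1]
  fy <- fft_freq(d[2]) * d[2]
  guard <- outer(fx^2, fy^2, "+") <= dc_guard_radius^2
  flag <- (acc > threshold * bg) & !guard
  # point reflection through the origin in FFT index space: idx -> (-idx) mod n
  refl <- flag[c(1L, rev(seq_len(d[1] - 1L) + 1L)), c(1L, rev(seq_len(d[2] - 1L) + 1L))]
  structure(list(notch_mask = flag | refl,
                 detection_params = list(threshold = threshold,
                                         background_window = background_window,
                                         dc_guard_radius = dc_guard_radius)),
            class = "fixed_pattern_filter")
}

#' Apply a fixed-pattern notch filter to every plane
#'
#' Zeroes the flagged spatial frequencies in each plane (2D FFT, notch,
#' inverse FFT). Real input planes stay real to numerical tolerance because
#' the notch mask is point-symmetric.
#'
#' @param stack A [spectral_stack()], [recon_volume()], or 3D array.
#' @param filter A [estimate_fixed_pattern_filter()] result on the same grid.
#' @return Object of the same type with filtered planes.
#' @export
apply_spatial_filter <- function(stack, filter) {
  stopifnot(inherits(filter, "fixed_pattern_filter"))
  is_stack <- inherits(stack, "spectral_stack")
  is_vol <- inherits(stack, "recon_volume")
  arr <- if (is_stack || is_vol) stack$data else stack
  d <- dim(arr)
  if (!all(dim(filter$notch_mask) == d[1:2])) {
    stop("filter grid does not match the volume", call. = FALSE)
  }
  was_real <- !is.complex(arr)
  keep <- !filter$notch_mask
  out <- arr
  for (l in seq_len(d[3])) {
    plane <- ifft2(fft2(arr[, , l]) * keep)
    out[, , l] <- if (was_real) Re(plane) else plane
  }
  if (is_stack || is_vol) {
    stack$data <- out
    if (is_vol) stack <- add_stage(stack, "fixed_pattern_filter",
                                   filter$detection_params)
    stack
  } else out
}

# ---- kurtosis phase correction ----------------------------------------------

#' Polynomial spectral phase corrector
#'
#' Five tunable coefficients applied as \eqn{\varphi(\kappa) = \sum_{j=1}^5
#' a_j \kappa^j} with \eqn{\kappa} the wavenumber axis normalized to
#' \eqn{[-1, 1]}. Orders 2-3 compensate physical group-velocity dispersion,
#' order 1 absorbs axial bulk motion, orders 4-5 residual chirp. The
#' corrector is unit-modulus (pure phase), so total spectral energy is
#' conserved.
#'
#' @param a Numeric vector of up to 5 coefficients (radians); padded with
#'   zeros.
#' @return An object of class `"phase_corrector"`.
#' @export
phase_corrector <- function(a = numeric(5)) {
  a <- c(as.numeric(a), numeric(5))[1:5]
  if (!all(is.finite(a))) stop("coefficients must be finite", call. = FALSE)
  structure(list(a = a), class = "phase_corrector")
}

#' @export
print.phase_corrector <- function(x, ...) {
  cat("<phase_corrector> a =", paste(sprintf("%.4g", x$a), collapse = ", "), "\n")
  invisible(x)
}

corrector_phase <- function(corrector, kappa) {
  phi <- 0
  for (j in 1:5) phi <- phi + corrector$a[j] * kappa^j
  phi
}

#' Apply a spectral phase corrector to a stack
#'
#' Resamples to uniform k and multiplies every pixel's spectrum by
#' \eqn{e^{i\varphi(\kappa)}}. The result is a complex `spectral_field`
#' that [reconstruct_depth()] accepts.
#'
#' @param stack A [spectral_stack()] or `spectral_field`.
#' @param corrector A [phase_corrector()].
#' @return A `spectral_field` (complex data + uniform `k_axis`).
#' @export
apply_phase_corrector <- function(stack, corrector) {
  stopifnot(inherits(corrector, "phase_corrector"))
  sm <- spectral_matrix(stack)
  kappa <- 2 * (sm$k - mean(sm$k)) / (sm$k[length(sm$k)] - sm$k[1])
  m <- sm$m * exp(1i * corrector_phase(corrector, kappa))
  structure(list(
    data = aperm(array(m, dim = c(length(sm$k), sm$nx, sm$ny)), c(2, 3, 1)),
    k_axis = sm$k
  ), class = "spectral_field")
}

#' Kurtosis-driven spectral phase correction
#'
#' Estimates the five-parameter polynomial phase corrector that maximizes the
#' kurtosis (standardized fourth central moment) of B-scan intensity after
#' transforming the corrected spectrum to depth — a sharpness measure:
#' dispersed axial peaks spread energy and lower kurtosis, compensated peaks
#' concentrate it. A coarse pre-scan of the quadratic (group-velocity
#' dispersion) coefficient seeds a Nelder-Mead refinement over all five
#' coefficients on the selected B-scan; the converged corrector is then
#' applied to the entire volume. Deterministic given `init` and the data.
#'
#' @param stack Spectral-domain data (a DC-removed [spectral_stack()] or
#'   complex `spectral_field`), i.e. pre-depth-FFT.
#' @param init A [phase_corrector()] starting point (default zeros).
#' @param plane `"XZ"` (fix a y row) or `"YZ"` (fix an x column).
#' @param index 1-based index of the fixed row/column; default mid-frame.
#' @param pad_factor Axial zero padding used during metric evaluation and for
#'   the returned volume.
#' @param maxit Nelder-Mead iteration cap.
#' @param prescan Logical; run the coarse dispersion pre-scan (recommended
#'   when `init` is zero).
#' @param min_improve Minimum relative kurtosis improvement required to adopt
#'   a new corrector (default 1%); below it the initial corrector is kept.
#' @param window Spectral apodization used in the metric and the returned
#'   volume (see [reconstruct_depth()]).
#' @return List with `volume` (corrected [recon_volume()]), `corrector`,
#'   `metric_initial`, `metric_final`, `converged`.
#' @export
kurtosis_phase_correct <- function(stack, init = phase_corrector(),
                                   plane = c("XZ", "YZ"), index = NULL,
                                   pad_factor = 1L, maxit = 500,
                                   prescan = TRUE, min_improve = 0.01,
                                   window = c("hann", "none")) {
  plane <- match.arg(plane)
  window <- match.arg(window)
  stopifnot(inherits(init, "phase_corrector"))
  sm <- spectral_matrix(stack)
  kappa <- 2 * (sm$k - mean(sm$k)) / (sm$k[length(sm$k)] - sm$k[1])
  cols <- if (plane == "XZ") {
    y0 <- index %||% (sm$ny %/% 2L + 1L)
    (y0 - 1L) * sm$nx + seq_len(sm$nx)
  } else {
    x0 <- index %||% (sm$nx %/% 2L + 1L)
    x0 + sm$nx * (seq_len(sm$ny) - 1L)
  }
  msub <- sm$m[, cols, drop = FALSE]
  metric <- function(a) {
    phi <- 0
    for (j in 1:5) phi <- phi + a[j] * kappa^j
    F <- depth_transform(msub * exp(1i * phi), sm$k, pad_factor, window)$F
    val <- kurtosis(Mod(F)^2)
    if (!is.finite(val)) stop("non-finite sharpness metric", call. = FALSE)
    val
  }
  a0 <- init$a
  m_init <- metric(a0)
  if (prescan) {
    grid <- seq(-15, 15, length.out = 31)
    vals <- vapply(grid, function(g) metric(a0 + c(0, g, 0, 0, 0)), numeric(1))
    best <- grid[which.max(vals)]
    if (max(vals) > m_init) a0 <- a0 + c(0, best, 0, 0, 0)
  }
  opt <- stats::optim(a0, metric, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = maxit,
                                     reltol = 1e-10))
  # second-stage restart tightens convergence of the simplex
  opt2 <- stats::optim(opt$par, metric, method = "Nelder-Mead",
                       control = list(fnscale = -1, maxit = maxit,
                                      reltol = 1e-12))
  # ascent guarantee, plus a minimum-improvement guard: data that is already
  # sharp keeps its initial corrector instead of chasing sub-bin jitter
  cand <- list(init$a, a0, opt$par, opt2$par)
  scores <- vapply(cand, metric, numeric(1))
  a_best <- if (max(scores) > m_init * (1 + min_improve)) {
    cand[[which.max(scores)]]
  } else init$a
  corr <- phase_corrector(a_best)
  field <- apply_phase_corrector(stack, corr)
  vol <- reconstruct_depth(field, pad_factor, window)
  vol <- add_stage(vol, "kurtosis_phase_correct",
                   list(a = corr$a, plane = plane,
                        converged = opt2$convergence == 0))
  list(volume = vol, corrector = corr, metric_initial = m_init,
       metric_final = metric(a_best), converged = opt2$convergence == 0)
}
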