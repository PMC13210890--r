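#' Complex optical field on the detector grid
#'
#' Lightweight container for a monochromatic field sampled on the camera
#' grid. The `component` tag distinguishes the ballistic mirror-image field,
#' the diffuse crosstalk field, their sum, and the reference arm field; the
#' total field is additive in its components.
#'
#' @param values nx x ny complex matrix (arbitrary field units).
#' @param k Wavenumber (1/µm).
#' @param component One of `"mirror"`, `"crosstalk"`, `"total"`, `"reference"`.
#' @return An object of class `"complex_field"`.
#' @export
complex_field <- function(values, k, component = c("total", "mirror",
                                                   "crosstalk", "reference")) {
  component <- match.arg(component)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("field values must be finite", call. = FALSE)
  }
  structure(list(values = values, k = k, component = component),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %s, k=%.4f 1/um, %dx%d\n", x$component, x$k,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Spectral interferogram stack
#'
#' Real-valued detected intensity over the camera grid and the wavenumber
#' sweep, for a single mask (or a single camera-integrated exposure).
#'
#' @param data nx x ny x n_k non-negative array of detected intensity.
#' @param k_axis Strictly monotonic wavenumber axis (1/µm), length n_k.
#' @param mask_id Integer mask identifier or `"integrated"`.
#' @param acquisition_mode `"sequential"` or `"camera_integrated"`.
#' @return An object of class `"spectral_stack"`.
#' @export
spectral_stack <- function(data, k_axis, mask_id = 0L,
                           acquisition_mode = c("sequential", "camera_integrated")) {
  acquisition_mode <- match.arg(acquisition_mode)
  d <- dim(data)
  if (length(d) != 3) stop("data must be a 3D array (nx, ny, n_k)", call. = FALSE)
  if (d[3] != length(k_axis)) stop("k_axis length must match dim(data)[3]", call. = FALSE)
  dk <- diff(k_axis)
  if (!(all(dk > 0) || all(dk < 0))) stop("k_axis must be strictly monotonic", call. = FALSE)
  if (min(data) < -1e-12 * max(abs(data))) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(data = data, k_axis = k_axis, mask_id = mask_id,
                 acquisition_mode = acquisition_mode),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_stack> %dx%dx%d, mask_id=%s, mode=%s\n",
              d[1], d[2], d[3], as.character(x$mask_id), x$acquisition_mode))
  invisible(x)
}

check_k_in_band <- function(config, k) {
  ks <- k_axis(config)
  lo <- min(ks); hi <- max(ks)
  tol <- 1e-9 * hi
  if (k < lo - tol || k > hi + tol) {
    stop(sprintf("k = %.6g 1/um lies outside the configured sweep band [%.6g, %.6g]",
                 k, lo, hi), call. = FALSE)
  }
  invisible(TRUE)
}

# Per-layer ballistic amplitude maps: reflectivity times the cumulative
# round-trip attenuation exp(-2 * sum(mu * d)) of the layers above.
layer_amplitudes <- function(phantom, config) {
  nlay <- length(phantom$layers)
  npix <- config$nx * config$ny
  A <- matrix(0, npix, nlay)
  z <- numeric(nlay)
  cum <- 0
  for (l in seq_len(nlay)) {
    lay <- phantom$layers[[l]]
    z[l] <- lay$z_top
    A[, l] <- as.numeric(lay$reflectivity_map) * exp(-2 * cum)
    cum <- cum + lay$scattering_mu * lay$thickness
  }
  list(A = A, z = z)
}

#' Propagate the ballistic (mirror-image) field
#'
#' For each lateral position the mirror field is the sum over layers of
#' reflectivity times the cumulative round-trip attenuation
#' \eqn{\exp(-2\sum \mu d)} of the material above, with the deterministic
#' round-trip phase \eqn{\Theta = 2kz} encoded as \eqn{e^{-i 2 k z}}. The
#' mask phase \eqn{e^{i\Delta\varphi}} is applied once (illumination side).
#'
#' @param phantom A [scattering_phantom()].
#' @param config An [optical_config()].
#' @param k Wavenumber (1/µm); must lie inside the configured sweep band.
#' @param mask A [generate_phase_mask()] result.
#' @return A [complex_field()] with `component = "mirror"`.
#' @export
propagate_mirror <- function(phantom, config, k, mask) {
  check_k_in_band(config, k)
  la <- layer_amplitudes(phantom, config)
  v <- la$A %*% exp(-1i * 2 * k * la$z)
  values <- matrix(as.complex(v), config$nx, config$ny) * exp(1i * mask$phase)
  complex_field(values, k, "mirror")
}

# Diffuse speckle fields shed by the scattering layers of one mask
# realization: one spatially low-pass-filtered circular complex Gaussian
# field per crosstalk-active layer, with per-pixel variance
# crosstalk_strength * (1 - exp(-2 mu d)).
crosstalk_speckles <- function(phantom, config, mask_seed, k_index = 0L) {
  nx <- config$nx; ny <- config$ny
  active <- which(vapply(phantom$layers, function(l) {
    l$crosstalk_strength * (1 - exp(-2 * l$scattering_mu * l$thickness)) > 0
  }, logical(1)))
  if (length(active) == 0) return(list(S = NULL, z = numeric(0)))
  fx <- fft_freq(nx) / config$pixel_pitch_obj
  fy <- fft_freq(ny) / config$pixel_pitch_obj
  S <- matrix(0 + 0i, nx * ny, length(active))
  z <- numeric(length(active))
  for (i in seq_along(active)) {
    lay <- phantom$layers[[active[i]]]
    v <- lay$crosstalk_strength * (1 - exp(-2 * lay$scattering_mu * lay$thickness))
    s <- with_seed(derive_seed(mask_seed, 100000L + active[i] * 131L + k_index), {
      # diffuse paths have variable length: the round-trip depth of this
      # realization is drawn uniformly within the layer extent
      z[i] <- lay$z_top + stats::runif(1) * lay$thickness
      complex_gaussian(nx, ny)
    })
    # detection-NA low-pass (hard circular aperture in spatial frequency)
    lambda_um <- (config$lambda_start + config$lambda_end) / 2 / 1000
    f_cut <- config$na_det / lambda_um
    ap <- outer(fx^2, fy^2, "+") <= f_cut^2
    frac <- mean(ap)
    s <- ifft2(fft2(s) * ap)
    S[, i] <- as.complex(s) * sqrt(v / frac)
  }
  list(S = S, z = z)
}

#' Propagate the optical-crosstalk field
#'
#' The crosstalk field is modeled statistically as circular complex Gaussian
#' speckle: each scattering layer sheds a diffuse field whose per-pixel
#' variance equals `crosstalk_strength` times the ballistic energy it removes,
#' \eqn{1 - \exp(-2\mu d)}, spatially low-pass filtered to the detection NA
#' and carrying the round-trip phase of a depth drawn uniformly within the
#' layer extent (diffuse paths have variable length). Realizations are
#' seeded jointly by the mask seed and (in `"per_k"` mode) the spectral index,
#' so crosstalk decorrelates across masks but is reproducible.
#'
#' @inheritParams propagate_mirror
#' @param k_index Spectral frame index (0-based) used for seeding in
#'   `"per_k"` mode.
#' @param spectral_mode `"frozen"` (default): one speckle realization per mask,
#'   fully correlated across the sweep; `"per_k"`: independent realization for
#'   every spectral frame.
#' @return A [complex_field()] with `component = "crosstalk"`.
#' @export
propagate_crosstalk <- function(phantom, config, k, mask, k_index = 0L,
                                spectral_mode = c("frozen", "per_k")) {
  spectral_mode <- match.arg(spectral_mode)
  check_k_in_band(config, k)
  sp <- crosstalk_speckles(phantom, config, mask$seed,
                           k_index = if (spectral_mode == "per_k") k_index else 0L)
  nx <- config$nx; ny <- config$ny
  if (is.null(sp$S)) {
    return(complex_field(matrix(0 + 0i, nx, ny), k, "crosstalk"))
  }
  v <- sp$S %*% exp(-1i * 2 * k * sp$z)
  complex_field(matrix(as.complex(v), nx, ny), k, "crosstalk")
}

#' Apply the detection-aperture low-pass to a field
#'
#' Hard circular aperture of radius \eqn{NA_{det}/\lambda} in the 2D spatial
#' frequency plane, the coherent cutoff of the detection optics.
#'
#' @param field A [complex_field()] (or a complex matrix with `k` supplied).
#' @param config An [optical_config()].
#' @param k Wavenumber (1/µm); defaults to the field's own.
#' @return A filtered object of the same type.
#' @export
detection_lowpass <- function(field, config, k = NULL) {
  is_cf <- inherits(field, "complex_field")
  values <- if (is_cf) field$values else field
  k <- k %||% (if (is_cf) field$k else stop("k required", call. = FALSE))
  lambda_um <- 2 * pi / k
  f_cut <- config$na_det / lambda_um
  fx <- fft_freq(nrow(values)) / config$pixel_pitch_obj
  fy <- fft_freq(ncol(values)) / config$pixel_pitch_obj
  ap <- outer(fx^2, fy^2, "+") <= f_cut^2
  out <- ifft2(fft2(values) * ap)
  if (is_cf) complex_field(out, k, field$component) else out
}

#' Record one interferogram frame
#'
#' Detected intensity \eqn{I = |E_s|^2 + |E_r|^2 + 2\,\mathrm{Re}(E_s E_r^*)}.
#' When the mask phase enters both arms identically (illumination-side
#' modulation) it cancels in the mirror interference term, which is what
#' makes mask-ensemble averaging preserve the ballistic fringe. Optional
#' Poisson shot noise (at `full_well` electrons at the brightest pixel) and
#' quantization to the configured bit depth.
#'
#' @param sample A [complex_field()] (component `"total"`/`"mirror"`/
#'   `"crosstalk"`).
#' @param reference A [complex_field()] with `component = "reference"` on the
#'   same grid and wavenumber.
#' @param config An [optical_config()].
#' @param shot_noise Logical; add Poisson noise.
#' @param full_well Electrons mapped to the brightest pixel when
#'   `shot_noise = TRUE`.
#' @param quantize Logical; round to `2^bit_depth` levels.
#' @param seed Seed for the shot-noise draw.
#' @return nx x ny matrix of non-negative intensities.
#' @export
record_interferogram <- function(sample, reference, config, shot_noise = FALSE,
                                 full_well = 10000, quantize = FALSE, seed = 0) {
  if (!all(dim(sample$values) == dim(reference$values))) {
    stop("sample and reference grids differ", call. = FALSE)
  }
  if (abs(sample$k - reference$k) > 1e-9 * abs(reference$k)) {
    stop("sample and reference wavenumbers differ", call. = FALSE)
  }
  I <- Mod(sample$values + reference$values)^2
  if (shot_noise) {
    scale <- full_well / max(I)
    I <- with_seed(seed, stats::rpois(length(I), lambda = as.numeric(I) * scale)) / scale
    I <- matrix(I, nrow(sample$values), ncol(sample$values))
  }
  if (quantize) {
    levels <- 2^config$bit_depth - 1
    top <- max(I)
    if (top > 0) I <- round(I / top * levels) / levels * top
  }
  I
}

#' Reference arm field
#'
#' A uniform field of amplitude `ref_amplitude`. With illumination-side
#' modulation (`mask_arm = "illumination"`) the reference carries the same
#' mask phase as the sample illumination; with object-arm modulation it is
#' flat.
#'
#' @inheritParams propagate_mirror
#' @param mask_arm `"illumination"` (mask pre-split, both arms share it) or
#'   `"object"` (sample arm only).
#' @return A [complex_field()] with `component = "reference"`.
#' @export
reference_field <- function(config, k, mask,
                            mask_arm = c("illumination", "object")) {
  mask_arm <- match.arg(mask_arm)
  base <- matrix(config$ref_amplitude + 0i, config$nx, config$ny)
  if (mask_arm == "illumination") base <- base * exp(1i * mask$phase)
  complex_field(base, k, "reference")
}

#' Acquire a full spectral volume under phase-mask modulation
#'
#' Simulates the swept-source acquisition: for every mask and every spectral
#' frame the mirror and crosstalk fields are propagated, interfered with the
#' reference, and recorded as intensity. In `"sequential"` mode one
#' [spectral_stack()] per mask is returned (post-processing averaging);
#' in `"camera_integrated"` mode the per-mask interferograms are averaged
#' frame-by-frame into a single stack (hardware integration on the chip).
#'
#' @param phantom A [scattering_phantom()].
#' @param config An [optical_config()].
#' @param masks List of [generate_phase_mask()] results (>= 1).
#' @param mode `"sequential"` or `"camera_integrated"`.
#' @param mask_arm Where the modulator sits; see [reference_field()].
#' @param spectral_mode Crosstalk decorrelation across the sweep; see
#'   [propagate_crosstalk()].
#' @param include Character subset of `c("mirror", "crosstalk")`; dropping a
#'   component yields matched partial simulations (same seeds) for
#'   diagnostics.
#' @param shot_noise,quantize,full_well Detector noise options, see
#'   [record_interferogram()].
#' @return A list of `spectral_stack` objects (`"sequential"`) or a single
#'   `spectral_stack` (`"camera_integrated"`).
#' @examples
#' cfg <- optical_config(nx = 16, ny = 16, n_k = 8)
#' ph <- make_phantom("plane_behind_diffuser", cfg, mu = 0)
#' masks <- phase_mask_ensemble(cfg, 2, kind = "slm")
#' stacks <- acquire_volume(ph, cfg, masks)
#' length(stacks)
#' @export
acquire_volume <- function(phantom, config, masks,
                           mode = c("sequential", "camera_integrated"),
                           mask_arm = c("illumination", "object"),
                           spectral_mode = c("frozen", "per_k"),
                           include = c("mirror", "crosstalk"),
                           shot_noise = FALSE, quantize = FALSE,
                           full_well = 10000) {
  mode <- match.arg(mode)
  mask_arm <- match.arg(mask_arm)
  spectral_mode <- match.arg(spectral_mode)
  include <- match.arg(include, several.ok = TRUE)
  if (length(masks) < 1) stop("at least one mask is required", call. = FALSE)
  ks <- k_axis(config)
  nx <- config$nx; ny <- config$ny; npix <- nx * ny; n_k <- length(ks)

  mirror_base <- if ("mirror" %in% include) {
    la <- layer_amplitudes(phantom, config)
    la$A %*% exp(-1i * 2 * outer(la$z, ks))      # npix x n_k
  } else matrix(0 + 0i, npix, n_k)

  make_stack <- function(mask, im) {
    phase <- as.vector(exp(1i * mask$phase))
    Es <- if ("mirror" %in% include) mirror_base * phase else
      matrix(0 + 0i, npix, n_k)
    if ("crosstalk" %in% include) {
      if (spectral_mode == "frozen") {
        sp <- crosstalk_speckles(phantom, config, mask$seed)
        if (!is.null(sp$S)) Es <- Es + sp$S %*% exp(-1i * 2 * outer(sp$z, ks))
      } else {
        for (l in seq_len(n_k)) {
          sp <- crosstalk_speckles(phantom, config, mask$seed, k_index = l)
          if (!is.null(sp$S)) {
            Es[, l] <- Es[, l] + sp$S %*% exp(-1i * 2 * ks[l] * sp$z)
          }
        }
      }
    }
    Er <- if (mask_arm == "illumination") {
      config$ref_amplitude * phase
    } else rep(config$ref_amplitude + 0i, npix)
    I <- Mod(Es + Er)^2                           # Er recycles down columns
    if (shot_noise) {
      scale <- full_well / max(I)
      I <- matrix(with_seed(derive_seed(mask$seed, 555L),
                            stats::rpois(length(I), as.numeric(I) * scale)) / scale,
                  npix, n_k)
    }
    if (quantize) {
      levels <- 2^config$bit_depth - 1
      top <- max(I)
      if (top > 0) I <- round(I / top * levels) / levels * top
    }
    spectral_stack(array(I, dim = c(nx, ny, n_k)), ks, mask_id = im)
  }

  stacks <- lapply(seq_along(masks), function(i) make_stack(masks[[i]], i))
  if (mode == "sequential") return(stacks)
  avg <- Reduce(`+`, lapply(stacks, function(s) s$data)) / length(stacks)
  spectral_stack(avg, ks, mask_id = "integrated",
                 acquisition_mode = "camera_integrated")
}
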