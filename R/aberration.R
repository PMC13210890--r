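# Zernike polynomials (Noll ordering, RMS-normalized) on the pupil disk
# inscribed in the spatial-frequency plane, and the computational
# adaptive-optics stages built on them.

#' Noll index to (radial order n, azimuthal frequency m)
#'
#' Standard Noll ordering: within a radial order, |m| ascends and the sign is
#' chosen so that even j carries m >= 0 and odd j carries m < 0.
#'
#' @param j Noll indices (>= 1).
#' @return Two-column integer matrix `(n, m)`.
#' @export
noll_to_nm <- function(j) {
  jmax <- max(j)
  res <- matrix(0L, jmax, 2)
  jj <- 0L; n <- 0L
  while (jj < jmax) {
    ms <- seq.int(-n, n, by = 2L)
    for (am in unique(abs(ms[order(abs(ms))]))) {
      if (am == 0L) {
        jj <- jj + 1L
        if (jj <= jmax) res[jj, ] <- c(n, 0L)
      } else {
        first_neg <- (jj + 1L) %% 2L == 1L
        jj <- jj + 1L
        if (jj <= jmax) res[jj, ] <- c(n, if (first_neg) -am else am)
        jj <- jj + 1L
        if (jj <= jmax) res[jj, ] <- c(n, if (first_neg) am else -am)
      }
    }
    n <- n + 1L
  }
  res[j, , drop = FALSE]
}

# Radial Zernike polynomial R_n^{|m|}(rho)
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  out
}

#' Evaluate a Zernike polynomial (Noll index, RMS-normalized)
#'
#' @param j Noll index.
#' @param rho Radial coordinate in \[0, 1\] (values > 1 give 0).
#' @param theta Azimuthal angle (radians).
#' @return Numeric array shaped like `rho`.
#' @export
zernike_noll <- function(j, rho, theta) {
  nm <- noll_to_nm(j)
  n <- nm[1]; m <- nm[2]
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  val <- norm * zernike_radial(n, m, rho) * ang
  val[rho > 1] <- 0
  val
}

# Pupil coordinates for an nx x ny frequency grid (unshifted FFT layout);
# the pupil disk is inscribed in the Nyquist square.
pupil_coords <- function(nx, ny) {
  fx <- fft_freq(nx)   # cycles per sample
  fy <- fft_freq(ny)
  X <- matrix(fx, nx, ny) / 0.5
  Y <- matrix(fy, nx, ny, byrow = TRUE) / 0.5
  list(rho = sqrt(X^2 + Y^2), theta = atan2(Y, X))
}

# Pupil phase surface for named Noll coefficients (radians)
zernike_pupil_phase <- function(nx, ny, coeffs) {
  pc <- pupil_coords(nx, ny)
  phi <- matrix(0, nx, ny)
  for (nm in names(coeffs)) {
    phi <- phi + coeffs[[nm]] * zernike_noll(as.integer(nm), pc$rho, pc$theta)
  }
  phi
}

#' Apply a Zernike pupil phase to an en-face complex image
#'
#' Multiplies the image's 2D spatial spectrum by
#' \eqn{e^{i\,\mathrm{sign}\sum_j c_j Z_j}} over the inscribed pupil disk.
#' With `sign = +1` this injects an aberration; with `sign = -1` it applies
#' the corresponding correction.
#'
#' @param image Complex (or real) matrix.
#' @param coeffs Named numeric vector; names are Noll indices, values radians.
#' @param sign +1 (inject) or -1 (correct).
#' @return Complex matrix.
#' @export
apply_pupil_phase <- function(image, coeffs, sign = 1) {
  phi <- zernike_pupil_phase(nrow(image), ncol(image), coeffs)
  ifft2(fft2(image) * exp(1i * sign * phi))
}

#' Split-aperture defocus estimation
#'
#' Defocus tilts the pupil phase quadratically, so images formed from the
#' left and right halves of the aperture are displaced laterally in opposite
#' directions. Per depth: 2D FFT of the en-face complex image, split into the
#' two half-apertures along x frequency, inverse FFT each, and estimate the
#' relative displacement by the cross-correlation peak with parabolic
#' sub-pixel interpolation. Displacement versus depth is fitted linearly and
#' converted to an RMS-normalized defocus Zernike coefficient (Noll j = 4)
#' through the geometric shear relation: a defocus coefficient \eqn{c_4}
#' shifts the half-aperture images by \eqn{\mp c_4\,8\sqrt3/(3\pi^2
#' f_{nyq})} pixels at the half-disk centroids \eqn{\pm 4 f_{nyq}/(3\pi)}.
#'
#' @param volume A [recon_volume()].
#' @param depth_range Optional `c(zmin, zmax)` (µm) restricting the planes
#'   used.
#' @param energy_floor Fraction of the brightest plane's energy below which a
#'   plane is skipped (default 0.01).
#' @return An object of class `"defocus_estimate"`: `coefficient` (radians of
#'   pupil phase, Noll j = 4, evaluated at the central fitted depth),
#'   `slope` (radians/µm of depth), `stderr`, and the per-depth
#'   `displacements` data frame.
#' @export
subaperture_defocus <- function(volume, depth_range = NULL,
                                energy_floor = 0.01) {
  stopifnot(inherits(volume, "recon_volume"))
  d <- dim(volume$data)
  z <- volume$z_axis
  sel <- seq_len(d[3])
  if (!is.null(depth_range)) {
    sel <- sel[z >= depth_range[1] & z <= depth_range[2]]
  }
  energy <- vapply(sel, function(l) sum(Mod(volume$data[, , l])^2), numeric(1))
  if (max(energy) <= 0) {
    stop("fewer than 3 depths carry usable signal", call. = FALSE)
  }
  sel <- sel[energy >= energy_floor * max(energy)]
  if (length(sel) < 3) stop("fewer than 3 depths carry usable signal", call. = FALSE)
  nx <- d[1]; ny <- d[2]
  pc <- pupil_coords(nx, ny)
  fxn <- matrix(fft_freq(nx), nx, ny)        # cycles per sample
  inside <- pc$rho <= 1
  maskL <- (fxn < 0) & inside
  maskR <- (fxn > 0) & inside
  f_nyq <- 0.5
  # energy-weighted x-frequency centroids of the two sub-apertures, pooled
  # over the selected depths: the geometric shear of a defocus phase
  # c4*sqrt(3)*(2 rho^2 - 1) is (1/2pi) d(phi)/d(fx) at the centroid, i.e.
  # (4 sqrt(3) c4 / (2 pi f_nyq^2)) * fx_centroid per sub-aperture.
  wL <- 0; wR <- 0; eL <- 0; eR <- 0
  specs <- lapply(sel, function(l) fft2(volume$data[, , l]))
  for (G in specs) {
    P <- Mod(G)^2
    wL <- wL + sum(P[maskL] * fxn[maskL]); eL <- eL + sum(P[maskL])
    wR <- wR + sum(P[maskR] * fxn[maskR]); eR <- eR + sum(P[maskR])
  }
  if (eL <= 0 || eR <= 0) stop("empty sub-aperture spectrum", call. = FALSE)
  fcL <- wL / eL; fcR <- wR / eR
  shear_per_c4 <- 4 * sqrt(3) / (2 * pi * f_nyq^2) * (fcR - fcL)  # px per rad
  disp <- vapply(seq_along(sel), function(i) {
    G <- specs[[i]]
    aL <- Mod(ifft2(G * maskL)); aL <- aL - mean(aL)
    aR <- Mod(ifft2(G * maskR)); aR <- aR - mean(aR)
    xcorr_shift(aL, aR)[1]
  }, numeric(1))
  zz <- z[sel]
  fit <- stats::lm(disp ~ zz)
  z_mid <- mean(zz)
  disp_mid <- unname(stats::predict(fit, data.frame(zz = z_mid)))
  co <- suppressWarnings(summary(fit)$coefficients)
  se <- sqrt(sum(co[, "Std. Error"]^2 * c(1, z_mid^2)))
  if (!is.finite(se)) se <- 0
  structure(list(
    coefficient = disp_mid / shear_per_c4,
    slope = unname(co["zz", "Estimate"]) / shear_per_c4,
    stderr = se / abs(shear_per_c4),
    displacements = data.frame(z = zz, dx = disp),
    noll_index = 4L
  ), class = "defocus_estimate")
}

#' @export
print.defocus_estimate <- function(x, ...) {
  cat(sprintf("<defocus_estimate> c4 = %.4g +/- %.3g rad (slope %.3g rad/um)\n",
              x$coefficient, x$stderr, x$slope))
  invisible(x)
}

# Relative displacement of image a with respect to image b (pixels, c(dx, dy))
# via the FFT cross-correlation peak with parabolic sub-pixel refinement.
xcorr_shift <- function(a, b) {
  C <- Re(ifft2(fft2(a) * Conj(fft2(b))))
  nx <- nrow(C); ny <- ncol(C)
  i0 <- which.max(C)
  ix <- (i0 - 1L) %% nx + 1L
  iy <- (i0 - 1L) %/% nx + 1L
  wrap <- function(i, n) (i - 1L) %% n + 1L
  para <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den == 0) 0 else 0.5 * (m1 - p1) / den
  }
  dx <- para(C[wrap(ix - 1L, nx), iy], C[ix, iy], C[wrap(ix + 1L, nx), iy])
  dy <- para(C[ix, wrap(iy - 1L, ny)], C[ix, iy], C[ix, wrap(iy + 1L, ny)])
  sx <- ix - 1L; if (sx > nx / 2) sx <- sx - nx
  sy <- iy - 1L; if (sy > ny / 2) sy <- sy - ny
  c(sx + dx, sy + dy)
}

#' Entropy-driven Zernike aberration correction
#'
#' Iterative coordinate descent over Zernike coefficients (piston, tip and
#' tilt excluded): each coefficient in turn is tuned by bracketed 1D
#' optimization of the Shannon entropy \eqn{S = -\sum p \ln p} of the
#' corrected image's normalized intensity, with the bracket halved every
#' cycle (multi-scale). Sharp images concentrate energy, so the default
#' direction is to minimize entropy; the direction is switchable.
#'
#' @param enface Complex (or real) non-constant matrix.
#' @param max_order Highest Zernike radial order to fit (>= 2).
#' @param init Optional named numeric vector of starting coefficients (Noll
#'   names).
#' @param direction `"minimize"` (default, sharper = lower entropy) or
#'   `"maximize"`.
#' @param max_cycles Coordinate-descent cycle cap (default 5).
#' @param tol Per-cycle metric improvement below which iteration stops.
#' @param span Initial half-width of the 1D search bracket (radians).
#' @return List: `image` (corrected complex matrix), `coeffs` (named vector,
#'   radians), `entropy_initial`, `entropy_final`, `cycles`.
#' @export
zernike_aberration_correct <- function(enface, max_order = 4, init = NULL,
                                       direction = c("minimize", "maximize"),
                                       max_cycles = 5, tol = 1e-4, span = 3) {
  direction <- match.arg(direction)
  if (max_order < 2) stop("max_order must be >= 2", call. = FALSE)
  if (sum(Mod(enface)^2) == 0) stop("zero-energy image", call. = FALSE)
  if (stats::sd(Mod(enface)) == 0) stop("constant image", call. = FALSE)
  nx <- nrow(enface); ny <- ncol(enface)
  jmax <- (max_order + 1) * (max_order + 2) / 2
  js <- 4:jmax
  pc <- pupil_coords(nx, ny)
  basis <- lapply(js, function(j) zernike_noll(j, pc$rho, pc$theta))
  names(basis) <- js
  coeffs <- stats::setNames(numeric(length(js)), js)
  if (!is.null(init)) coeffs[names(init)] <- init
  G0 <- fft2(enface)
  sgn <- if (direction == "minimize") 1 else -1
  metric <- function(cf) {
    phi <- matrix(0, nx, ny)
    for (i in seq_along(js)) {
      if (cf[i] != 0) phi <- phi + cf[i] * basis[[i]]
    }
    img <- ifft2(G0 * exp(-1i * phi))
    sgn * shannon_entropy(Mod(img)^2)
  }
  cur <- metric(coeffs)
  s_init <- sgn * cur
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    before <- cur
    # full-span sweeps first (escapes coupled-coefficient local minima),
    # then a shrinking bracket for refinement
    w <- span / 2^max(0, cycle - 2)
    # probe every coefficient from the current state and descend in order of
    # achievable improvement: the dominant aberration is corrected before
    # correlated lower-impact terms can absorb part of it
    probe <- vapply(seq_along(js), function(i) {
      min(vapply(coeffs[i] + seq(-w, w, length.out = 9), function(v) {
        cf <- coeffs; cf[i] <- v; metric(cf)
      }, numeric(1)))
    }, numeric(1))
    for (i in order(probe)) {
      f1 <- function(v) {
        cf <- coeffs; cf[i] <- v; metric(cf)
      }
      # coarse bracketing grid, then a local golden-section refinement around
      # the best grid node — robust against the shallow multi-minimum
      # landscape of sharpness metrics
      grid <- coeffs[i] + seq(-w, w, length.out = 9)
      vals <- vapply(grid, f1, numeric(1))
      gbest <- which.min(vals)
      lo <- grid[max(1, gbest - 1)]; hi <- grid[min(length(grid), gbest + 1)]
      opt <- stats::optimize(f1, interval = c(lo, hi))
      if (opt$objective < cur) {
        coeffs[i] <- opt$minimum
        cur <- opt$objective
      } else if (vals[gbest] < cur) {
        coeffs[i] <- grid[gbest]
        cur <- vals[gbest]
      }
    }
    if (before - cur < tol) break
  }
  phi <- matrix(0, nx, ny)
  for (i in seq_along(js)) phi <- phi + coeffs[i] * basis[[i]]
  img <- ifft2(G0 * exp(-1i * phi))
  list(image = img, coeffs = coeffs, entropy_initial = s_init,
       entropy_final = sgn * cur, cycles = cycles)
}
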