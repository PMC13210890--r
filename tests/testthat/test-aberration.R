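test_that("Noll ordering and Zernike normalization are standard", {
  nm <- noll_to_nm(1:10)
  expect_equal(nm[, 1], c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3))
  expect_equal(nm[, 2], c(0, 1, -1, 0, -2, 2, -1, 1, -3, 3))
  # RMS normalization over the unit disk: <Z_j^2> = 1 (Monte Carlo)
  set.seed(30)
  r <- sqrt(runif(2e5)); th <- runif(2e5, 0, 2 * pi)
  for (j in c(4, 5, 6, 11)) {
    expect_equal(mean(zernike_noll(j, r, th)^2), 1, tolerance = 0.02)
  }
  # defocus is radially symmetric, astigmatism changes sign under 90 deg
  expect_equal(zernike_noll(4, 0.5, 0), zernike_noll(4, 0.5, 1.3))
  expect_equal(zernike_noll(6, 0.5, 0), -zernike_noll(6, 0.5, pi / 2))
})

make_point_grid <- function(nx = 64, n = 40, seed = 2) {
  set.seed(seed)
  img <- matrix(0, nx, nx)
  img[cbind(sample(8:(nx - 8), n, TRUE), sample(8:(nx - 8), n, TRUE))] <- 1
  img
}

test_that("sub-aperture displacement estimates defocus with the right sign", {
  img <- make_point_grid()
  z <- seq(10, 60, 10)
  vol_of <- function(c4) {
    planes <- lapply(z, function(zz) apply_pupil_phase(img, c("4" = c4)))
    recon_volume(array(unlist(planes), dim = c(64, 64, length(z))), z)
  }
  # aberration-free: coefficient indistinguishable from zero
  d0 <- subaperture_defocus(recon_volume(
    array(rep(img + 0i, 6), c(64, 64, 6)), z))
  expect_lt(abs(d0$coefficient), 0.05)

  d_pos <- subaperture_defocus(vol_of(1.5))
  d_neg <- subaperture_defocus(vol_of(-1.5))
  expect_equal(d_pos$coefficient, 1.5, tolerance = 0.1 * 1.5)
  expect_equal(d_neg$coefficient, -d_pos$coefficient, tolerance = 0.02)

  expect_error(subaperture_defocus(recon_volume(
    array(0 + 0i, c(64, 64, 6)), z)), "signal")
})

test_that("entropy-driven Zernike correction recovers injected aberrations", {
  img <- make_point_grid(seed = 5)
  ab <- apply_pupil_phase(img, c("6" = 2))
  zc <- zernike_aberration_correct(ab, max_order = 4)
  expect_equal(zc$coeffs[["6"]], 2, tolerance = 0.15 * 2)
  expect_lt(zc$entropy_final, zc$entropy_initial)       # strictly sharper

  # oblique astigmatism too
  ab5 <- apply_pupil_phase(img, c("5" = -2))
  zc5 <- zernike_aberration_correct(ab5, max_order = 4)
  expect_equal(zc5$coeffs[["5"]], -2, tolerance = 0.15 * 2)

  # idempotence: a second pass changes nothing beyond the tolerance
  zc2 <- zernike_aberration_correct(zc$image, max_order = 4)
  expect_lt(max(abs(zc2$coeffs)), 0.05)

  # aberration-free input: coefficients stay near zero, entropy untouched
  zc0 <- zernike_aberration_correct(img + 0i, max_order = 3)
  expect_lt(max(abs(zc0$coeffs)), 0.1)
  expect_lt(abs(zc0$entropy_final - zc0$entropy_initial) /
              zc0$entropy_initial, 0.005)

  expect_error(zernike_aberration_correct(matrix(0, 16, 16)), "zero-energy")
  expect_error(zernike_aberration_correct(matrix(1, 16, 16)), "constant")
})
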