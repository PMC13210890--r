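test_that("depth reconstruction matches a direct Fourier-sum oracle", {
  set.seed(20)
  nx <- 8; ny <- 8; n_k <- 32
  ku <- seq(7.2, 7.8, length.out = n_k)          # uniform k: no resampling
  arr <- array(rnorm(nx * ny * n_k), c(nx, ny, n_k))
  st <- spectral_stack(arr - min(arr), ku)
  vol <- reconstruct_depth(st, pad_factor = 1, window = "none")
  m <- matrix(aperm(st$data, c(3, 1, 2)), nrow = n_k)
  oracle <- direct_depth_sum(m, n_k)
  got <- matrix(aperm(vol$data, c(3, 1, 2)), nrow = n_k %/% 2)
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(vol$z_axis[2] - vol$z_axis[1], pi / (n_k * diff(ku)[1]))
})

test_that("a single mirror reconstructs at its depth, stable under padding", {
  cfg <- tiny_config(nx = 16, ny = 16, n_k = 128)
  z0 <- 100
  ph <- mirror_phantom(cfg, z0 = z0)
  st <- remove_dc(acquire_volume(ph, cfg, phase_mask_ensemble(cfg, 1, "flat"))[[1]])
  v1 <- reconstruct_depth(st, pad_factor = 1)
  v2 <- reconstruct_depth(st, pad_factor = 2)
  pk1 <- v1$z_axis[which.max(Mod(v1$data[8, 8, ]))]
  pk2 <- v2$z_axis[which.max(Mod(v2$data[8, 8, ]))]
  dz1 <- v1$z_axis[2] - v1$z_axis[1]
  expect_lt(abs(pk1 - z0), dz1)                  # within a coarse bin
  expect_lt(abs(pk2 - pk1), dz1 / 2 + 1e-9)      # refined, not moved
  expect_equal(v2$z_axis[2] - v2$z_axis[1], dz1 / 2)
  # every lateral pixel peaks at the same bin
  pks <- apply(Mod(v2$data), c(1, 2), which.max)
  expect_true(all(pks == pks[1, 1]))

  bad <- st
  bad$k_axis <- sample(bad$k_axis)
  expect_error(reconstruct_depth(bad), "monotonic")
})

test_that("the real interferogram spectrum is Hermitian so half retention loses nothing", {
  cfg <- tiny_config(nx = 8, ny = 8, n_k = 64)
  ph <- mirror_phantom(cfg, z0 = 60)
  st <- remove_dc(acquire_volume(ph, cfg, phase_mask_ensemble(cfg, 1, "flat"))[[1]])
  sm <- stoct:::spectral_matrix(st)
  F <- stats::mvfft(sm$m)
  n <- nrow(F)
  expect_equal(F[2:(n / 2), ], Conj(F[n:(n / 2 + 2), ]), tolerance = 1e-9)
})

test_that("fixed-pattern filter flags injected tones and nothing else", {
  set.seed(21)
  # null volumes: false-positive rate below 0.1% of frequency pixels
  rates <- vapply(1:10, function(r) {
    arr <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
    mean(estimate_fixed_pattern_filter(arr)$notch_mask)
  }, numeric(1))
  expect_lt(mean(rates), 0.001)

  # a fixed sinusoidal pattern present in every plane is flagged (with its
  # point-symmetric mirror), removed > 60 dB, and other bins stay put
  arr <- array(rnorm(64 * 64 * 8, sd = 0.5), c(64, 64, 8))
  tone <- 2 * cos(2 * pi * 10 * (0:63) / 64)
  for (l in 1:8) arr[, , l] <- arr[, , l] + matrix(tone, 64, 64)
  flt <- estimate_fixed_pattern_filter(arr)
  expect_true(flt$notch_mask[11, 1] && flt$notch_mask[55, 1])
  # point symmetry is exact
  refl <- flt$notch_mask[c(1, 64:2), c(1, 64:2)]
  expect_identical(flt$notch_mask, refl)

  out <- apply_spatial_filter(arr, flt)
  g0 <- Mod(stoct:::fft2(arr[, , 1])); g1 <- Mod(stoct:::fft2(out[, , 1]))
  expect_lt(20 * log10((g1[11, 1] + 1e-300) / g0[11, 1]), -60)
  untouched <- abs(g1 - g0); untouched[flt$notch_mask] <- 0
  expect_lt(max(untouched / max(g0)), 0.01)
  # Parseval: energy removed equals the energy of the masked bins
  e_removed <- sum(arr[, , 1]^2) - sum(out[, , 1]^2)
  e_masked <- sum(g0[flt$notch_mask]^2) / (64 * 64)
  expect_equal(e_removed, e_masked, tolerance = 1e-9)

  # the empty filter is the identity
  empty <- structure(list(notch_mask = matrix(FALSE, 64, 64),
                          detection_params = list()),
                     class = "fixed_pattern_filter")
  expect_equal(apply_spatial_filter(arr, empty), arr, tolerance = 1e-12)
})

test_that("phase correctors are pure phase: spectral energy is conserved", {
  cfg <- tiny_config(nx = 8, ny = 8, n_k = 64)
  ph <- mirror_phantom(cfg, z0 = 60)
  st <- remove_dc(acquire_volume(ph, cfg, phase_mask_ensemble(cfg, 1, "flat"))[[1]])
  sm0 <- stoct:::spectral_matrix(st)
  fld <- apply_phase_corrector(st, phase_corrector(c(1.5, -6, 3, 0.2, -0.1)))
  e0 <- sum(Mod(sm0$m)^2)
  e1 <- sum(Mod(fld$data)^2)
  expect_equal(e1, e0, tolerance = 1e-9)
  expect_error(phase_corrector(c(NA, 1)), "finite")
})

test_that("kurtosis phase correction recovers injected dispersion", {
  cfg <- tiny_config(nx = 32, ny = 8, n_k = 256)
  ph <- mirror_phantom(cfg, z0 = 150, reflectivity = 0.7)
  st <- remove_dc(acquire_volume(ph, cfg, phase_mask_ensemble(cfg, 1, "flat"))[[1]])

  # inject a2 = -6, a3 = +3 (rad); recovery must find the compensating +6, -3
  inj <- phase_corrector(c(0, -6, 3, 0, 0))
  dispersed <- apply_phase_corrector(st, inj)
  res <- kurtosis_phase_correct(dispersed, pad_factor = 2)
  expect_equal(res$corrector$a[2], 6, tolerance = 0.1 * 6)
  expect_equal(res$corrector$a[3], -3, tolerance = 0.1 * 3)
  expect_gte(res$metric_final, res$metric_initial)

  # axial PSF restored within 10% of the dispersion-free width
  clean <- reconstruct_depth(st, pad_factor = 2)
  fw_clean <- stoct:::profile_fwhm(Mod(clean$data[16, 4, ]), clean$z_axis)
  fw_corr <- stoct:::profile_fwhm(Mod(res$volume$data[16, 4, ]),
                                  res$volume$z_axis)
  fw_disp <- {
    vd <- reconstruct_depth(dispersed, pad_factor = 2)
    stoct:::profile_fwhm(Mod(vd$data[16, 4, ]), vd$z_axis)
  }
  expect_gt(fw_disp, 1.3 * fw_clean)             # the injection really blurred
  expect_equal(fw_corr, fw_clean, tolerance = 0.1)
})

test_that("dispersion-free data keeps its corrector at zero", {
  cfg <- tiny_config(nx = 32, ny = 8, n_k = 256)
  ks <- sort(k_axis(cfg))
  dk <- (max(ks) - min(ks)) / (cfg$n_k - 1)
  z0 <- 64 * pi / (512 * dk) * 2                 # on a coarse depth bin
  ph <- mirror_phantom(cfg, z0 = z0, reflectivity = 0.7)
  st <- remove_dc(acquire_volume(ph, cfg, phase_mask_ensemble(cfg, 1, "flat"))[[1]])
  res <- kurtosis_phase_correct(st, pad_factor = 2)
  expect_true(all(abs(res$corrector$a) < 0.05))
  expect_lt(abs(res$metric_final / res$metric_initial - 1), 0.01)
})
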