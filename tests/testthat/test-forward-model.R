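test_that("mirror field carries the round-trip phase and Beer-Lambert attenuation", {
  cfg <- tiny_config(nx = 16, ny = 16, n_k = 32)
  ks <- k_axis(cfg)
  flat <- generate_phase_mask(cfg, "flat")

  # reflector at z = 0: phase identically zero
  ph0 <- mirror_phantom(cfg, z0 = 0, reflectivity = 0.8)
  f0 <- propagate_mirror(ph0, cfg, ks[3], flat)
  expect_equal(max(abs(Arg(f0$values))), 0, tolerance = 1e-12)
  expect_equal(Mod(f0$values[1, 1]), 0.8)

  # reflector at depth z0: uniform phase -2 k z0 (mod 2 pi)
  z0 <- 120
  ph1 <- mirror_phantom(cfg, z0 = z0)
  f1 <- propagate_mirror(ph1, cfg, ks[5], flat)
  expect_equal(max(abs(Arg(f1$values * exp(1i * 2 * ks[5] * z0)))), 0,
               tolerance = 1e-9)

  # two layers: amplitude ratio r2/r1 * exp(-2 mu1 d1), closed form
  m <- matrix(1, 16, 16)
  ph2 <- scattering_phantom(list(
    list(z_top = 0, thickness = 100, reflectivity_map = 0.5 * m,
         scattering_mu = 0.004, crosstalk_strength = 0),
    list(z_top = 150, thickness = 1, reflectivity_map = 0.8 * m,
         scattering_mu = 0, crosstalk_strength = 0)))
  la <- stoct:::layer_amplitudes(ph2, cfg)
  expect_equal(la$A[1, 2] / la$A[1, 1], 0.8 / 0.5 * exp(-2 * 0.004 * 100),
               tolerance = 1e-12)

  expect_error(propagate_mirror(ph1, cfg, 100, flat), "outside")
})

test_that("total field is the sum of mirror and crosstalk components", {
  cfg <- tiny_config(nx = 32, ny = 32, n_k = 8)
  k0 <- k_axis(cfg)[4]
  mask <- generate_phase_mask(cfg, "slm", seed = 2)
  ph <- scattering_phantom(list(list(
    z_top = 50, thickness = 40, reflectivity_map = matrix(0.6, 32, 32),
    scattering_mu = 0.01, crosstalk_strength = 1)))
  fm <- propagate_mirror(ph, cfg, k0, mask)
  fc <- propagate_crosstalk(ph, cfg, k0, mask)
  total <- complex_field(fm$values + fc$values, k0, "total")
  expect_equal(total$values, fm$values + fc$values)
  expect_true(all(is.finite(Mod(total$values))))
})

test_that("crosstalk realizations have the configured variance and decorrelate", {
  cfg <- tiny_config(nx = 128, ny = 128, n_k = 8)
  k0 <- k_axis(cfg)[1]
  ph <- diffuser_phantom(cfg, mu = 0.005, thickness = 150, strength = 1)
  v_target <- 1 * (1 - exp(-2 * 0.005 * 150))

  m1 <- generate_phase_mask(cfg, "slm", seed = 3)
  m2 <- generate_phase_mask(cfg, "slm", seed = 4)
  c1 <- propagate_crosstalk(ph, cfg, k0, m1)
  c2 <- propagate_crosstalk(ph, cfg, k0, m2)
  # law of large numbers: mean intensity within 5% at 128x128
  expect_equal(mean(Mod(c1$values)^2), v_target, tolerance = 0.05)
  # realizations under different masks are statistically independent
  rho <- abs(sum(Conj(c1$values) * c2$values)) /
    sqrt(sum(Mod(c1$values)^2) * sum(Mod(c2$values)^2))
  expect_lt(rho, 0.1)
  # same mask reproduces bit-identically
  c1b <- propagate_crosstalk(ph, cfg, k0, m1)
  expect_identical(c1$values, c1b$values)

  # zero strength gives the zero field
  ph0 <- diffuser_phantom(cfg, strength = 0)
  expect_true(all(propagate_crosstalk(ph0, cfg, k0, m1)$values == 0))
})

test_that("interferogram detection follows |Es + Er|^2 with the fringe oracle", {
  cfg <- tiny_config(nx = 16, ny = 16, n_k = 32)
  ks <- k_axis(cfg)
  flat <- generate_phase_mask(cfg, "flat")
  ref <- reference_field(cfg, ks[1], flat)

  # no sample field: intensity is |Er|^2 exactly, no fringes
  es0 <- complex_field(matrix(0 + 0i, 16, 16), ks[1], "total")
  expect_equal(record_interferogram(es0, ref, cfg),
               Mod(ref$values)^2, tolerance = 1e-14)

  # fully constructive: Es = Er gives 4 |Er|^2
  expect_equal(record_interferogram(ref, ref, cfg), 4 * Mod(ref$values)^2)

  # mirror at z0: fringe along k equals 2 A R cos(2 k z0), per-pixel oracle
  z0 <- 80; A <- 0.6; R <- cfg$ref_amplitude
  ph <- mirror_phantom(cfg, z0 = z0, reflectivity = A)
  st <- acquire_volume(ph, cfg, list(flat))[[1]]
  fringe <- st$data[4, 9, ] - (A^2 + R^2)
  expect_equal(fringe, 2 * A * R * cos(2 * ks * z0), tolerance = 1e-9)

  bad <- complex_field(matrix(0 + 0i, 8, 8), ks[1], "total")
  expect_error(record_interferogram(bad, ref, cfg), "grids differ")
})

test_that("acquisition modes agree and are deterministic", {
  cfg <- tiny_config(nx = 16, ny = 16, n_k = 16)
  ph <- scattering_phantom(list(list(
    z_top = 40, thickness = 30, reflectivity_map = matrix(0.5, 16, 16),
    scattering_mu = 0.01, crosstalk_strength = 0.5)))
  masks <- phase_mask_ensemble(cfg, 4, kind = "slm", base_seed = 9)

  seq_stacks <- acquire_volume(ph, cfg, masks, mode = "sequential")
  cam <- acquire_volume(ph, cfg, masks, mode = "camera_integrated")
  manual <- Reduce(`+`, lapply(seq_stacks, function(s) s$data)) / 4
  expect_equal(cam$data, manual, tolerance = 1e-14)
  expect_identical(cam$mask_id, "integrated")

  # a single flat mask: both modes coincide
  flat <- phase_mask_ensemble(cfg, 1, kind = "flat")
  s1 <- acquire_volume(ph, cfg, flat, mode = "sequential")[[1]]
  s2 <- acquire_volume(ph, cfg, flat, mode = "camera_integrated")
  expect_equal(s1$data, s2$data, tolerance = 1e-14)

  # bit-identical reruns under identical seeds
  rerun <- acquire_volume(ph, cfg, masks, mode = "sequential")
  expect_identical(seq_stacks[[1]]$data, rerun[[1]]$data)
  expect_identical(seq_stacks[[4]]$data, rerun[[4]]$data)

  expect_error(acquire_volume(ph, cfg, list()), "at least one mask")
})

test_that("mask phase cancels in the mirror fringe for illumination-side modulation", {
  cfg <- tiny_config(nx = 16, ny = 16, n_k = 16)
  ph <- mirror_phantom(cfg, z0 = 60)
  masks <- phase_mask_ensemble(cfg, 3, kind = "slm", base_seed = 5)
  stacks <- acquire_volume(ph, cfg, masks)
  expect_equal(stacks[[1]]$data, stacks[[2]]$data, tolerance = 1e-12)
  expect_equal(stacks[[2]]$data, stacks[[3]]$data, tolerance = 1e-12)
  # object-arm modulation does NOT cancel: interferograms differ across masks
  obj <- acquire_volume(ph, cfg, masks, mask_arm = "object")
  expect_gt(max(abs(obj[[1]]$data - obj[[2]]$data)), 0.1)
})
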