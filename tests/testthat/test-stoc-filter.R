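test_that("stack averaging is the arithmetic mean with matched axes", {
  cfg <- tiny_config(n_k = 16)
  ph <- mirror_phantom(cfg, z0 = 60)
  masks <- phase_mask_ensemble(cfg, 3, kind = "slm")
  stacks <- acquire_volume(ph, cfg, masks)

  one <- average_stacks(stacks[1])
  expect_equal(one$data, stacks[[1]]$data)
  same <- average_stacks(list(stacks[[1]], stacks[[1]], stacks[[1]]))
  expect_equal(same$data, stacks[[1]]$data)

  other <- stacks[[2]]
  other$k_axis <- other$k_axis * 1.01
  expect_error(average_stacks(list(stacks[[1]], other)), "k_axis")
  expect_error(average_stacks(list()), "empty")
})

test_that("DC removal keeps the fringe and kills the offset", {
  cfg <- tiny_config(nx = 8, ny = 8, n_k = 64)
  ks <- k_axis(cfg)
  # constant-in-k stack -> zeros under mean subtraction
  const <- spectral_stack(array(3, c(8, 8, 64)), ks)
  expect_equal(max(abs(remove_dc(const)$data)), 0)

  # offset + fringe: mean_subtract leaves the fringe untouched
  z0 <- 80
  fringe <- 2 * cos(2 * ks * z0)
  st <- spectral_stack(aperm(array(rep(5 + fringe, 64), c(64, 8, 8)), c(2, 3, 1)), ks)
  out <- remove_dc(st)
  expect_lt(abs(mean(out$data[1, 1, ])), 1e-9 * stats::sd(out$data[1, 1, ]))
  expect_equal(out$data[1, 1, ], fringe - mean(fringe), tolerance = 1e-12)

  # highpass: offset suppressed > 40 dB, single-tone fringe within 1%
  hp <- remove_dc(st, method = "highpass", cutoff_fraction = 0.02)
  expect_lt(abs(mean(hp$data[1, 1, ])) / 5, 10^(-40 / 20))
  proj <- 2 * abs(mean(hp$data[1, 1, ] * exp(2i * ks * z0)))
  expect_equal(proj, 2, tolerance = 0.01)

  expect_error(remove_dc(st, method = "highpass", cutoff_fraction = 0.7),
               "cutoff_fraction")
})

test_that("averaging commutes with mean-subtract DC removal", {
  cfg <- tiny_config(n_k = 16)
  ph <- scattering_phantom(list(list(
    z_top = 30, thickness = 40, reflectivity_map = matrix(0.4, 16, 16),
    scattering_mu = 0.01, crosstalk_strength = 1)))
  stacks <- acquire_volume(ph, cfg, phase_mask_ensemble(cfg, 4, "slm"))
  a <- remove_dc(average_stacks(stacks))$data
  b <- average_stacks(lapply(stacks, remove_dc))$data
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("mask averaging preserves the mirror fringe and suppresses crosstalk as 1/sqrt(M)", {
  cfg <- tiny_config(nx = 32, ny = 32, n_k = 48)
  # mirror preservation across the ensemble (no crosstalk)
  phm <- mirror_phantom(cfg, z0 = 60)
  masks <- phase_mask_ensemble(cfg, 8, kind = "membrane", base_seed = 2)
  stacks <- acquire_volume(phm, cfg, masks)
  avg <- average_stacks(stacks)
  a0 <- stoct:::fringe_band_rms(stacks[[1]])
  a1 <- stoct:::fringe_band_rms(avg)
  expect_lt(abs(a1 - a0) / a0, 1e-6)

  # crosstalk-only ensemble: fitted log-log slope of residual RMS vs M
  ph <- diffuser_phantom(cfg, mu = 0.005, thickness = 150)
  Ms <- c(4, 16, 64)
  rms <- matrix(0, 5, length(Ms))
  for (r in 1:5) {
    ms <- phase_mask_ensemble(cfg, max(Ms), kind = "slm", base_seed = 100 * r)
    dat <- lapply(acquire_volume(ph, cfg, ms), function(s) s$data)
    for (j in seq_along(Ms)) {
      st <- spectral_stack(pmax(Reduce(`+`, dat[1:Ms[j]]) / Ms[j], 0), k_axis(cfg))
      rms[r, j] <- stoct:::fringe_band_rms(st)
    }
  }
  slope <- stats::coef(stats::lm(log(colMeans(rms)) ~ log(Ms)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.05)
})

test_that("suppression metrics report the mode-count attenuation factor", {
  cfg <- tiny_config(nx = 32, ny = 32, n_k = 16)
  ph <- diffuser_phantom(cfg, mu = 0.02, thickness = 40)
  zero <- spectral_stack(array(0, c(32, 32, 16)), k_axis(cfg))

  # a single mask: suppression factor is exactly 1
  m1 <- phase_mask_ensemble(cfg, 1, kind = "slm", base_seed = 4)
  s1 <- acquire_volume(ph, cfg, m1)[[1]]
  rep1 <- suppression_metrics(average_stacks(list(s1)), zero, s1, n_masks = 1)
  expect_equal(rep1$suppression_factor, 1)

  # crosstalk-free input: residual is identically zero
  phm <- mirror_phantom(cfg, z0 = 30)
  sm <- acquire_volume(phm, cfg, m1)[[1]]
  repm <- suppression_metrics(sm, sm, sm, n_masks = 1)
  expect_equal(repm$residual_crosstalk_rms, 0)

  # averaging over the guided-mode count of the reference fiber attenuates
  # crosstalk by about sqrt(N) ~ 29
  N <- guided_mode_count(fiber_spec())$n_int
  sf <- vapply(1:2, function(r) {
    masks <- phase_mask_ensemble(cfg, N, kind = "slm", base_seed = 5000 + r)
    stacks <- acquire_volume(ph, cfg, masks)
    rep <- suppression_metrics(average_stacks(stacks), zero, stacks, n_masks = N)
    rep$suppression_factor
  }, numeric(1))
  expect_equal(mean(sf), 29, tolerance = 0.15)
})
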