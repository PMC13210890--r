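test_that("pixel linearization maps (n, m) to n + m*N and back", {
  lin <- linearize(4, 4)
  expect_identical(lin$forward(2, 1), 6)
  expect_equal(unname(lin$inverse(6)), matrix(c(2, 1), 1))
  lin9 <- linearize(3, 3)
  chi <- lin9$forward(rep(0:2, 3), rep(0:2, each = 3))
  expect_equal(sort(chi), 0:8)                    # K = 9, all distinct
  nm <- lin9$inverse(chi)
  expect_identical(lin9$forward(nm[, "n"], nm[, "m"]), chi)
})

test_that("build_G matches the brute-force pairwise definition and is Hermitian", {
  set.seed(10)
  d <- c(5, 4, 24)
  arr <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  G <- build_G(arr)
  expect_equal(G$gamma, brute_force_G(arr), tolerance = 1e-12)
  expect_equal(G$gamma, Conj(t(G$gamma)), tolerance = 1e-12)
  expect_equal(unname(Mod(diag(G$gamma))), rep(1, 20), tolerance = 1e-12)
  expect_true(all(Mod(G$gamma) <= 1 + 1e-9))
})

test_that("coherent waveforms give unit coherence; independent noise gives the null level", {
  # all pixels carry the identical waveform -> |gamma| = 1 everywhere
  set.seed(11)
  wave <- complex(real = rnorm(64), imaginary = rnorm(64))
  arr <- array(rep(wave, each = 9), c(3, 3, 64))
  G <- build_G(arr)
  expect_equal(Mod(G$gamma), matrix(1, 9, 9), tolerance = 1e-12)

  # independent white noise, T = 1024: off-diagonal magnitudes follow the
  # null distribution with mean ~ sqrt(pi/4)/sqrt(T)
  d <- c(4, 4, 1024)
  arr2 <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  G2 <- build_G(arr2)
  off <- Mod(G2$gamma)[upper.tri(G2$gamma)]
  expect_equal(mean(off), sqrt(pi / 4) / sqrt(1024), tolerance = 0.15)
  expect_lt(max(off), 5 / sqrt(1024))
})

test_that("zero-energy pixels are masked, not reported as incoherent", {
  set.seed(12)
  arr <- array(complex(real = rnorm(4 * 4 * 32),
                       imaginary = rnorm(4 * 4 * 32)), c(4, 4, 32))
  arr[2, 3, ] <- 0
  G <- build_G(arr)
  idx <- linearize(4, 4)$forward(1, 2) + 1       # 1-based position
  expect_true(G$masked[idx])
  expect_true(all(Mod(G$gamma[idx, ]) == 0))
  expect_error(build_G(arr[, , 1, drop = FALSE]), "at least 2")
})

test_that("diagonality separates diagonal from uniform matrices", {
  mk <- function(g) {
    structure(list(gamma = g, masked = rep(FALSE, nrow(g)),
                   roi = NULL, tau = 0), class = "coherence_matrix")
  }
  expect_identical(diagonality(mk(diag(8) + 0i)), Inf)
  expect_equal(diagonality(mk(matrix(1 + 0i, 8, 8))), 1)
})

test_that("STOC mask ensembles diagonalize G relative to coherent illumination", {
  cfg <- tiny_config(nx = 16, ny = 16, n_k = 8)
  k0 <- k_axis(cfg)[4]
  ph <- scattering_phantom(list(
    list(z_top = 0, thickness = 150, reflectivity_map = matrix(0, 16, 16),
         scattering_mu = 0.001, crosstalk_strength = 1),
    list(z_top = 160, thickness = 1, reflectivity_map = matrix(1, 16, 16),
         scattering_mu = 0, crosstalk_strength = 0)))
  fields <- function(kind, n) {
    masks <- phase_mask_ensemble(cfg, n, kind = kind, base_seed = 21,
                                 correlation_length = 2)
    arr <- array(0 + 0i, c(16, 16, n))
    for (i in seq_len(n)) {
      arr[, , i] <- propagate_mirror(ph, cfg, k0, masks[[i]])$values +
        propagate_crosstalk(ph, cfg, k0, masks[[i]])$values
    }
    arr
  }
  d64 <- diagonality(build_G(fields("slm", 64)))
  d128 <- diagonality(build_G(fields("slm", 128)))
  dcoh <- diagonality(build_G(fields("flat", 128)))
  expect_gt(d64, dcoh)
  expect_gt(d128, d64)            # more masks, more diagonal
})

test_that("modified-Rician fit recovers known parameter mixes", {
  set.seed(13)
  # fully developed speckle: exponential law, I_d ~ 0, sigma2 ~ mean
  x <- stats::rexp(1e5)
  f <- fit_rician(x)
  expect_lt(f$i_det, 0.05)
  expect_equal(f$sigma_n2, 1, tolerance = 0.05)
  expect_true(f$converged)

  # deterministic + weak circular noise
  y <- Mod(sqrt(0.9) + complex(real = rnorm(1e5, sd = sqrt(0.05)),
                               imaginary = rnorm(1e5, sd = sqrt(0.05))))^2
  g <- fit_rician(y)
  expect_equal(g$i_det, 0.9, tolerance = 0.1)
  # fitted mean matches the sample mean (moment identity of the law)
  expect_equal(g$i_det + g$sigma_n2, mean(y), tolerance = 0.02)

  expect_error(fit_rician(c(-1, x[1:300])), "negative")
  expect_error(fit_rician(x[1:100]), "at least 200")
})
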