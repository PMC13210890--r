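# Shared fixtures: small configurations and phantoms built in code.

tiny_config <- function(nx = 16, ny = 16, n_k = 8, ...) {
  optical_config(nx = nx, ny = ny, n_k = n_k, pixel_pitch_obj = 2,
                 na_ill = 0.1, na_det = 0.2, ...)
}

# single perfect reflector at depth z0 (µm), no scattering
mirror_phantom <- function(config, z0 = 100, reflectivity = 0.8) {
  scattering_phantom(list(list(
    z_top = z0, thickness = 1,
    reflectivity_map = matrix(reflectivity, config$nx, config$ny),
    scattering_mu = 0, crosstalk_strength = 0)))
}

# crosstalk-only diffuser (no reflecting structure)
diffuser_phantom <- function(config, mu = 0.005, thickness = 150,
                             strength = 1) {
  scattering_phantom(list(list(
    z_top = 0, thickness = thickness,
    reflectivity_map = matrix(0, config$nx, config$ny),
    scattering_mu = mu, crosstalk_strength = strength)))
}

# brute-force complex degree of coherence, straight from the definition
brute_force_G <- function(fields_array) {
  d <- dim(fields_array)
  K <- d[1] * d[2]
  E <- matrix(aperm(fields_array, c(3, 1, 2)), nrow = d[3])
  g <- matrix(0 + 0i, K, K)
  en <- colSums(Mod(E)^2)
  for (j in seq_len(K)) {
    for (k in seq_len(K)) {
      g[j, k] <- sum(Conj(E[, j]) * E[, k]) / sqrt(en[j] * en[k])
    }
  }
  g
}

# direct discrete-Fourier-sum A-scan oracle for a (n_k x npix) matrix on a
# uniform k grid: matches depth_transform with window = "none"
direct_depth_sum <- function(m, n_pad) {
  n_k <- nrow(m)
  nz <- n_pad %/% 2
  out <- matrix(0 + 0i, nz, ncol(m))
  for (mm in seq_len(nz)) {
    w <- exp(-2i * pi * (mm - 1) * (seq_len(n_k) - 1) / n_pad)
    out[mm, ] <- colSums(m * w)
  }
  out
}
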