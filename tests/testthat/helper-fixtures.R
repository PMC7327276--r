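# Shared fixtures: the solid-phantom media (mu_a = 0.1056 cm^-1,
# mu_s' = 2.529 cm^-1 at 680 nm) in its isotropic and anisotropic
# parameterizations, and the apple-tissue parameter set.

phantom_iso <- function() media_optics(0.1056, 2.529, 0, 1.35)
phantom_aniso <- function() media_optics(0.1056, 25.29, 0.9, 1.35)
apple_media <- function() media_optics(0.63, 30, 0, 1.4)

phantom_config <- function(photons = 1e4, seed = 1, rpx = 0.05, ...) {
  simulation_config(photons = photons, beam_radius = 0.05, limit = 1e-9,
                    obs_radius = 3, rpx = rpx, seed = seed, ...)
}

# analytic Henyey-Greenstein CDF of the deflection cosine
hg_cdf <- function(x, g) {
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * x) - 1 / (1 + g))
}

# deflection cosines observed by repeatedly scattering a +z photon
# (the near-vertical update returns w = cos(theta) directly)
sample_deflections <- function(g, n, seed = 42) {
  rmu <- stream_uniforms(seed, "rmu", 1, n)
  rx <- stream_uniforms(seed, "rx", 1, 4L * n)
  pos <- 0L
  out <- numeric(n)
  base <- list(x = 0, y = 0, z = 1, u = 0, v = 0, w = 1,
               weight = 1, alive = TRUE)
  for (i in seq_len(n)) {
    idx <- seq.int(pos + 1L, length(rx), by = 2L)
    st <- scatter_photon(base, g, rmu[i], 2 * rx[idx] - 1,
                         2 * rx[idx + 1L] - 1)
    pos <- pos + 2L * attr(st, "pairs_used")
    out[i] <- st$w
  }
  out
}
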