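make_state <- function(...) {
  modifyList(list(x = 0, y = 0, z = 0.1, u = 0, v = 0, w = 1,
                  weight = 1, event_index = 0L, alive = TRUE),
             list(...))
}

test_that("launch: oblique entry direction, specular deduction, elliptic footprint", {
  cfg <- simulation_config(photons = 10, beam_radius = 0.05, seed = 2)
  med <- apple_media()
  d <- derive_optics(med, cfg)
  streams <- launch_streams(cfg)

  b0 <- refraction_angle(0, med$n)
  s0 <- launch_photon(3, b0, streams, d)
  expect_equal(c(s0$u, s0$v, s0$w), c(0, 0, 1))
  expect_equal(s0$weight, 1 - (0.4 / 2.4)^2)
  expect_equal(s0$z, 0)
  # circular footprint at normal incidence
  expect_equal(sqrt(s0$x^2 + s0$y^2), streams$rbr[3])

  b15 <- refraction_angle(15, med$n)
  s15 <- launch_photon(3, b15, streams, d)
  expect_equal(b15$phi2 * 180 / pi, 10.65, tolerance = 1e-3)
  expect_equal(s15$w, cos(b15$phi2), tolerance = 1e-12)
  expect_equal(s15$w, 0.9828, tolerance = 1e-4)
  expect_equal(s15$u, 0)
  expect_equal(s15$v, sin(b15$phi2))
  # y stretched by 1/cos(phi2), x unchanged
  expect_equal(s15$x, s0$x)
  expect_equal(s15$y, s0$y * b15$stretch)
  expect_equal(b15$stretch, 1.0175, tolerance = 1e-4)
})

test_that("launch footprint variance ratio matches the elliptic distortion", {
  cfg <- simulation_config(photons = 1e5, beam_radius = 0.05, seed = 8)
  b <- refraction_angle(20, 1.4)
  ls <- launch_streams(cfg)
  x <- ls$rbr * cos(ls$rba)
  y <- ls$rbr * sin(ls$rba) / cos(b$phi2)
  ratio <- var(y) / var(x)
  expect_equal(ratio, 1 / cos(b$phi2)^2, tolerance = 0.05)
})

test_that("move: exponential free path with guarded draw", {
  mu_t <- 30.63
  s <- make_state(z = 1)
  s2 <- move_photon(s, exp(-1), mu_t)
  expect_equal(s2$z - s$z, 1 / mu_t)
  # guarded away from log(0)
  s3 <- move_photon(make_state(z = 1), 0, mu_t)
  expect_true(is.finite(s3$z))
  # mean step over many draws is 1/mu_t (3 SE band; exponential sd = mean)
  xi <- stream_uniforms(4, "rmv", 1, 2e4)
  steps <- -log(pmax(xi, 2^-53)) / mu_t
  expect_lt(abs(mean(steps) - 1 / mu_t), 3 * sd(steps) / sqrt(length(steps)))
  # downward photon far from surface stays inside
  s4 <- move_photon(make_state(z = 5, w = 0.5), 0.5, mu_t)
  expect_gte(s4$z, 0)
})

test_that("bounce: matched boundary releases the full weight", {
  cfg <- simulation_config(photons = 1, rpx = 0.05, obs_radius = 3)
  med <- media_optics(0.5, 5, 0, 1)
  d <- derive_optics(med, cfg)
  acc <- flux_accumulator(cfg)
  s <- make_state(x = 0.3, y = 0.4, z = -0.01, w = -0.6, u = 0.8, weight = 0.9)
  s2 <- bounce_photon(s, d, acc, cfg$rpx, med$n)
  expect_equal(s2$z, 0.01)
  expect_equal(s2$w, 0.6)
  expect_equal(acc$rd, 0.9)              # rf = 0 at n = 1
  expect_equal(s2$weight, 0)
  # Lambertian factor equals the internal cosine when n = 1
  k <- round(0.5 / 0.05) + 1
  expect_equal(acc$heat[k], 0.6 * 0.9)
})

test_that("bounce: total internal reflection below the critical angle", {
  cfg <- simulation_config(photons = 1, rpx = 0.05)
  med <- phantom_iso()  # n = 1.35, cos(critical) = 0.6718
  d <- derive_optics(med, cfg)
  acc <- flux_accumulator(cfg)
  s <- make_state(z = -0.02, w = -0.5, u = sqrt(1 - 0.25), weight = 0.8)
  s2 <- bounce_photon(s, d, acc, cfg$rpx, med$n)
  expect_equal(s2$weight, 0.8)
  expect_equal(acc$rd, 0)
  expect_equal(sum(acc$heat), 0)
  expect_equal(s2$w, 0.5)
})

test_that("bounce: normal exit uses the normal-incidence Fresnel coefficient", {
  cfg <- simulation_config(photons = 1, rpx = 0.05)
  med <- phantom_iso()
  d <- derive_optics(med, cfg)
  acc <- flux_accumulator(cfg)
  s <- make_state(x = 0.1, y = 0, z = -0.001, w = -1, weight = 1)
  s2 <- bounce_photon(s, d, acc, cfg$rpx, med$n)
  rf <- ((1 - 1.35) / (1 + 1.35))^2  # both polarizations equal
  expect_equal(acc$rd, 1 - rf)
  expect_equal(rf, 0.02218, tolerance = 1e-3)
  # lcc = 1 for normal exit: ring deposit equals the escaped weight
  expect_equal(acc$heat[round(0.1 / 0.05) + 1], 1 - rf)
  expect_equal(s2$weight, rf)
})

test_that("bounce rejects a photon that has not crossed the surface", {
  cfg <- simulation_config(photons = 1)
  d <- derive_optics(phantom_iso(), cfg)
  acc <- flux_accumulator(cfg)
  expect_error(bounce_photon(make_state(z = 0.1), d, acc, cfg$rpx, 1.35),
               "z >= 0")
})

test_that("absorb: implicit capture and deterministic termination", {
  cfg <- simulation_config(photons = 1, limit = 1e-9)
  d <- derive_optics(apple_media(), cfg)
  acc <- flux_accumulator(cfg)
  s <- absorb_photon(make_state(weight = 1), d, acc, cfg$limit)
  expect_equal(s$weight, 30 / 30.63)
  expect_equal(acc$absorbed, 1 - 30 / 30.63)
  expect_true(s$alive)
  # termination transfers the residual weight
  acc2 <- flux_accumulator(cfg)
  s2 <- absorb_photon(make_state(weight = 1e-9), d, acc2, cfg$limit)
  expect_false(s2$alive)
  expect_equal(acc2$absorbed, 1e-9)
  # after maxlen events the weight is necessarily below the limit
  expect_lte((30 / 30.63)^998, 1e-9)
})

test_that("scatter: isotropic deflection, preserved norm, HG mean", {
  # g = 0: cos(theta) = 2 rmu - 1
  s <- make_state(w = 1)
  out <- scatter_photon(s, 0, 0.75, 0.3, 0.4)
  expect_equal(out$w, 0.5)
  # direction norm preserved across random cases, tilted and vertical
  set.seed(1)
  for (i in 1:200) {
    w <- runif(1, -1, 1)
    den <- sqrt(1 - w^2)
    phi <- runif(1, 0, 2 * pi)
    st0 <- make_state(u = den * cos(phi), v = den * sin(phi), w = w)
    out <- scatter_photon(st0, 0.9, runif(1), runif(20, -1, 1),
                          runif(20, -1, 1))
    expect_equal(out$u^2 + out$v^2 + out$w^2, 1, tolerance = 1e-9)
  }
  # sample mean of the HG deflection cosine equals g (3 SE band)
  ct <- sample_deflections(0.9, 2e4, seed = 6)
  expect_lt(abs(mean(ct) - 0.9), 3 * sd(ct) / sqrt(length(ct)))
})

test_that("scatter consumes azimuth pairs by rejection", {
  s <- make_state(w = 1)
  # first pair outside the unit disk, second inside
  out <- scatter_photon(s, 0, 0.5, c(0.9, 0.6), c(0.9, 0))
  expect_equal(attr(out, "pairs_used"), 2L)
  expect_error(scatter_photon(s, 0, 0.5, 0.99, 0.99), "exhausted")
})

test_that("HG sampling matches the analytic CDF (Kolmogorov-Smirnov)", {
  g <- 0.9
  ct <- sample_deflections(g, 1e5, seed = 13)
  ks <- suppressWarnings(stats::ks.test(ct, function(x) hg_cdf(x, g)))
  expect_gt(ks$p.value, 0.01)
})

test_that("compiled kernel and R reference tracer agree exactly", {
  med <- phantom_iso()
  for (ang in c(0, 15)) {
    cfg <- phantom_config(photons = 40, seed = 7, angle_deg = ang)
    a <- run_simulation(med, cfg, engine = "cpp")
    b <- run_simulation(med, cfg, engine = "r")
    expect_identical(a$heat, b$heat)
    expect_identical(a$rd, b$rd)
    expect_identical(a$absorbed, b$absorbed)
    expect_identical(a$specular, b$specular)
  }
  # anisotropic medium exercises the HG branch and local-frame rotation
  cfga <- phantom_config(photons = 12, seed = 3)
  a <- run_simulation(phantom_aniso(), cfga, engine = "cpp")
  b <- run_simulation(phantom_aniso(), cfga, engine = "r")
  expect_identical(a$heat, b$heat)
  expect_identical(a$rd, b$rd)
})

test_that("energy is conserved: specular + rd + absorbed = launched weight", {
  for (med in list(phantom_iso(), apple_media(),
                   media_optics(2, 8, 0.7, 1.5))) {
    cfg <- phantom_config(photons = 3000, seed = 11)
    res <- run_simulation(med, cfg)
    eb <- energy_balance(res)
    expect_lt(abs(eb$residual_rel), 1e-6)
    expect_equal(res$n_truncated, 0)
    expect_true(all(res$heat >= 0))
    expect_lte(sum(res$heat), res$rd)  # Lambertian factor <= 1
  }
})

test_that("conservative matched-boundary limit: rd approaches 1", {
  # boundary absorption scales like sqrt(mu_a / mu_s'), so rd -> 1 as
  # mu_a -> 0: at mu_a = 1e-4 mu_s about 2.5% is still absorbed, at
  # mu_a = 1e-6 mu_s under 1%
  cfg <- simulation_config(photons = 2000, beam_radius = 0.05,
                           obs_radius = 3, rpx = 0.05, seed = 5)
  res4 <- run_simulation(media_optics(1e-3, 10, 0, 1), cfg)
  res6 <- run_simulation(media_optics(1e-5, 10, 0, 1), cfg)
  expect_equal(res4$specular, 0)
  expect_gt(res4$rd / cfg$photons, 0.95)
  expect_gt(res6$rd / cfg$photons, res4$rd / cfg$photons)
  expect_gt(res6$rd / cfg$photons, 0.99)
})

test_that("absorbing limit: almost nothing escapes", {
  med <- media_optics(50, 0.5, 0, 1.4)
  cfg <- simulation_config(photons = 1000, beam_radius = 0.05,
                           obs_radius = 3, rpx = 0.05, seed = 5)
  res <- run_simulation(med, cfg)
  expect_lt(res$rd / cfg$photons, 0.02)
})

test_that("diffuse reflectance is monotone in the transport albedo", {
  mus <- 10
  rd_at <- function(mu_a, seed) {
    cfg <- simulation_config(photons = 3000, beam_radius = 0.05,
                             obs_radius = 2, rpx = 0.05, seed = seed)
    run_simulation(media_optics(mu_a, mus, 0, 1.4), cfg)$rd
  }
  for (seed in 1:3) {
    rds <- c(rd_at(3, seed), rd_at(1, seed), rd_at(0.2, seed))
    expect_true(all(diff(rds) > 0))
  }
})

test_that("runs are reproducible for a fixed seed and change with it", {
  med <- phantom_iso()
  a <- run_simulation(med, phantom_config(photons = 500, seed = 21))
  b <- run_simulation(med, phantom_config(photons = 500, seed = 21))
  expect_identical(a$heat, b$heat)
  expect_identical(a$rd, b$rd)
  c <- run_simulation(med, phantom_config(photons = 500, seed = 22))
  expect_false(identical(a$heat, c$heat))
})

test_that("zero photons yield an empty accumulator", {
  res <- run_simulation(phantom_iso(), phantom_config(photons = 0))
  expect_equal(sum(res$heat), 0)
  expect_equal(res$rd, 0)
  expect_equal(res$absorbed, 0)
  expect_equal(res$specular, 0)
})

test_that("roulette mode conserves energy in expectation and runs to completion", {
  med <- phantom_iso()
  cfg <- phantom_config(photons = 2000, seed = 17)
  det <- run_simulation(med, cfg)
  rr <- run_simulation(med, cfg, roulette = TRUE)
  # unbiased within a few percent of the deterministic-cutoff estimate
  expect_equal(rr$rd / cfg$photons, det$rd / cfg$photons, tolerance = 0.05)
  a <- run_simulation(med, cfg, roulette = TRUE)
  expect_identical(a$heat, rr$heat)
})
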