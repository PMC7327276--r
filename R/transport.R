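# Photon transport: launch, move, bounce, absorb, scatter.
#
# The R functions below are a plain, step-by-step implementation used for
# unit testing and as a reference tracer; run_simulation() dispatches to
# the compiled kernel by default, which consumes the same random
# substreams in the same order and produces identical tallies.

.mcbs_min_unif <- 2^-53  # smallest positive draw on the uniform grid

.mcbs_nbin <- function(cfg) 1L + as.integer(round(cfg$obs_radius / cfg$rpx))

#' Flux accumulator
#'
#' Mutable tally of one simulation run: `heat` is the per-ring escaped
#' weight (ring `k` is centred at radius `(k-1) * rpx`, `k = 1` at the
#' incident point), `rd` the total diffuse reflectance (all escaped
#' weight, Lambertian-unweighted, including escapes beyond the observed
#' radius), `absorbed` the weight deposited in the medium, and `specular`
#' the weight lost to specular reflection at launch.
#'
#' @param cfg A [simulation_config()] object.
#' @return An environment of class `flux_accumulator`.
#' @export
flux_accumulator <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  acc <- new.env(parent = emptyenv())
  acc$heat <- numeric(.mcbs_nbin(cfg))
  acc$rd <- 0
  acc$absorbed <- 0
  acc$specular <- 0
  acc$n_truncated <- 0
  class(acc) <- "flux_accumulator"
  acc
}

#' Launch a photon into the medium
#'
#' Starts a trajectory on the surface. The initial weight is `1 - rs`
#' (specular loss deducted once at launch); the direction is the
#' refracted beam direction `(0, sin(phi2), cos(phi2))` in the y-z tilt
#' plane; and the start position is drawn uniformly over the beam disk,
#' with the y coordinate divided by `cos(phi2)` so that the footprint is
#' the ellipse the tilted beam paints on the surface.
#'
#' @param photon_index 1-based photon index.
#' @param beam A [refraction_angle()] result.
#' @param streams A [launch_streams()] result.
#' @param derived A [derive_optics()] result.
#' @return A photon state: list with `x, y, z` (cm), direction cosines
#'   `u, v, w`, `weight`, `event_index` and `alive`.
#' @export
launch_photon <- function(photon_index, beam, streams, derived) {
  rbr <- streams$rbr[photon_index]
  rba <- streams$rba[photon_index]
  list(x = rbr * cos(rba),
       y = rbr * sin(rba) / cos(beam$phi2),
       z = 0,
       u = 0, v = sin(beam$phi2), w = cos(beam$phi2),
       weight = 1 - derived$rs,
       event_index = 0L,
       alive = TRUE)
}

#' Propagate a photon by one free path
#'
#' Step length `s = -log(xi) / mu_t` with the draw guarded away from
#' zero. If the new `z` is negative the photon has crossed the surface
#' and [bounce_photon()] must be invoked before anything else.
#'
#' @param state Photon state.
#' @param rmv_value Uniform draw on `[0, 1)`.
#' @param mu_t Total attenuation coefficient `mu_a + mu_s`, cm^-1.
#' @return Updated photon state.
#' @export
move_photon <- function(state, rmv_value, mu_t) {
  xi <- if (rmv_value < .mcbs_min_unif) .mcbs_min_unif else rmv_value
  s <- -log(xi) / mu_t
  state$x <- state$x + s * state$u
  state$y <- state$y + s * state$v
  state$z <- state$z + s * state$w
  state
}

#' Surface interaction of an escaping photon
#'
#' Called when a move has carried the photon across the surface
#' (`z < 0`, `w < 0`). The position and direction are mirrored back into
#' the medium. If the internal angle is steeper than the critical angle
#' the photon is totally internally reflected and nothing else happens.
#' Otherwise the Fresnel-transmitted fraction of the weight escapes: it
#' is added to `rd`, and — attenuated by the Lambertian factor, the
#' cosine of the external exit angle, modelling a camera on the surface
#' normal — to the ring of the current radius if that ring lies within
#' the observed area. The photon continues inside with the reflected
#' remainder of its weight.
#'
#' @param state Photon state with `z < 0`.
#' @param derived A [derive_optics()] result.
#' @param acc A [flux_accumulator()]; updated in place.
#' @param rpx Radial bin width, cm.
#' @param n Refractive index of the medium.
#' @return Updated photon state.
#' @export
bounce_photon <- function(state, derived, acc, rpx, n) {
  if (state$z >= 0)
    stop("bounce_photon() called with z >= 0: photon has not crossed the surface")
  state$w <- -state$w
  state$z <- -state$z
  w <- state$w
  if (w > derived$cangle) {
    t <- sqrt(1 - (1 - w * w) * n * n)
    temp1 <- (w - n * t) / (w + n * t)
    temp <- (t - n * w) / (t + n * w)
    rf <- (temp1 * temp1 + temp * temp) / 2
    esc <- (1 - rf) * state$weight
    acc$rd <- acc$rd + esc
    lcc <- abs(w) / sqrt(state$u^2 + state$v^2 + state$w^2)
    lcc <- n * sqrt(1 - lcc * lcc)
    if (lcc * lcc > 1) {
      lcc <- 0  # failsafe; unreachable when the critical-angle test holds
    } else {
      lcc <- sqrt(1 - lcc * lcc)
    }
    r <- sqrt(state$x^2 + state$y^2)
    k <- round(r / rpx) + 1
    if (k <= length(acc$heat)) acc$heat[k] <- acc$heat[k] + lcc * esc
    state$weight <- state$weight - esc
  }
  state
}

#' Absorb energy at an interaction site
#'
#' Implicit capture: a fraction `1 - albedo` of the current weight is
#' deposited in the medium and the weight is attenuated by the transport
#' albedo. A photon whose weight falls below `limit` is terminated and
#' its residual weight scored as absorbed; in roulette mode it instead
#' survives with probability `roulette_chance` and has its weight boosted
#' by the reciprocal.
#'
#' @param state Photon state.
#' @param derived A [derive_optics()] result.
#' @param acc A [flux_accumulator()]; updated in place.
#' @param limit Limiting energy level.
#' @param roulette Use Russian roulette instead of the deterministic
#'   cutoff? Default `FALSE`.
#' @param rabs_value Uniform draw consumed only in roulette mode.
#' @param roulette_chance Survival probability in roulette mode.
#' @return Updated photon state (`alive = FALSE` once terminated).
#' @export
absorb_photon <- function(state, derived, acc, limit, roulette = FALSE,
                          rabs_value = NULL, roulette_chance = 0.1) {
  acc$absorbed <- acc$absorbed + state$weight * (1 - derived$albedo)
  state$weight <- state$weight * derived$albedo
  if (state$weight < limit) {
    if (roulette) {
      if (rabs_value < roulette_chance) {
        state$weight <- state$weight / roulette_chance
      } else {
        acc$absorbed <- acc$absorbed + state$weight
        state$alive <- FALSE
      }
    } else {
      acc$absorbed <- acc$absorbed + state$weight
      state$alive <- FALSE
    }
  }
  state
}

#' Scatter a photon into a new direction
#'
#' Deflection cosine sampled from the Henyey-Greenstein phase function
#' (uniform on `[-1, 1]` when `g = 0`); azimuth sampled by rejection on
#' the unit disk from pairs `(rx1, rx2)` — on rejection the next pair is
#' consumed. The direction is rotated in the local frame, with the
#' degenerate near-vertical update used when `|w| > 0.99999`.
#'
#' @param state Photon state.
#' @param g Anisotropy factor.
#' @param rmu_value Uniform draw on `[0, 1)` for the deflection cosine.
#' @param rx1,rx2 Numeric vectors of draws on `[-1, 1]`; pairs are
#'   consumed in order until one is accepted.
#' @return Updated photon state, with attribute `pairs_used` giving the
#'   number of `(rx1, rx2)` pairs consumed.
#' @export
scatter_photon <- function(state, g, rmu_value, rx1, rx2) {
  if (g == 0) {
    ct <- 2 * rmu_value - 1
  } else {
    tmp <- (1 - g * g) / (1 - g + 2 * g * rmu_value)
    ct <- (1 + g * g - tmp * tmp) / (2 * g)
  }
  if (ct > 1) ct <- 1
  if (ct < -1) ct <- -1
  st <- sqrt(1 - ct * ct)
  used <- 0L
  repeat {
    used <- used + 1L
    if (used > length(rx1))
      stop("azimuth pair stream exhausted during rejection sampling")
    a <- rx1[used]
    b <- rx2[used]
    rho2 <- a * a + b * b
    if (rho2 > 0 && rho2 <= 1) {
      rho <- sqrt(rho2)
      cphi <- a / rho
      sphi <- b / rho
      break
    }
  }
  u <- state$u; v <- state$v; w <- state$w
  if (abs(w) > 0.99999) {
    state$u <- st * cphi
    state$v <- st * sphi
    state$w <- if (w >= 0) ct else -ct
  } else {
    den <- sqrt(1 - w * w)
    state$u <- st * (u * w * cphi - v * sphi) / den + u * ct
    state$v <- st * (v * w * cphi + u * sphi) / den + v * ct
    state$w <- -st * cphi * den + w * ct
  }
  attr(state, "pairs_used") <- used
  state
}

#' Trace one photon trajectory (reference tracer)
#'
#' Composes the five trajectory steps — launch, move, bounce on surface
#' crossing, absorb, scatter — drawing each random number on demand from
#' the photon's substreams, until the photon is terminated. All weight is
#' accounted to `heat`/`rd`/`absorbed` in `acc`. This pure-R tracer
#' consumes the same draws in the same order as the compiled kernel and
#' reproduces its tallies exactly.
#'
#' @param photon_index 1-based photon index.
#' @param media A [media_optics()] object.
#' @param cfg A [simulation_config()] object.
#' @param derived A [derive_optics()] result.
#' @param beam A [refraction_angle()] result.
#' @param streams A [launch_streams()] result.
#' @param acc A [flux_accumulator()]; updated in place.
#' @param seed Run seed.
#' @param roulette Use Russian roulette termination? Default `FALSE`.
#' @param roulette_chance Survival probability in roulette mode.
#' @return The final photon state, invisibly.
#' @export
trace_photon <- function(photon_index, media, cfg, derived, beam, streams,
                         acc, seed = cfg$seed, roulette = FALSE,
                         roulette_chance = 0.1) {
  maxlen <- derived$maxlen
  rmv <- stream_uniforms(seed, "rmv", photon_index, maxlen)
  rmu <- stream_uniforms(seed, "rmu", photon_index, maxlen)
  rabs <- if (roulette) stream_uniforms(seed, "rabs", photon_index, maxlen)
  # azimuth pairs: drawn in bulk with headroom, regrown if rejection is
  # unusually heavy (expected consumption is 4/pi pairs per scatter)
  n_rx <- 4L * maxlen
  rx <- stream_uniforms(seed, "rx", photon_index, n_rx)
  rx_pos <- 0L

  state <- launch_photon(photon_index, beam, streams, derived)
  for (midx in seq_len(maxlen)) {
    state <- move_photon(state, rmv[midx], derived$mu_t)
    if (state$z < 0)
      state <- bounce_photon(state, derived, acc, cfg$rpx, media$n)
    state <- absorb_photon(state, derived, acc, cfg$limit,
                           roulette = roulette, rabs_value = rabs[midx],
                           roulette_chance = roulette_chance)
    if (!state$alive) break
    if (2L * (rx_pos %/% 2L) + 64L > n_rx) {
      n_rx <- 2L * n_rx
      rx <- stream_uniforms(seed, "rx", photon_index, n_rx)
    }
    pair_idx <- seq.int(rx_pos + 1L, n_rx, by = 2L)
    state <- scatter_photon(state, media$g, rmu[midx],
                            2 * rx[pair_idx] - 1, 2 * rx[pair_idx + 1L] - 1)
    rx_pos <- rx_pos + 2L * attr(state, "pairs_used")
    state$event_index <- midx
  }
  if (state$alive) {
    if (!roulette)
      stop("internal error: photon alive after maxlen events under ",
           "deterministic cutoff")
    acc$absorbed <- acc$absorbed + state$weight
    acc$n_truncated <- acc$n_truncated + 1
  }
  invisible(state)
}

#' Run a full backscattering simulation
#'
#' Launches `cfg$photons` photons into the medium and accumulates the
#' Lambertian-corrected escaping flux per radial ring, the total diffuse
#' reflectance `rd`, the absorbed energy, and the specular loss. The
#' compiled kernel (`engine = "cpp"`, the default) and the pure-R
#' reference tracer (`engine = "r"`) consume identical random substreams
#' and give identical results; the R engine is only practical for small
#' photon counts.
#'
#' @param media A [media_optics()] object.
#' @param cfg A [simulation_config()] object.
#' @param engine `"cpp"` (compiled kernel) or `"r"` (reference tracer).
#' @param roulette Use Russian roulette termination instead of the
#'   deterministic weight cutoff? Default `FALSE`.
#' @param roulette_chance Survival probability in roulette mode.
#' @param max_events Trajectory-length cap used when `mu_a = 0`.
#' @return An object of class `mcbs_result`: the accumulator fields
#'   (`heat`, `rd`, `absorbed`, `specular`, `n_truncated`) plus the
#'   inputs and derived constants of the run.
#' @examples
#' med <- media_optics(0.1056, 2.529, 0, 1.35)
#' cfg <- simulation_config(photons = 2000, beam_radius = 0.05,
#'                          obs_radius = 3, rpx = 0.05, seed = 1)
#' res <- run_simulation(med, cfg)
#' res$rd / cfg$photons  # diffuse reflectance fraction
#' @export
run_simulation <- function(media, cfg, engine = c("cpp", "r"),
                           roulette = FALSE, roulette_chance = 0.1,
                           max_events = 1e6) {
  stopifnot(inherits(media, "media_optics"),
            inherits(cfg, "simulation_config"))
  engine <- match.arg(engine)
  derived <- derive_optics(media, cfg, max_events = max_events)
  beam <- refraction_angle(cfg$angle_deg, media$n)

  if (engine == "cpp") {
    out <- cpp_run_simulation(media$mu_a, media$mu_s, media$g, media$n,
                              as.double(cfg$photons), cfg$beam_radius,
                              cfg$limit, cfg$obs_radius, cfg$rpx,
                              cfg$angle_deg, as.double(cfg$seed),
                              derived$maxlen, roulette, roulette_chance)
  } else {
    acc <- flux_accumulator(cfg)
    streams <- launch_streams(cfg)
    for (i in seq_len(cfg$photons))
      trace_photon(i, media, cfg, derived, beam, streams, acc,
                   seed = cfg$seed, roulette = roulette,
                   roulette_chance = roulette_chance)
    out <- list(heat = acc$heat, rd = acc$rd, absorbed = acc$absorbed,
                specular = derived$rs * cfg$photons,
                n_truncated = acc$n_truncated)
  }

  structure(c(out, list(media = media, config = cfg, derived = derived,
                        beam = beam, engine = engine,
                        roulette = roulette)),
            class = "mcbs_result")
}

#' Energy-balance audit of a run
#'
#' Under the deterministic weight cutoff every unit of launched weight is
#' scored exactly once, so `specular + rd + absorbed` equals the number
#' of launched photons up to floating-point rounding.
#'
#' @param result An [run_simulation()] result.
#' @return A list with `total` (launched weight), `specular`, `rd`,
#'   `absorbed` and `residual_rel` (relative residual).
#' @export
energy_balance <- function(result) {
  stopifnot(inherits(result, "mcbs_result"))
  total <- result$config$photons
  resid <- total - (result$specular + result$rd + result$absorbed)
  list(total = total, specular = result$specular, rd = result$rd,
       absorbed = result$absorbed,
       residual_rel = if (total > 0) resid / total else 0)
}

#' @export
print.mcbs_result <- function(x, ...) {
  n <- x$config$photons
  cat("Monte Carlo backscattering run (", x$engine, " engine)\n", sep = "")
  print(x$media)
  print(x$config)
  cat(sprintf("  albedo %.6f, rs %.5f, cos(critical) %.4f, maxlen %d\n",
              x$derived$albedo, x$derived$rs, x$derived$cangle,
              x$derived$maxlen))
  if (n > 0) {
    eb <- energy_balance(x)
    cat(sprintf("  diffuse reflectance rd = %.5f, absorbed = %.5f, specular = %.5f\n",
                x$rd / n, x$absorbed / n, x$specular / n))
    cat(sprintf("  energy-balance residual = %.3g (relative)\n",
                eb$residual_rel))
  }
  invisible(x)
}
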