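# Planck's constant (J s) and vacuum speed of light (m/s), CODATA values.
.mcbs_h <- 6.62607015e-34
.mcbs_c0 <- 2.99792458e8

#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the four optical parameters that govern photon transport:
#' absorption coefficient, scattering coefficient, scattering anisotropy
#' and refractive index.
#'
#' @param mu_a Absorption coefficient, cm^-1 (>= 0).
#' @param mu_s Scattering coefficient, cm^-1 (> 0).
#' @param g Anisotropy factor, the mean cosine of the scattering
#'   deflection angle; strictly between -1 and 1. `g = 0` is isotropic;
#'   biological tissue typically scatters forward with `g > 0.6`.
#' @param n Refractive index of the medium relative to air (>= 1).
#'
#' @return An object of class `media_optics`.
#' @examples
#' media_optics(mu_a = 0.63, mu_s = 30, g = 0, n = 1.4)
#' @export
media_optics <- function(mu_a, mu_s, g, n) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1, is.finite(mu_a),
            is.numeric(mu_s), length(mu_s) == 1, is.finite(mu_s),
            is.numeric(g), length(g) == 1, is.finite(g),
            is.numeric(n), length(n) == 1, is.finite(n))
  if (mu_a < 0) stop("`mu_a` must be >= 0 (cm^-1)")
  if (mu_s <= 0) stop("`mu_s` must be > 0 (cm^-1)")
  if (g <= -1 || g >= 1) stop("`g` must lie strictly between -1 and 1")
  if (n < 1) stop("`n` must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "media_optics")
}

#' Simulation and vision-system configuration
#'
#' The five measurement-system parameters plus the incident angle of the
#' light beam and the random seed.
#'
#' @param photons Number of photons to launch (>= 1; 0 is allowed and
#'   yields an empty result).
#' @param beam_radius Radius of the circular light beam, cm.
#' @param limit Limiting energy level: a photon is terminated once its
#'   weight falls below this fraction of its launch energy; in (0, 1).
#' @param obs_radius Radius of the observed surface area, cm.
#' @param rpx Spatial resolution of the vision system, cm per pixel; this
#'   is the radial bin width of the recorded profile.
#' @param angle_deg Incident angle of the beam measured from the surface
#'   normal, degrees in `[0, 90)`. Defaults to 0 (normal incidence).
#' @param seed Integer seed for the random substreams.
#'
#' @return An object of class `simulation_config`.
#' @examples
#' simulation_config(photons = 1e6, beam_radius = 0.05, limit = 1e-9,
#'                   obs_radius = 3, rpx = 0.05)
#' @export
simulation_config <- function(photons, beam_radius = 0.05, limit = 1e-9,
                              obs_radius = 3, rpx = 0.01, angle_deg = 0,
                              seed = 1L) {
  stopifnot(is.numeric(photons), length(photons) == 1, is.finite(photons),
            photons >= 0, photons == floor(photons))
  if (beam_radius < 0) stop("`beam_radius` must be >= 0 (cm)")
  if (limit <= 0 || limit >= 1) stop("`limit` must lie in (0, 1)")
  if (obs_radius <= 0) stop("`obs_radius` must be > 0 (cm)")
  if (rpx <= 0) stop("`rpx` must be > 0 (cm/pixel)")
  if (angle_deg < 0 || angle_deg >= 90)
    stop("`angle_deg` must lie in [0, 90) degrees")
  structure(list(photons = photons, beam_radius = beam_radius, limit = limit,
                 obs_radius = obs_radius, rpx = rpx, angle_deg = angle_deg,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Reduced scattering coefficient
#'
#' The similarity-transformed scattering parameter `mu_s' = (1 - g) mu_s`
#' reported in most tissue-optics literature. Many (`g`, `mu_s`) pairs
#' share the same reduced value, which is why validating anisotropic runs
#' against diffusion theory is delicate.
#'
#' @param mu_s Scattering coefficient, cm^-1 (>= 0).
#' @param g Anisotropy factor, strictly between -1 and 1.
#' @return Reduced scattering coefficient, cm^-1.
#' @examples
#' reduced_scattering(25.29, 0.9)  # 2.529
#' @export
reduced_scattering <- function(mu_s, g) {
  stopifnot(is.numeric(mu_s), is.numeric(g))
  if (any(mu_s < 0)) stop("`mu_s` must be >= 0")
  if (any(g <= -1) || any(g >= 1)) stop("`g` must lie strictly in (-1, 1)")
  (1 - g) * mu_s
}

#' Photon budget of a light pulse from Planck's law
#'
#' Number of photons delivered by a light source of given power over a
#' given duration, with the single-photon energy `E = h C0 / (n lambda)`
#' evaluated at the in-medium frequency.
#'
#' @param power Source power, W (>= 0).
#' @param duration Pulse duration, s (> 0).
#' @param wavelength Vacuum wavelength, m (> 0).
#' @param n Refractive index of the medium (>= 1).
#' @return Photon count (a pure number, generally not an integer).
#' @examples
#' planck_photon_count(3e-3, 1, 670e-9, 1.4)  # about 1.42e16
#' @export
planck_photon_count <- function(power, duration, wavelength, n) {
  stopifnot(is.numeric(power), is.numeric(duration),
            is.numeric(wavelength), is.numeric(n))
  if (any(power < 0)) stop("`power` must be >= 0")
  if (any(duration <= 0) || any(wavelength <= 0) || any(n < 1))
    stop("`duration` and `wavelength` must be > 0 and `n` >= 1")
  energy <- .mcbs_h * .mcbs_c0 / (n * wavelength)
  power * duration / energy
}

#' Refraction of the launch direction at the surface
#'
#' Applies Snell's law to the incident beam: `phi2 = asin(sin(phi1) / n)`.
#' Because the beam meets the surface at an angle, its circular cross
#' section paints an ellipse on the surface whose major axis is stretched
#' by `1 / cos(phi2)`.
#'
#' @param phi1_deg Incident angle in air, degrees in `[0, 90)`.
#' @param n Refractive index of the medium (>= 1).
#' @return An object of class `beam_geometry` with elements `phi1` and
#'   `phi2` (radians) and `stretch` (elliptic distortion factor).
#' @examples
#' refraction_angle(10, 1.4)  # refracted angle about 7.12 degrees
#' @export
refraction_angle <- function(phi1_deg, n) {
  stopifnot(length(phi1_deg) == 1, length(n) == 1)
  if (phi1_deg < 0 || phi1_deg >= 90)
    stop("`phi1_deg` must lie in [0, 90)")
  if (n < 1) stop("`n` must be >= 1")
  phi1 <- phi1_deg * pi / 180
  phi2 <- asin(sin(phi1) / n)
  structure(list(phi1 = phi1, phi2 = phi2, stretch = 1 / cos(phi2)),
            class = "beam_geometry")
}

#' Derived per-run transport constants
#'
#' Computes the quantities fixed for one simulation run: total attenuation
#' `mu_t = mu_a + mu_s`, transport albedo `mu_s / (mu_s + mu_a)` (the
#' fraction of photon weight surviving each interaction event), specular
#' reflectance at normal incidence `((n-1)/(n+1))^2`, the cosine of the
#' critical angle `sqrt(1 - 1/n^2)`, and the maximum trajectory length in
#' events, `round(log(limit) / log(albedo)) + 1`, after which the weight
#' of any photon has necessarily fallen below `limit`.
#'
#' For a non-absorbing medium (`mu_a = 0`) the albedo is 1 and the event
#' bound degenerates; a hard cap of `max_events` is then used instead and
#' a warning is issued.
#'
#' @param media A [media_optics()] object.
#' @param cfg A [simulation_config()] object (supplies `limit`).
#' @param max_events Hard cap on trajectory length used when `mu_a = 0`.
#' @return An object of class `derived_optics` with elements `mu_t`,
#'   `albedo`, `rs`, `cangle`, `maxlen`.
#' @examples
#' derive_optics(media_optics(0.63, 30, 0, 1.4),
#'               simulation_config(photons = 1e5, limit = 1e-9))
#' @export
derive_optics <- function(media, cfg, max_events = 1e6) {
  stopifnot(inherits(media, "media_optics"),
            inherits(cfg, "simulation_config"))
  mu_t <- media$mu_a + media$mu_s
  albedo <- media$mu_s / (media$mu_s + media$mu_a)
  rs <- ((media$n - 1) / (media$n + 1))^2
  cangle <- sqrt(1 - 1 / media$n^2)
  if (media$mu_a == 0) {
    warning("mu_a = 0: albedo is 1 and the event bound degenerates; ",
            "using the hard cap max_events = ", format(max_events))
    maxlen <- as.integer(max_events)
  } else {
    maxlen <- as.integer(round(log(cfg$limit) / log(albedo)) + 1)
  }
  structure(list(mu_t = mu_t, albedo = albedo, rs = rs, cangle = cangle,
                 maxlen = maxlen),
            class = "derived_optics")
}

#' @export
print.media_optics <- function(x, ...) {
  cat("Turbid medium: mu_a =", x$mu_a, "cm^-1, mu_s =", x$mu_s,
      "cm^-1, g =", x$g, ", n =", x$n, "\n")
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation: %g photons, beam radius %g cm, limit %g,\n",
                     "  observed radius %g cm, resolution %g cm/px, ",
                     "incident angle %g deg, seed %d\n"),
              x$photons, x$beam_radius, x$limit, x$obs_radius, x$rpx,
              x$angle_deg, x$seed))
  invisible(x)
}
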