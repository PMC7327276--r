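# Random-number substreams.
#
# One splitmix64 substream per (seed, variable, photon) triple. Photon
# trajectories are therefore independent of the order in which photons
# are traced, and the bulk stream extraction below is numerically
# identical to the on-demand draws made inside the transport kernel.

.mcbs_stream_tags <- c(launch = 0L, rmv = 1L, rabs = 2L, rmu = 3L, rx = 4L)

#' Raw uniform substream
#'
#' First `n` uniforms on `[0, 1)` of the substream identified by
#' `(seed, stream, photon_index)`. This is the exact sequence the
#' transport kernel consumes for that variable of that photon, exposed
#' for reference tracing and testing.
#'
#' @param seed Integer run seed.
#' @param stream One of `"launch"`, `"rmv"`, `"rabs"`, `"rmu"`, `"rx"`.
#' @param photon_index 1-based photon index.
#' @param n Number of uniforms to return.
#' @return Numeric vector of length `n`.
#' @export
stream_uniforms <- function(seed, stream = c("launch", "rmv", "rabs",
                                             "rmu", "rx"),
                            photon_index, n) {
  stream <- match.arg(stream)
  cpp_stream_uniforms(as.double(seed), .mcbs_stream_tags[[stream]],
                      as.double(photon_index), as.integer(n))
}

#' Per-photon launch coordinates
#'
#' Pre-generates the launch position of every photon in polar
#' coordinates within the circular beam: radius `rbr = beam_radius *
#' sqrt(U)` (uniform over the disk area) and azimuth `rba` uniform on
#' `[0, 2*pi)`.
#'
#' @param cfg A [simulation_config()] object.
#' @param seed Run seed; defaults to `cfg$seed`.
#' @return A list with numeric vectors `rbr` (cm) and `rba` (radians),
#'   each of length `cfg$photons`.
#' @examples
#' ls <- launch_streams(simulation_config(photons = 100), seed = 7)
#' @export
launch_streams <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  u <- cpp_launch_uniforms(as.double(seed), as.double(cfg$photons))
  list(rbr = cfg$beam_radius * sqrt(u$u_radius),
       rba = 2 * pi * u$u_azimuth)
}

#' Per-photon trajectory random vectors
#'
#' Pre-generates, for one photon, the random variables consumed along its
#' trajectory: `rmv` (free-path draw, per event), `rabs` (roulette
#' survival, per event; unused under the deterministic cutoff), `rmu`
#' (Henyey-Greenstein deviate, per scattering), and `rx1`/`rx2` (azimuth
#' rejection pairs on `[-1, 1]`). Each vector has length `maxlen`; the
#' azimuth pair stream may be consumed past `maxlen` entries by rejection,
#' in which case the kernel continues drawing from the same substream.
#'
#' @param derived A [derive_optics()] result (supplies `maxlen`).
#' @param seed Run seed.
#' @param photon_index 1-based photon index.
#' @return A list with vectors `rmv`, `rabs`, `rmu`, `rx1`, `rx2`.
#' @export
trajectory_streams <- function(derived, seed, photon_index) {
  stopifnot(inherits(derived, "derived_optics"))
  m <- derived$maxlen
  rx <- stream_uniforms(seed, "rx", photon_index, 2L * m)
  list(rmv = stream_uniforms(seed, "rmv", photon_index, m),
       rabs = stream_uniforms(seed, "rabs", photon_index, m),
       rmu = stream_uniforms(seed, "rmu", photon_index, m),
       rx1 = 2 * rx[seq(1L, 2L * m, by = 2L)] - 1,
       rx2 = 2 * rx[seq(2L, 2L * m, by = 2L)] - 1)
}
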