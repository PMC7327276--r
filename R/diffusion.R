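# Diffusion-theory reference model for spatially resolved steady-state
# diffuse reflectance from a semi-infinite medium.

#' Diffusion-theory parameters of a medium
#'
#' Derives the quantities of the standard dipole diffusion model: the
#' reduced scattering coefficient `musp = (1 - g) mu_s`, the effective
#' attenuation `mu_eff = sqrt(3 mu_a (mu_a + musp))` governing the
#' exponential tail of the profile, the source depth `z0 = 1 / (mu_a +
#' musp)`, the diffusion constant `D = 1 / (3 (mu_a + musp))`, and the
#' extrapolated-boundary offset `zb = 2 A D` with the internal-reflection
#' parameter `A = (1 + ri) / (1 - ri)` computed from the empirical
#' polynomial `ri = -1.440/n^2 + 0.710/n + 0.668 + 0.0636 n`.
#'
#' @param media A [media_optics()] object.
#' @return An object of class `diffusion_params` with elements `musp`,
#'   `mu_eff`, `z0`, `D`, `A`, `zb`.
#' @examples
#' diffusion_params(media_optics(0.1056, 2.529, 0, 1.35))
#' @export
diffusion_params <- function(media) {
  stopifnot(inherits(media, "media_optics"))
  musp <- reduced_scattering(media$mu_s, media$g)
  if (musp <= 0) stop("reduced scattering coefficient must be > 0")
  mu_a <- media$mu_a
  n <- media$n
  mut_p <- mu_a + musp
  ri <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + ri) / (1 - ri)
  D <- 1 / (3 * mut_p)
  structure(list(musp = musp,
                 mu_eff = sqrt(3 * mu_a * mut_p),
                 z0 = 1 / mut_p,
                 D = D, A = A, zb = 2 * A * D),
            class = "diffusion_params")
}

#' Spatially resolved diffuse reflectance from diffusion theory
#'
#' The dipole-source solution with extrapolated boundary:
#' \deqn{R(r) = \frac{1}{4\pi}\left[z_0\left(\mu_{eff}+\frac{1}{r_1}\right)
#'   \frac{e^{-\mu_{eff} r_1}}{r_1^2} + (z_0+2 z_b)\left(\mu_{eff}+
#'   \frac{1}{r_2}\right)\frac{e^{-\mu_{eff} r_2}}{r_2^2}\right]}
#' with \eqn{r_1 = \sqrt{z_0^2+r^2}} and
#' \eqn{r_2 = \sqrt{(z_0+2 z_b)^2+r^2}}. The single isotropic-source
#' variant (first term only) is available via `variant = "point"` for
#' sensitivity analysis.
#'
#' @param media A [media_optics()] object.
#' @param radii Radii at which to evaluate, cm (>= 0; `r = 0` is finite
#'   since the source sits at depth `z0 > 0`).
#' @param variant `"dipole"` (default) or `"point"`.
#' @return Numeric vector of reflectance values, cm^-2.
#' @examples
#' med <- media_optics(0.1056, 2.529, 0, 1.35)
#' diffusion_profile(med, seq(0, 3, by = 0.05))
#' @export
diffusion_profile <- function(media, radii, variant = c("dipole", "point")) {
  variant <- match.arg(variant)
  if (any(radii < 0)) stop("`radii` must be >= 0")
  p <- diffusion_params(media)
  r1 <- sqrt(p$z0^2 + radii^2)
  term1 <- p$z0 * (p$mu_eff + 1 / r1) * exp(-p$mu_eff * r1) / r1^2
  if (variant == "point")
    return(term1 / (4 * pi))
  zpos <- p$z0 + 2 * p$zb
  r2 <- sqrt(zpos^2 + radii^2)
  term2 <- zpos * (p$mu_eff + 1 / r2) * exp(-p$mu_eff * r2) / r2^2
  (term1 + term2) / (4 * pi)
}
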