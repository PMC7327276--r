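---
title: "Monte Carlo simulation of laser-induced backscattering profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo simulation of laser-induced backscattering profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcbacksim)
```

## The measurement being simulated

When a narrow laser beam hits a turbid material — fruit tissue, a solid
optical phantom, skin — most of the light enters the medium, scatters many
times, and a fraction re-emerges through the surface around the incident
point. A camera mounted on the surface normal sees a diffuse glow whose
radial intensity profile encodes the medium's optical properties. Vision
systems measure this profile in concentric one-pixel rings; inverse models
then estimate absorption and scattering from it.

`mcbacksim` simulates this measurement by Monte Carlo photon transport in
a semi-infinite homogeneous medium described by four parameters: the
absorption coefficient $\mu_a$ (cm$^{-1}$), the scattering coefficient
$\mu_s$ (cm$^{-1}$), the scattering anisotropy $g$ (mean cosine of the
deflection angle), and the refractive index $n$. The vision system adds
five more: photon count, beam radius, limiting energy level, observed
radius, and spatial resolution — plus the incident angle of the beam.

Two features distinguish this simulator from a textbook pencil-beam code:

* **Oblique launch with elliptic beam distortion.** Because the camera
  occupies the surface normal, the light source must be tilted (10–20° is
  practical). The launch direction inside the medium follows Snell's law,
  $\varphi_2 = \arcsin(\sin\varphi_1 / n)$, and the circular beam paints
  an ellipse on the surface: the launch position's $y$ coordinate is
  divided by $\cos\varphi_2$.
* **Lambertian correction of the escaping flux.** A camera on the normal
  does not collect the full hemispherical escape; each escaping weight
  packet is attenuated by the cosine of its *external* exit angle before
  being added to the ring tally.

## Transport model

Each photon starts with weight $1 - r_s$, where
$r_s = ((n-1)/(n+1))^2$ is the normal-incidence specular reflectance
(deducted once at launch; the same $r_s$ is used for tilted beams,
matching the original method). A trajectory then iterates five steps:

1. **Move**: free path $s = -\ln \xi / \mu_t$ with $\mu_t = \mu_a + \mu_s$.
2. **Bounce** (if the step crossed the surface, $z < 0$): position and
   direction are mirrored. If the internal cosine $w$ exceeds the critical
   cosine $\sqrt{1 - 1/n^2}$, the polarization-averaged Fresnel
   transmitted fraction escapes: it is added to the diffuse reflectance
   $r_d$, and — weighted by the Lambertian factor
   $\sqrt{1 - n^2(1 - w^2)}$, the external exit cosine — to the ring at
   the current radius (ring index $\mathrm{round}(r/r_{px})$). The
   reflected remainder continues inside.
3. **Absorb**: implicit capture; a fraction $1 - a$ of the weight is
   deposited, where $a = \mu_s / (\mu_s + \mu_a)$ is the transport albedo.
4. **Terminate** when the weight falls below the limiting energy level
   (default $10^{-9}$); the residual is scored as absorbed. This
   deterministic cutoff matches the pre-computed trajectory bound
   $\mathrm{maxlen} = \mathrm{round}(\ln \mathit{limit} / \ln a) + 1$ and
   biases each photon by at most $10^{-9}$. A Russian-roulette mode
   (survival probability 0.1, weight boost 10) is available behind
   `roulette = TRUE` for users who prefer the classical scheme; it is off
   by default because the deterministic cutoff conserves energy exactly
   per run, which the test suite exploits.
5. **Scatter**: deflection cosine from the Henyey–Greenstein phase
   function ($\cos\theta$ uniform when $g = 0$), azimuth by rejection
   sampling on the unit disk (two draws per attempt, no trigonometric
   calls), then the standard local-frame rotation with the degenerate
   near-vertical branch at $|w| > 0.99999$.

Energy is conserved exactly: specular + $r_d$ + absorbed equals the
launched weight to floating-point rounding, and the suite enforces a
$10^{-6}$ relative bound.

### Random-number streams

Reproducibility is organized around counter-based substreams: one
splitmix64 substream per (seed, variable, photon) triple — launch
coordinates, free paths, roulette decisions, Henyey–Greenstein deviates,
and azimuth pairs each have their own. Consequences worth knowing:

* a run is bit-reproducible for a fixed seed;
* photon trajectories are independent of tracing order;
* bulk pre-generation (`launch_streams()`, `trajectory_streams()`) and
  the kernel's on-demand draws are numerically identical — the pure-R
  reference tracer (`trace_photon()`, `engine = "r"`) reproduces the
  compiled kernel's tallies exactly, which the tests assert.

The azimuth rejection loop may consume more than `maxlen` pairs; the
kernel simply keeps drawing from the same substream, so the pre-generated
vectors remain a prefix of what is actually consumed.

## From tally to profile

The raw tally `heat[k]` is escaped (Lambertian-weighted) photon weight in
ring $k$, with ring 0 at the incident point. `intensity_profile()`
converts it to flux in cm$^{-2}$ per launched photon by dividing by the
area of the annulus each bin actually covers under round-based binning —
inner radius $(k - \tfrac12) r_{px}$, width $r_{px}$, and a central disc
of radius $r_{px}/2$ — so that flux × area × photons exactly inverts the
tally. Division by the photon count makes profiles from different run
sizes comparable.

The original code this package re-implements normalized differently: it
divided ring $k$ by the annulus with inner radius $k \cdot r_{px}$
(equivalently, the central bin by the full disc of radius $r_{px}$). That
convention does not invert the round-based tally — it flattens the near
field and quarters the central bin — but it is the convention under which
the published validation statistics were produced. Both are implemented:
the profile module uses the self-consistent edge convention; the
validation comparison (`compare_to_diffusion()`) defaults to the
original's nominal convention (`area_convention = "nominal"`).

## The diffusion reference and validation statistics

The closed-form reference is the standard dipole diffusion model for
spatially resolved steady-state reflectance from a semi-infinite medium:
an isotropic source at depth $z_0 = 1/(\mu_a + \mu_s')$ and its image
above the extrapolated boundary at $z_0 + 2 z_b$, $z_b = 2AD$, with
$D = 1/(3(\mu_a + \mu_s'))$ and the internal-reflection parameter $A$
from the empirical polynomial
$r_i = -1.440/n^2 + 0.710/n + 0.668 + 0.0636\,n$. The effective
attenuation $\mu_{\mathrm{eff}} = \sqrt{3 \mu_a (\mu_a + \mu_s')}$
governs the far-field decay. A single-source variant
(`variant = "point"`) is provided for sensitivity analysis; for the
phantom parameters it changes the comparison statistics only in the third
decimal, so the choice of variant is not what separates simulation from
reference.

`compare_profiles()` reports the Pearson correlation and three RMSE
scalings over the retained bins (the innermost bin is excluded by
default — the incident-point bin, where a measured profile saturates and
diffusion theory is least valid):

* `rmse` — raw difference of the two absolute flux profiles, cm$^{-2}$;
* `rmse_01` — after rescaling both profiles to 0–1, the convention
  needed when a camera profile with arbitrary intensity units enters;
* `rmse_unit_sum` — after scaling both to unit sum.

Correlation is invariant under all of these, so only the exclusion depth
and the area convention affect it.

## What the simulation does and does not reproduce

For the reference phantom ($\mu_a = 0.1056$ cm$^{-1}$,
$\mu_s' = 2.529$ cm$^{-1}$, $n = 1.35$, $10^6$ photons, 0.05 cm
resolution to 3 cm), the isotropic run correlates with the dipole model
at about 0.97 and the anisotropic run ($\mu_s = 25.29$, $g = 0.9$ — the
same reduced scattering) at about 0.95, with the anisotropic RMSE the
larger of the two: anisotropy rotates the near-field profile even at
fixed $\mu_s'$, which is the core argument for not validating
anisotropic media against similarity-scaled diffusion theory. These
numbers are recomputed, not quoted, by `scripts/acceptance.R` and the
test suite.

Two physical effects put a ceiling on the MC–diffusion agreement and are
worth understanding before reading the statistics:

* **Near-source steepness.** Monte Carlo reflectance rises steeply toward
  the incident point (short-path backscatter), while the dipole model is
  nearly flat within $r \lesssim z_0$. Excluding one bin does not remove
  this regime; correlations computed over the full 0–3 cm window are
  therefore structurally below 1 even for a perfect transport kernel.
* **Transitional far field.** For this phantom, $1/\mu_{\mathrm{eff}}
  \approx 1.1$ cm and $z_0 + 2 z_b \approx 1.9$ cm, so the classical
  asymptotic slope $-\mu_{\mathrm{eff}}$ of $\ln(r^2 R)$ is not yet
  reached inside the 3 cm window: the effective slope over 1–3 cm is
  about $0.6$ cm$^{-1}$ for the analytic dipole curve itself (a fit over
  8–12 cm recovers $\mu_{\mathrm{eff}}$ within 1%). Estimating
  $\mu_{\mathrm{eff}}$ from a 3 cm profile by a log-slope fit will
  underestimate it substantially; this is a property of the geometry, not
  of the simulator.

## Parameters that matter

| Parameter | Unit | Default | Notes |
|---|---|---|---|
| `photons` | count | — | $10^6$ is the practical minimum for a low-noise profile; per-bin noise falls like $1/\sqrt{N}$ |
| `beam_radius` | cm | 0.05 | 1 mm diameter laser |
| `limit` | — | $10^{-9}$ | termination level; also fixes `maxlen` |
| `obs_radius` | cm | 3 | observation window |
| `rpx` | cm/px | 0.01 | ring width; validation runs use 0.05 |
| `angle_deg` | deg | 0 | 10–20° recommended so the source clears the camera |
| `seed` | int | 1 | root of all substreams |

The trajectory bound grows quickly as the albedo approaches 1: the
isotropic phantom needs 508 events per photon, the anisotropic
parameterization 4 972 — which is why the anisotropic validation run is
roughly ten times slower at equal photon count. For a non-absorbing
medium (`mu_a = 0`) the bound degenerates and a hard cap (`max_events`,
default $10^6$) applies instead.

## Degenerate inputs and numerical guards

* Free-path draws are clamped away from 0 (at $2^{-53}$) before the
  logarithm.
* The Henyey–Greenstein cosine is clipped to $[-1, 1]$ against rounding.
* The Lambertian factor retains the original failsafe (`lcc` set to 0 if
  the intermediate square exceeds 1) even though the critical-angle test
  makes it unreachable.
* A zero-photon run returns an empty, all-zero accumulator; a zero beam
  radius launches every photon at the origin.
* Escapes beyond the observed radius count toward $r_d$ but are not
  binned.

## Choices made where the method description was open

* **Comparison protocol for the validation statistics.** The published
  validation does not print its comparison protocol. This package uses:
  the simulation's own 0.05 cm grid to 3 cm; the dipole diffusion model;
  one excluded central bin; the nominal ring-area convention (the literal
  reading of the original export step); raw cm$^{-2}$ RMSE as the
  headline `rmse` (matching the published unit), with the 0–1 and
  unit-sum scalings also reported.
* **Step length.** The free-path distribution is the standard
  exponential with mean $1/\mu_t$; the original text names the stream but
  not the transform.
* **Survival stream.** The `rabs` stream exists for every photon (and is
  consumed in roulette mode) but the default termination is the
  deterministic cutoff, which matches the pre-computed `maxlen` bound.
* **Specular loss at tilt.** The normal-incidence $r_s$ is applied for
  all incident angles, as in the original launch code; an angle-dependent
  Fresnel specular term is deliberately not used.
* **Elliptic distortion.** The $y$ coordinate is divided by
  $\cos\varphi_2$ (the refracted angle), following the original code
  verbatim, although a purely geometric surface footprint would use the
  incident angle.

## Worked example

```{r example, eval = FALSE}
phantom <- media_optics(mu_a = 0.1056, mu_s = 2.529, g = 0, n = 1.35)
cfg <- simulation_config(photons = 1e6, beam_radius = 0.05, limit = 1e-9,
                         obs_radius = 3, rpx = 0.05, seed = 1)
res <- run_simulation(phantom, cfg)
res
compare_to_diffusion(res)
plot(intensity_profile(res))
```

Problem sizes in the shipped tests: the validation comparisons run the
full $10^6$-photon phantom configurations over three seeds; unit and
property tests use $10^3$–$2\times10^5$ photons, which is ample for the
3-standard-error bands they assert.

## Known limitations

* Single homogeneous semi-infinite layer only; no layered media, no
  lateral or bottom boundaries, no time resolution, no polarization.
* The diffusion reference is a similarity-theory model: it shares
  $\mu_s'$ between the isotropic and anisotropic parameterizations and
  therefore cannot capture the near-field rotation that the simulation
  itself demonstrates.
* The simulated camera is ideal: Lambertian collection, no lens model,
  no saturation; comparison against real camera frames requires
  normalizing both profiles to 0–1 and excluding the saturated center.
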