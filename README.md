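# mcbacksim

Monte Carlo simulation of laser-induced diffuse reflectance
(backscattering) measured on the surface of a semi-infinite homogeneous
turbid medium — the measurement made by computer-vision systems that
shine a narrow laser on fruit tissue or an optical phantom and record the
radial glow around the incident point with a camera on the surface
normal.

The medium is described by its absorption coefficient μa (cm⁻¹),
scattering coefficient μs (cm⁻¹), Henyey–Greenstein anisotropy g and
refractive index n; the vision system by photon count, beam radius,
limiting energy level, observed radius, spatial resolution, and the
incident angle of the beam. Photons carry a continuous weight (implicit
capture with transport albedo μs/(μs+μa)), take exponential free paths,
scatter by Henyey–Greenstein, and interact with the surface through the
critical angle and polarization-averaged Fresnel reflection. Two features
target the camera geometry specifically:

- **oblique launch**: the refracted entry direction follows Snell's law,
  φ₂ = asin(sin φ₁ / n), and the tilted beam's circular cross-section is
  stretched into an ellipse on the surface (y divided by cos φ₂);
- **Lambertian correction**: escaping flux is weighted by the cosine of
  the external exit angle, modeling a camera viewing along the normal.

The package also provides the dipole diffusion-theory reflectance model
(Farrell-type, extrapolated boundary) as a closed-form reference, and the
validation statistics (Pearson correlation, RMSE under three scaling
conventions) used to compare simulated profiles against it. The
transport kernel is compiled (Rcpp) with counter-based per-photon random
substreams, and a pure-R reference tracer reproduces the kernel's tallies
bit-for-bit.

## Worked example

Simulate the reference phantom (μa = 0.1056 cm⁻¹, μs′ = 2.529 cm⁻¹,
n = 1.35) with 10⁶ photons on a 0.05 cm grid out to 3 cm, and compare
with diffusion theory:

```r
library(mcbacksim)

phantom <- media_optics(mu_a = 0.1056, mu_s = 2.529, g = 0, n = 1.35)
cfg <- simulation_config(photons = 1e6, beam_radius = 0.05, limit = 1e-9,
                         obs_radius = 3, rpx = 0.05, seed = 1)
res <- run_simulation(phantom, cfg)
res
#> Monte Carlo backscattering run (cpp engine)
#> Turbid medium: mu_a = 0.1056 cm^-1, mu_s = 2.529 cm^-1, g = 0 , n = 1.35
#> Simulation: 1e+06 photons, beam radius 0.05 cm, limit 1e-09,
#>   observed radius 3 cm, resolution 0.05 cm/px, incident angle 0 deg, seed 1
#>   albedo 0.959918, rs 0.02218, cos(critical) 0.6718, maxlen 508
#>   diffuse reflectance rd = 0.41556, absorbed = 0.56226, specular = 0.02218
#>   energy-balance residual = -2.08e-11 (relative)

compare_to_diffusion(res)
#> Profile comparison over 60 radii:
#>   Pearson correlation   0.9734
#>   RMSE (cm^-2)          0.0570
#>   RMSE (0-1 scaling)    0.0774
#>   RMSE (unit-sum)       0.00824
```

Read: 41.6% of the launched light re-emerges as diffuse reflectance
(2.2% was lost to specular reflection at launch, the rest absorbed); the
simulated radial profile correlates at 0.973 with the dipole diffusion
model over the 60 rings outside the incident point, differing by
0.057 cm⁻² RMS in absolute flux. Repeating with the anisotropic
parameterization of the same phantom (`mu_s = 25.29, g = 0.9` — the same
reduced scattering μs′ = (1−g)μs = 2.529 cm⁻¹) gives a lower correlation
(≈0.95) and larger RMSE: anisotropy rotates the near-field profile even
at fixed μs′.

Export the profile, or run everything from the shell:

```r
export_profile(intensity_profile(res), "phantom.tsv")
```

```sh
Rscript inst/cli/mcbacksim.R run --config inst/extdata/phantom_isotropic.json --out phantom.tsv
Rscript inst/cli/mcbacksim.R photons --power 3e-3 --duration 1 --wavelength 670e-9 --n 1.4
```

The `photons` subcommand evaluates the Planck photon budget of a light
pulse: 3 mW for 1 s at 670 nm in n = 1.4 delivers 1.42 × 10¹⁶ photons.

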