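#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Counter-based substreams built on splitmix64.  One substream per
// (seed, variable tag, photon index) triple, so every photon owns an
// independent, reproducible set of random sequences and trajectories do
// not depend on the order in which photons are traced.
//
// Tags: 0 launch (radius, azimuth), 1 rmv (free path), 2 rabs (roulette
// survival), 3 rmu (Henyey-Greenstein deviate), 4 rx (azimuth pair stream).

static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Substream {
  uint64_t s;
  Substream(uint64_t seed, int tag, uint64_t idx) {
    s = mix64(seed + 0x9E3779B97F4A7C15ULL * (uint64_t)(tag + 1)) ^
        mix64(idx + 0xD1B54A32D192ED03ULL);
  }
  // uniform on [0, 1), 53-bit grid
  double next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = mix64(s);
    return (double)(z >> 11) * 1.1102230246251565e-16;
  }
};

// smallest positive value the 53-bit uniform grid can produce; guards log(0)
static const double MIN_UNIF = 1.1102230246251565e-16;

// [[Rcpp::export]]
NumericVector cpp_stream_uniforms(double seed, int tag, double photon_index,
                                  int n) {
  Substream st((uint64_t)seed, tag, (uint64_t)photon_index);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = st.next();
  return out;
}

// First two draws of each photon's launch substream, in bulk:
// column 1 feeds the radius (via sqrt), column 2 the azimuth.
// [[Rcpp::export]]
List cpp_launch_uniforms(double seed, double n_photons) {
  uint64_t np = (uint64_t)n_photons;
  NumericVector u1(np), u2(np);
  for (uint64_t i = 1; i <= np; ++i) {
    Substream st((uint64_t)seed, 0, i);
    u1[i - 1] = st.next();
    u2[i - 1] = st.next();
  }
  return List::create(_["u_radius"] = u1, _["u_azimuth"] = u2);
}

// Full transport kernel.  Geometry: medium occupies z >= 0, surface at
// z = 0, semi-infinite; tilt plane is y-z so the launch direction is
// (0, sin(phi2), cos(phi2)) and the beam footprint stretches along y.
// [[Rcpp::export]]
List cpp_run_simulation(double mu_a, double mu_s, double g, double n_rel,
                        double n_photons, double beam_radius, double limit,
                        double obs_radius, double rpx, double angle_deg,
                        double seed, int maxlen, bool roulette,
                        double roulette_chance) {
  const double mu_t = mu_a + mu_s;
  const double albedo = mu_s / (mu_s + mu_a);
  const double rs =
      ((n_rel - 1.0) / (n_rel + 1.0)) * ((n_rel - 1.0) / (n_rel + 1.0));
  const double cangle = std::sqrt(1.0 - 1.0 / (n_rel * n_rel));
  const double phi2 = std::asin(std::sin(angle_deg * M_PI / 180.0) / n_rel);
  const double sin2 = std::sin(phi2), cos2 = std::cos(phi2);
  const int nbin = 1 + (int)std::nearbyint(obs_radius / rpx);

  NumericVector heat(nbin);
  double rd = 0.0, absorbed = 0.0;
  double n_truncated = 0.0;
  const uint64_t np = (uint64_t)n_photons;
  const uint64_t sd = (uint64_t)seed;

  for (uint64_t i = 1; i <= np; ++i) {
    Substream s_launch(sd, 0, i), s_mv(sd, 1, i), s_abs(sd, 2, i),
        s_mu(sd, 3, i), s_rx(sd, 4, i);

    // launch: oblique entry, elliptic footprint along y
    double rbr = beam_radius * std::sqrt(s_launch.next());
    double rba = 2.0 * M_PI * s_launch.next();
    double weight = 1.0 - rs;
    double u = 0.0, v = sin2, w = cos2;
    double x = rbr * std::cos(rba);
    double y = rbr * std::sin(rba) / cos2;
    double z = 0.0;
    bool alive = true;

    for (int midx = 1; midx <= maxlen && alive; ++midx) {
      // move: exponential free path
      double xi = s_mv.next();
      if (xi < MIN_UNIF) xi = MIN_UNIF;
      double step = -std::log(xi) / mu_t;
      x += step * u;
      y += step * v;
      z += step * w;

      if (z < 0.0) {
        // bounce: mirror, then Fresnel-partial escape above critical angle
        w = -w;
        z = -z;
        if (w > cangle) {
          double t = std::sqrt(1.0 - (1.0 - w * w) * n_rel * n_rel);
          double temp1 = (w - n_rel * t) / (w + n_rel * t);
          double temp = (t - n_rel * w) / (t + n_rel * w);
          double rf = (temp1 * temp1 + temp * temp) / 2.0;
          double esc = (1.0 - rf) * weight;
          rd += esc;
          // Lambertian correction: cosine of the external exit angle
          double lcc = std::fabs(w) / std::sqrt(u * u + v * v + w * w);
          lcc = n_rel * std::sqrt(1.0 - lcc * lcc);
          if (lcc * lcc > 1.0) {
            lcc = 0.0;  // failsafe, unreachable when the cangle test holds
          } else {
            lcc = std::sqrt(1.0 - lcc * lcc);
          }
          double r = std::sqrt(x * x + y * y);
          int k = (int)std::nearbyint(r / rpx);
          if (k < nbin) heat[k] += lcc * esc;
          weight -= esc;
        }
      }

      // absorb: implicit capture, then termination test
      absorbed += weight * (1.0 - albedo);
      weight *= albedo;
      if (weight < limit) {
        if (roulette) {
          if (s_abs.next() < roulette_chance) {
            weight /= roulette_chance;
          } else {
            absorbed += weight;
            alive = false;
          }
        } else {
          absorbed += weight;
          alive = false;
        }
      }
      if (!alive) break;

      // scatter: Henyey-Greenstein deflection, rejection-sampled azimuth
      double rmu = s_mu.next();
      double ct;
      if (g == 0.0) {
        ct = 2.0 * rmu - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rmu);
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      }
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double cphi, sphi;
      for (;;) {
        double a = 2.0 * s_rx.next() - 1.0;
        double b = 2.0 * s_rx.next() - 1.0;
        double rho2 = a * a + b * b;
        if (rho2 > 0.0 && rho2 <= 1.0) {
          double rho = std::sqrt(rho2);
          cphi = a / rho;
          sphi = b / rho;
          break;
        }
      }
      if (std::fabs(w) > 0.99999) {
        u = st * cphi;
        v = st * sphi;
        w = (w >= 0.0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - w * w);
        double un = st * (u * w * cphi - v * sphi) / den + u * ct;
        double vn = st * (v * w * cphi + u * sphi) / den + v * ct;
        double wn = -st * cphi * den + w * ct;
        u = un;
        v = vn;
        w = wn;
      }
    }

    if (alive) {
      // only reachable in roulette mode: survivor hit the event cap
      absorbed += weight;
      n_truncated += 1.0;
    }
  }

  return List::create(_["heat"] = heat, _["rd"] = rd,
                      _["absorbed"] = absorbed,
                      _["specular"] = rs * n_photons,
                      _["n_truncated"] = n_truncated);
}
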