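// Monte Carlo kernel for fluorescence cascade transport in layered slabs.
//
// Analog event-based transport: free paths are drawn from the total
// extinction coefficient, absorption vs scattering is decided at each
// interaction site, and absorption in a fluorescent component triggers a
// Bernoulli(phi_f) re-emission with a new wavelength drawn from the
// component's tabulated emission CDF. Photon weights carry only the Stokes
// energy factor lambda_old / lambda_new; there is no implicit capture and
// no roulette, so integer photon conservation holds exactly.
//
// Reproducibility: each photon runs on its own xoshiro256++ stream seeded
// deterministically from (seed, photon index), so results do not depend on
// execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed_stream(uint64_t seed, uint64_t idx) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + idx * 0xD1B54A32D192ED03ULL + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
};

// ------------------------------------------------------------- helpers ----

// Unpolarized Fresnel reflectance for incidence cosine ci (> 0) going from
// index n1 to n2; returns 1 beyond the critical angle.
static inline double fresnel_unpolarized(double n1, double n2, double ci) {
  if (ci > 1.0) ci = 1.0;
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;
  if (st2 >= 1.0) return 1.0;             // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine by analytic CDF inversion.
static inline double hg_cos(double g, double xi) {
  if (std::fabs(g) < 1e-8) return 2.0 * xi - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Continuous inverse of a CDF tabulated at bin edges (piecewise linear).
static inline double inv_cdf_edges(const double *cdf, const double *edges,
                                   int n_bins, double u) {
  int lo = 0, hi = n_bins;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] <= u) lo = mid; else hi = mid;
  }
  double c0 = cdf[lo], c1 = cdf[lo + 1];
  double frac = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.5;
  return edges[lo] + frac * (edges[lo + 1] - edges[lo]);
}

static inline void rotate_direction(double &ux, double &uy, double &uz,
                                    double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = st * cp; ny = st * sp; nz = (uz >= 0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nz = -st * cp * den + uz * ct;
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / norm; uy = ny / norm; uz = nz / norm;
}

// ---------------------------------------------------------------- kernel ----

// [[Rcpp::export]]
List cpp_mc_run(List resolved, NumericVector source_cdf,
                int launch_geom, int launch_wavelength,
                double n_photons, double seed, bool collect_records) {
  NumericVector edges = resolved["edges"];
  int n_bins = as<int>(resolved["n_bins"]);
  double edge0 = edges[0], step = as<double>(resolved["step"]);
  NumericVector z_bounds = resolved["z_bounds"];
  List mu_a_l = resolved["mu_a"], mu_s_l = resolved["mu_s"],
       g_l = resolved["g"], n_l = resolved["n_layer"];
  IntegerVector is_fluo = resolved["is_fluo"];
  NumericVector phi_f = resolved["phi_f"];
  NumericMatrix em_cdf = resolved["em_cdf"];
  double n_above = as<double>(resolved["n_above"]);
  double n_below = as<double>(resolved["n_below"]);

  int nlay = mu_a_l.size();
  int ncomp = is_fluo.size();
  std::vector<NumericMatrix> MU_A, MU_S, G;
  std::vector<NumericVector> NLAY;
  for (int l = 0; l < nlay; ++l) {
    MU_A.push_back(as<NumericMatrix>(mu_a_l[l]));
    MU_S.push_back(as<NumericMatrix>(mu_s_l[l]));
    G.push_back(as<NumericMatrix>(g_l[l]));
    NLAY.push_back(as<NumericVector>(n_l[l]));
  }
  double z_top = z_bounds[0], z_bot = z_bounds[nlay];

  NumericVector refl(n_bins), trans(n_bins);
  NumericVector launch_w(n_bins), refl_by_launch(n_bins), trans_by_launch(n_bins);
  std::vector<double> n_abs_prim(ncomp, 0.0), n_abs_sec(ncomp, 0.0),
      w_abs_prim(ncomp, 0.0), w_abs_sec(ncomp, 0.0),
      n_emit(ncomp, 0.0), n_term(ncomp, 0.0);
  double n_escaped = 0, n_terminated = 0, n_stuck = 0;
  double n_exit_fluo = 0;  // escaping photons with >= 1 conversion
  std::vector<double> rec;  // 10 columns per exit record
  if (collect_records) rec.reserve((size_t)std::min(n_photons, 2e6) * 10);

  uint64_t useed = (uint64_t)seed;
  long long N = (long long)n_photons;
  Xoshiro rng;

  for (long long i = 0; i < N; ++i) {
    rng.seed_stream(useed, (uint64_t)i);

    // --- launch -------------------------------------------------------
    double lam;
    if (launch_wavelength == 1) {       // stratified: one bin per photon
      int k = (int)(i % n_bins);
      lam = edges[k] + rng.u01() * step;
    } else {
      lam = inv_cdf_edges(source_cdf.begin(), edges.begin(), n_bins, rng.u01());
    }
    int kl = (int)((lam - edge0) / step);
    if (kl < 0) kl = 0; if (kl >= n_bins) kl = n_bins - 1;
    int k_launch = kl;
    launch_w[k_launch] += 1.0;

    double x = 0, y = 0, z = z_top;
    double ux, uy, uz;
    if (launch_geom == 1) {             // cosine-distributed incidence
      double ct = std::sqrt(rng.u01());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.u01();
      ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
    } else {                            // collimated pencil beam
      ux = 0; uy = 0; uz = 1;
    }
    double w = 1.0, lam0 = lam;
    int cycles = 0, layer = 0;
    bool alive = true;

    // entry interface ambient -> first layer at z = z_top
    {
      int k = (int)((lam - edge0) / step);
      if (k < 0) k = 0; if (k >= n_bins) k = n_bins - 1;
      double R = fresnel_unpolarized(n_above, NLAY[0][k], uz);
      if (rng.u01() < R) {
        uz = -uz;                       // specular reflection off the surface
        refl[k] += w; refl_by_launch[k_launch] += w;
        n_escaped += 1;
        if (collect_records) {
          double row[10] = {0, x, y, ux, uy, uz, lam, w, 0, lam0};
          rec.insert(rec.end(), row, row + 10);
        }
        continue;
      } else {
        double eta = n_above / NLAY[0][k];
        double st2 = eta * eta * (1.0 - uz * uz);
        double ct = std::sqrt(std::max(0.0, 1.0 - st2));
        ux *= eta; uy *= eta; uz = ct;
        double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;
      }
    }

    // --- transport loop ----------------------------------------------
    int guard = 0;
    while (alive) {
      // guards against grazing-angle waveguide traps in non-absorbing
      // layers (floating-point artifacts at the critical angle)
      if (++guard > 1000000) { n_stuck += 1; n_terminated += 1; break; }
      int k = (int)((lam - edge0) / step);
      if (k < 0) k = 0; if (k >= n_bins) k = n_bins - 1;
      const NumericMatrix &A = MU_A[layer], &S = MU_S[layer];
      double mu_a_tot = 0, mu_s_tot = 0;
      for (int c = 0; c < ncomp; ++c) {
        mu_a_tot += A(k, c);
        mu_s_tot += S(k, c);
      }
      double mu_t = mu_a_tot + mu_s_tot;

      double s = (mu_t > 0.0)
        ? -std::log1p(-rng.u01()) / mu_t
        : R_PosInf;
      double z_lo = z_bounds[layer], z_hi = z_bounds[layer + 1];
      double db;
      if (uz > 0)      db = (z_hi - z) / uz;
      else if (uz < 0) db = (z - z_lo) / (-uz);
      else             db = R_PosInf;

      if (!(s < db)) {                 // reach the layer boundary first
        if (!std::isfinite(db)) { n_stuck += 1; n_terminated += 1; break; }
        x += db * ux; y += db * uy;
        bool down = uz > 0;
        z = down ? z_hi : z_lo;
        double n1 = NLAY[layer][k];
        double n2;
        int next = down ? layer + 1 : layer - 1;
        if (next < 0)           n2 = n_above;
        else if (next >= nlay)  n2 = n_below;
        else                    n2 = NLAY[next][k];
        double R = fresnel_unpolarized(n1, n2, std::fabs(uz));
        if (rng.u01() < R) {
          uz = -uz;                     // internal reflection
        } else {
          double eta = n1 / n2;
          double st2 = eta * eta * (1.0 - uz * uz);
          double ct = std::sqrt(std::max(0.0, 1.0 - st2));
          ux *= eta; uy *= eta; uz = (down ? ct : -ct);
          double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= norm; uy /= norm; uz /= norm;
          if (next < 0 || next >= nlay) {       // escape
            int side = (next < 0) ? 0 : 1;
            if (side == 0) { refl[k] += w; refl_by_launch[k_launch] += w; }
            else           { trans[k] += w; trans_by_launch[k_launch] += w; }
            n_escaped += 1;
            if (cycles >= 1) n_exit_fluo += 1;
            if (collect_records) {
              double row[10] = {(double)side, x, y, ux, uy, uz, lam, w,
                                (double)cycles, lam0};
              rec.insert(rec.end(), row, row + 10);
            }
            alive = false;
          } else {
            layer = next;
          }
        }
        continue;
      }

      // interaction inside the layer
      x += s * ux; y += s * uy; z += s * uz;
      double xi = rng.u01();
      if (xi < mu_a_tot / mu_t) {
        // Absorption: choose the absorbing component by cumulative mu_a
        double target = rng.u01() * mu_a_tot, cum = 0;
        int c = ncomp - 1;
        for (int j = 0; j < ncomp; ++j) {
          cum += A(k, j);
          if (target < cum) { c = j; break; }
        }
        if (cycles == 0) { n_abs_prim[c] += 1; w_abs_prim[c] += w; }
        else             { n_abs_sec[c] += 1;  w_abs_sec[c] += w; }
        if (!is_fluo[c]) {
          n_term[c] += 1; n_terminated += 1; alive = false;
        } else {
          double xi1 = rng.u01();
          if (xi1 > phi_f[c]) {
            n_term[c] += 1; n_terminated += 1; alive = false;
          } else {
            // re-emission: new wavelength, Stokes weight, isotropic direction
            double lam_new = inv_cdf_edges(&em_cdf(0, c), edges.begin(),
                                           n_bins, rng.u01());
            w *= lam / lam_new;
            lam = lam_new;
            cycles += 1;
            n_emit[c] += 1;
            double ct = 1.0 - 2.0 * rng.u01();
            double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
            double phi = 2.0 * M_PI * rng.u01();
            ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
          }
        }
      } else {
        // Scattering: choose the component by cumulative mu_s, then HG
        double target = rng.u01() * mu_s_tot, cum = 0;
        int c = ncomp - 1;
        for (int j = 0; j < ncomp; ++j) {
          cum += S(k, j);
          if (target < cum) { c = j; break; }
        }
        double ct = hg_cos(G[layer](k, c), rng.u01());
        double phi = 2.0 * M_PI * rng.u01();
        rotate_direction(ux, uy, uz, ct, phi);
      }
    }
  }

  NumericMatrix records(0, 10);
  if (collect_records) {
    size_t n_rec = rec.size() / 10;
    records = NumericMatrix((int)n_rec, 10);
    for (size_t r = 0; r < n_rec; ++r)
      for (int cjj = 0; cjj < 10; ++cjj)
        records(r, cjj) = rec[r * 10 + cjj];
    colnames(records) =
      CharacterVector::create("side", "x", "y", "ux", "uy", "uz",
                              "lambda", "weight", "n_cycles", "lambda_launch");
  }

  return List::create(
    _["refl"] = refl, _["trans"] = trans,
    _["launch_w"] = launch_w,
    _["refl_by_launch"] = refl_by_launch,
    _["trans_by_launch"] = trans_by_launch,
    _["records"] = records,
    _["n_launched"] = (double)N,
    _["n_escaped"] = n_escaped,
    _["n_terminated"] = n_terminated,
    _["n_stuck"] = n_stuck,
    _["n_exit_fluorescent"] = n_exit_fluo,
    _["n_abs_primary"] = NumericVector(n_abs_prim.begin(), n_abs_prim.end()),
    _["n_abs_secondary"] = NumericVector(n_abs_sec.begin(), n_abs_sec.end()),
    _["w_abs_primary"] = NumericVector(w_abs_prim.begin(), w_abs_prim.end()),
    _["w_abs_secondary"] = NumericVector(w_abs_sec.begin(), w_abs_sec.end()),
    _["n_emit"] = NumericVector(n_emit.begin(), n_emit.end()),
    _["n_term"] = NumericVector(n_term.begin(), n_term.end()));
}

// ----------------------------------------------------- exported helpers ----

// [[Rcpp::export]]
NumericVector cpp_sample_hg(double n, double g, double seed) {
  long long N = (long long)n;
  NumericVector out(N);
  Xoshiro rng;
  for (long long i = 0; i < N; ++i) {
    rng.seed_stream((uint64_t)seed, (uint64_t)i);
    out[i] = hg_cos(g, rng.u01());
  }
  return out;
}

// [[Rcpp::export]]
double cpp_hg_cos(double g, double xi) { return hg_cos(g, xi); }

// [[Rcpp::export]]
double cpp_fresnel(double n1, double n2, double cos_i) {
  if (n1 <= 0 || n2 <= 0) stop("refractive indices must be positive");
  return fresnel_unpolarized(n1, n2, cos_i);
}

// [[Rcpp::export]]
NumericVector cpp_sample_cdf_edges(NumericVector cdf, NumericVector edges,
                                   NumericVector u) {
  int n_bins = edges.size() - 1;
  NumericVector out(u.size());
  for (int i = 0; i < u.size(); ++i)
    out[i] = inv_cdf_edges(cdf.begin(), edges.begin(), n_bins, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_stream_uniforms(double n, double seed) {
  long long N = (long long)n;
  NumericVector out(N);
  Xoshiro rng;
  for (long long i = 0; i < N; ++i) {
    rng.seed_stream((uint64_t)seed, (uint64_t)i);
    out[i] = rng.u01();
  }
  return out;
}
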