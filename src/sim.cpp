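// Monte Carlo core for the FRAP simulator.
//
// Molecules diffuse by Gaussian steps inside an ellipsoidal cell (optional
// ellipsoidal nucleus excluded), associate with FA ellipsoids under the
// three-pool scheme mobile <-> medium, medium -> long -> mobile, and are
// bleached by a localized pulse with a 3D intensity profile.  The fitted
// observable is the number of fluorescent molecules inside the target FA
// ellipsoid at every sample instant.
//
// Implementation notes:
//  * per-molecule independent RNG streams (xoshiro256++ seeded via
//    splitmix64 from (run seed, molecule index)) make runs bit-reproducible
//    and independent of molecule ordering;
//  * bound dwell times are sampled as geometric episode lengths, identical
//    in law to per-step Bernoulli draws with p = 1 - exp(-k dt), so bound
//    episodes cost O(1);
//  * association is mean-field: a mobile molecule binds with
//    p = 1 - exp(-k_on,medium dt) per step wherever it is, and is placed
//    uniformly inside an FA ellipsoid on binding.  This reproduces the
//    global steady-state balance defining the effective on rates exactly
//    (the per-volume local rule saturates at probability 1 for most of the
//    physiological rate range and cannot).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

namespace {

struct Xoshiro {
  uint64_t s[4];
  bool has_cache;
  double cache;

  explicit Xoshiro(uint64_t seed) : has_cache(false), cache(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline double norm() {  // Marsaglia polar with cache
    if (has_cache) {
      has_cache = false;
      return cache;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v * f;
    has_cache = true;
    return u * f;
  }
};

struct Ellipsoid {
  double cx, cy, cz, ax, ay, az;
  inline bool contains(double x, double y, double z) const {
    const double dx = (x - cx) / ax, dy = (y - cy) / ay, dz = (z - cz) / az;
    return dx * dx + dy * dy + dz * dz <= 1.0;
  }
};

// Geometric episode length (>= 1 steps) for per-step success probability p.
inline long geom_steps(Xoshiro& rng, double p, long inf) {
  if (p <= 0.0) return inf;
  if (p >= 1.0) return 1;
  const double u = 1.0 - rng.unif();  // (0, 1]
  const double l = std::log(u) / std::log1p(-p);
  long k = 1 + static_cast<long>(std::floor(l));
  if (k < 1) k = 1;
  return k;
}

inline void uniform_in_ellipsoid(Xoshiro& rng, const Ellipsoid& e, double* out) {
  double x, y, z;
  do {
    x = e.cx + e.ax * (2.0 * rng.unif() - 1.0);
    y = e.cy + e.ay * (2.0 * rng.unif() - 1.0);
    z = e.cz + e.az * (2.0 * rng.unif() - 1.0);
  } while (!e.contains(x, y, z));
  out[0] = x;
  out[1] = y;
  out[2] = z;
}

inline void uniform_in_cell(Xoshiro& rng, const Ellipsoid& cell, bool has_nuc,
                            const Ellipsoid& nuc, double* out) {
  double x, y, z;
  do {
    x = cell.cx + cell.ax * (2.0 * rng.unif() - 1.0);
    y = cell.cy + cell.ay * (2.0 * rng.unif() - 1.0);
    z = cell.cz + cell.az * (2.0 * rng.unif() - 1.0);
  } while (!cell.contains(x, y, z) || (has_nuc && nuc.contains(x, y, z)));
  out[0] = x;
  out[1] = y;
  out[2] = z;
}

struct BleachProfile {
  double cx, cy, cz, half, sxy, sz, alpha;
  // Intensity: 1 on a square footprint of half-width `half` centred on
  // (cx, cy), Gaussian shoulders (sd sxy) beyond the square edge laterally,
  // Gaussian (sd sz) axially around cz.
  inline double prob(double x, double y, double z) const {
    const double dx = std::max(std::fabs(x - cx) - half, 0.0);
    const double dy = std::max(std::fabs(y - cy) - half, 0.0);
    const double dz = z - cz;
    const double lat = std::exp(-(dx * dx + dy * dy) / (2.0 * sxy * sxy));
    const double ax = std::exp(-(dz * dz) / (2.0 * sz * sz));
    return 1.0 - std::exp(-alpha * lat * ax);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_simulate_frap(
    int n_mol, double seed, Rcpp::NumericVector cell_half,
    Rcpp::NumericMatrix fa_centres, Rcpp::NumericVector fa_half, int target_fa,
    bool has_nucleus, Rcpp::NumericVector nuc_centre,
    Rcpp::NumericVector nuc_half, double D, double dt, int steps_per_sample,
    int n_samples, Rcpp::IntegerVector bleach_steps, double bl_cx, double bl_cy,
    double bl_cz, double bl_half, double bl_sxy, double bl_sz, double bl_alpha,
    double kon_m, double koff_m, double kon_l, double koff_l, double f_mob,
    double f_med, double f_lng, bool record_states, bool drop_bleached,
    int transport) {
  // transport 0: explicit Gaussian diffusion for every mobile step.
  // transport 1: hybrid "well-mixed" mobile transport — explicit diffusion
  //   only within a neighbourhood of the target FA (where the molecule can
  //   contribute transit counts), elsewhere the molecule's position is a
  //   uniform draw over the accessible volume whenever it is needed (FA
  //   transit occupancy per sample is Bernoulli(phi), bleach positions are
  //   drawn at pulse time).  Exact in distribution at equilibrium because
  //   association is mean-field; it only smooths a ~2 s transit transient.
  const Ellipsoid cell{0.0, 0.0, 0.0, cell_half[0], cell_half[1], cell_half[2]};
  const Ellipsoid nuc{has_nucleus ? nuc_centre[0] : 0.0,
                      has_nucleus ? nuc_centre[1] : 0.0,
                      has_nucleus ? nuc_centre[2] : 0.0,
                      has_nucleus ? nuc_half[0] : 1.0,
                      has_nucleus ? nuc_half[1] : 1.0,
                      has_nucleus ? nuc_half[2] : 1.0};
  const int n_fa = fa_centres.nrow();
  std::vector<Ellipsoid> fas(n_fa);
  for (int j = 0; j < n_fa; ++j) {
    fas[j] = Ellipsoid{fa_centres(j, 0), fa_centres(j, 1), fa_centres(j, 2),
                       fa_half[0], fa_half[1], fa_half[2]};
  }
  const Ellipsoid target = fas[target_fa];
  const BleachProfile pulse{bl_cx, bl_cy, bl_cz, bl_half, bl_sxy, bl_sz,
                            bl_alpha};

  const long total_steps = static_cast<long>(n_samples) * steps_per_sample;
  const int nb = bleach_steps.size();
  std::vector<long> bsteps(nb);
  for (int i = 0; i < nb; ++i) bsteps[i] = bleach_steps[i];

  const double sd = std::sqrt(2.0 * D * dt);
  const double p_bind = (kon_m > 0.0) ? -std::expm1(-kon_m * dt) : 0.0;
  const double exit_med_rate = koff_m + kon_l;
  const double p_exit_med =
      (exit_med_rate > 0.0) ? -std::expm1(-exit_med_rate * dt) : 0.0;
  const double q_long = (exit_med_rate > 0.0) ? kon_l / exit_med_rate : 0.0;
  const double p_exit_long = (koff_l > 0.0) ? -std::expm1(-koff_l * dt) : 0.0;
  const long INF_STEPS = total_steps + 1;

  // Difference arrays over sample indices 1..n_samples.
  std::vector<double> fl_diff(n_samples + 2, 0.0);
  std::vector<double> st_diff[3];
  if (record_states) {
    for (int k = 0; k < 3; ++k) st_diff[k].assign(n_samples + 2, 0.0);
  }
  // Per-pulse bookkeeping: bleached counts by state inside the target FA,
  // plus total bleached anywhere.
  Rcpp::NumericMatrix bleach_book(nb, 4);

  const uint64_t base =
      static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 0x12345678ULL;

  // accessible-volume fraction of the target FA (transit occupancy of a
  // well-mixed mobile molecule at a sample instant)
  const double four_thirds_pi = 4.18879020478639053;
  double v_acc = four_thirds_pi * cell.ax * cell.ay * cell.az;
  if (has_nucleus) v_acc -= four_thirds_pi * nuc.ax * nuc.ay * nuc.az;
  const double v_fa = four_thirds_pi * fa_half[0] * fa_half[1] * fa_half[2];
  const double phi = v_fa / v_acc;
  // lateral neighbourhood of the target FA inside which mobile transport
  // stays explicit (margin ~ a few diffusion steps)
  const double nb_x = fa_half[0] + 1.2, nb_y = fa_half[1] + 1.2;
  const auto in_neighbourhood = [&](const double* p) {
    return std::fabs(p[0] - target.cx) < nb_x &&
           std::fabs(p[1] - target.cy) < nb_y;
  };

  for (int i = 0; i < n_mol; ++i) {
    Xoshiro rng(base ^ (static_cast<uint64_t>(i) * 0xD1342543DE82EF95ULL + 1));
    int state;  // 0 mobile, 1 medium, 2 long
    {
      const double u = rng.unif();
      state = (u < f_mob) ? 0 : ((u < f_mob + f_med) ? 1 : 2);
    }
    double pos[3];
    if (state == 0) {
      uniform_in_cell(rng, cell, has_nucleus, nuc, pos);
    } else {
      const int j = std::min(static_cast<int>(rng.unif() * n_fa), n_fa - 1);
      uniform_in_ellipsoid(rng, fas[j], pos);
    }
    bool fluor = true;
    bool mixed = false;  // transport 1: position currently undefined
    int bptr = 0;
    long step = 0;

    while (step < total_steps) {
      const long barrier = (bptr < nb) ? bsteps[bptr] : total_steps;
      const long horizon = std::min(barrier, total_steps);

      if (state != 0) {
        const double p = (state == 1) ? p_exit_med : p_exit_long;
        const long L = geom_steps(rng, p, INF_STEPS);
        long ep_end = step + L;
        if (ep_end > horizon) ep_end = horizon;
        const bool exits = (step + L == ep_end);
        // contribute samples s with step < s*sps <= ep_end
        const long s_lo = step / steps_per_sample + 1;
        const long s_hi = ep_end / steps_per_sample;
        if (s_lo <= s_hi) {
          if (fluor && target.contains(pos[0], pos[1], pos[2])) {
            fl_diff[s_lo] += 1.0;
            fl_diff[s_hi + 1] -= 1.0;
          }
          if (record_states) {
            st_diff[state][s_lo] += 1.0;
            st_diff[state][s_hi + 1] -= 1.0;
          }
        }
        step = ep_end;
        if (exits) {
          if (state == 1) {
            state = (rng.unif() < q_long) ? 2 : 0;
          } else {
            state = 0;
          }
        }
      } else {
        const long L = geom_steps(rng, p_bind, INF_STEPS);
        long ep_end = step + L;
        if (ep_end > horizon) ep_end = horizon;
        const bool binds = (step + L == ep_end);
        bool walk = (transport == 0) || (!mixed && in_neighbourhood(pos));
        while (step < ep_end && walk) {
          ++step;
          // Gaussian step; a proposal leaving the accessible volume is
          // rejected and the molecule stays put for this step (symmetric
          // proposal + rejection keeps the uniform equilibrium exact and
          // conserves molecules).
          {
            const double nx = pos[0] + sd * rng.norm();
            const double ny = pos[1] + sd * rng.norm();
            const double nz = pos[2] + sd * rng.norm();
            if (cell.contains(nx, ny, nz) &&
                !(has_nucleus && nuc.contains(nx, ny, nz))) {
              pos[0] = nx;
              pos[1] = ny;
              pos[2] = nz;
            }
          }
          if (step % steps_per_sample == 0) {
            const long s = step / steps_per_sample;
            if (fluor && target.contains(pos[0], pos[1], pos[2]))
              fl_diff[s] += 1.0, fl_diff[s + 1] -= 1.0;
            if (record_states) st_diff[0][s] += 1.0, st_diff[0][s + 1] -= 1.0;
          }
          if (transport == 1 && !in_neighbourhood(pos)) walk = false;
        }
        if (step < ep_end) {
          // well-mixed remainder of the mobile episode: occupancy of the
          // target FA at each sample instant is Bernoulli(phi)
          mixed = true;
          const long s_lo = step / steps_per_sample + 1;
          const long s_hi = ep_end / steps_per_sample;
          if (record_states && s_lo <= s_hi) {
            st_diff[0][s_lo] += 1.0;
            st_diff[0][s_hi + 1] -= 1.0;
          }
          if (fluor && s_lo <= s_hi && phi > 0) {
            long k = s_lo - 1;
            for (;;) {
              k += geom_steps(rng, phi, n_samples + 2L);
              if (k > s_hi) break;
              fl_diff[k] += 1.0;
              fl_diff[k + 1] -= 1.0;
            }
          }
          step = ep_end;
        }
        if (binds) {
          state = 1;
          const int j = std::min(static_cast<int>(rng.unif() * n_fa), n_fa - 1);
          uniform_in_ellipsoid(rng, fas[j], pos);
          mixed = false;
        }
      }

      // Bleach pulse(s) firing at this step (after the step's dynamics and
      // sampling).
      while (bptr < nb && step == bsteps[bptr]) {
        if (fluor) {
          if (mixed) {  // well-mixed mobile: draw the instantaneous position
            uniform_in_cell(rng, cell, has_nucleus, nuc, pos);
            mixed = false;
          }
          const double P = pulse.prob(pos[0], pos[1], pos[2]);
          if (rng.unif() < P) {
            fluor = false;
            bleach_book(bptr, 3) += 1.0;
            if (target.contains(pos[0], pos[1], pos[2]))
              bleach_book(bptr, state) += 1.0;
          }
        }
        ++bptr;
      }
      if (!fluor && drop_bleached && !record_states) break;
    }
  }

  Rcpp::NumericVector counts(n_samples);
  double acc = 0.0;
  for (int s = 1; s <= n_samples; ++s) {
    acc += fl_diff[s];
    counts[s - 1] = acc;
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("counts") = counts,
                                      Rcpp::Named("bleach_book") = bleach_book);
  if (record_states) {
    Rcpp::NumericMatrix states(n_samples, 3);
    for (int k = 0; k < 3; ++k) {
      double a = 0.0;
      for (int s = 1; s <= n_samples; ++s) {
        a += st_diff[k][s];
        states(s - 1, k) = a;
      }
    }
    out["state_counts"] = states;
  }
  return out;
}

// Advance positions by n_steps Gaussian diffusion steps (mobile molecules
// only), with the same boundary rule as the full simulation.  `bounded`
// FALSE gives free-space diffusion (used to verify the step statistics).
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_diffusion_steps(Rcpp::NumericMatrix pos,
                                        Rcpp::LogicalVector mobile,
                                        int n_steps, double D, double dt,
                                        bool bounded,
                                        Rcpp::NumericVector cell_half,
                                        bool has_nucleus,
                                        Rcpp::NumericVector nuc_centre,
                                        Rcpp::NumericVector nuc_half,
                                        double seed) {
  const int n = pos.nrow();
  Rcpp::NumericMatrix out = Rcpp::clone(pos);
  const Ellipsoid cell{0.0, 0.0, 0.0, cell_half[0], cell_half[1], cell_half[2]};
  const Ellipsoid nuc{has_nucleus ? nuc_centre[0] : 0.0,
                      has_nucleus ? nuc_centre[1] : 0.0,
                      has_nucleus ? nuc_centre[2] : 0.0,
                      has_nucleus ? nuc_half[0] : 1.0,
                      has_nucleus ? nuc_half[1] : 1.0,
                      has_nucleus ? nuc_half[2] : 1.0};
  const double sd = std::sqrt(2.0 * D * dt);
  const uint64_t base =
      static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 0xABCDEFULL;
  for (int i = 0; i < n; ++i) {
    if (!mobile[i]) continue;
    Xoshiro rng(base ^ (static_cast<uint64_t>(i) * 0xD1342543DE82EF95ULL + 1));
    double x = out(i, 0), y = out(i, 1), z = out(i, 2);
    for (int s = 0; s < n_steps; ++s) {
      if (!bounded) {
        x += sd * rng.norm();
        y += sd * rng.norm();
        z += sd * rng.norm();
        continue;
      }
      const double nx = x + sd * rng.norm();
      const double ny = y + sd * rng.norm();
      const double nz = z + sd * rng.norm();
      if (cell.contains(nx, ny, nz) &&
          !(has_nucleus && nuc.contains(nx, ny, nz))) {
        x = nx;
        y = ny;
        z = nz;
      }
    }
    out(i, 0) = x;
    out(i, 1) = y;
    out(i, 2) = z;
  }
  return out;
}

// Uniform positions in the accessible cell volume / inside FA ellipsoids.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_uniform_positions(int n, Rcpp::NumericVector cell_half,
                                          bool has_nucleus,
                                          Rcpp::NumericVector nuc_centre,
                                          Rcpp::NumericVector nuc_half,
                                          double seed) {
  const Ellipsoid cell{0.0, 0.0, 0.0, cell_half[0], cell_half[1], cell_half[2]};
  const Ellipsoid nuc{has_nucleus ? nuc_centre[0] : 0.0,
                      has_nucleus ? nuc_centre[1] : 0.0,
                      has_nucleus ? nuc_centre[2] : 0.0,
                      has_nucleus ? nuc_half[0] : 1.0,
                      has_nucleus ? nuc_half[1] : 1.0,
                      has_nucleus ? nuc_half[2] : 1.0};
  Rcpp::NumericMatrix out(n, 3);
  Xoshiro rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 7ULL);
  double p[3];
  for (int i = 0; i < n; ++i) {
    uniform_in_cell(rng, cell, has_nucleus, nuc, p);
    out(i, 0) = p[0];
    out(i, 1) = p[1];
    out(i, 2) = p[2];
  }
  return out;
}
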