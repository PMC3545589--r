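// Overdamped Langevin (Brownian dynamics) engine for quasi-1D ion
// permeation through a nanotube channel.
//
// Model, in reduced units (length A, time ps, energy kT):
//   z <- z + D(z) F(z) dt + D'(z) dt + sqrt(2 D(z) dt) eta
// with F the deterministic force (PMF mean force inside the pore, applied
// field across the pore, pairwise axial Coulomb between ions), and the
// D'(z) drift the Ito correction required for position-dependent diffusion
// to preserve Boltzmann statistics.
//
// Reservoir slabs at both ends are concentration-clamped: every step each
// slab is resampled to a Poisson-drawn target count (mean = c * slab
// volume), inserting uniformly and removing at random, which realises
// Dirichlet concentration boundary conditions at the pore faces. Outer
// domain boundaries are reflective. Complete pore traversals are counted
// per direction.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Table {
  double lo, inv_dx;
  const double* y;
  int n;
  double operator()(double x) const {
    double t = (x - lo) * inv_dx;
    if (t <= 0) return y[0];
    if (t >= n - 1) return y[n - 1];
    int i = (int)t;
    double f = t - i;
    return y[i] * (1 - f) + y[i + 1] * f;
  }
};

// [[Rcpp::export]]
List bd_run(NumericVector grid, NumericVector force_det, NumericVector Dtab,
            NumericVector dDdz, double dt, double n_steps_d,
            double equil_steps_d, double pore_lo, double pore_hi,
            double res_len, double area_A2, double conc_left_A3,
            double conc_right_A3, int valence, bool interactions,
            double eps_pore, double eps_res, double min_dist,
            double coulomb_kT_A, double hist_lo, double hist_hi,
            double hist_bin, int thin, int seed, double clamp_buffer) {
  const int ng = grid.size();
  const double glo = grid[0];
  const double inv_dx = (ng - 1) / (grid[ng - 1] - glo);
  Table Ftab{glo, inv_dx, REAL(force_det), ng};
  Table Dfun{glo, inv_dx, REAL(Dtab), ng};
  Table dDfun{glo, inv_dx, REAL(dDdz), ng};

  const double dom_lo = pore_lo - res_len;
  const double dom_hi = pore_hi + res_len;
  const double cross_lo = pore_lo - clamp_buffer;  // inner slab edges
  const double cross_hi = pore_hi + clamp_buffer;
  const double slab_len = res_len - clamp_buffer;
  const double mean_left = conc_left_A3 * area_A2 * slab_len;
  const double mean_right = conc_right_A3 * area_A2 * slab_len;
  const long long n_steps = (long long)n_steps_d;
  const long long equil_steps = (long long)equil_steps_d;

  std::mt19937_64 rng((unsigned long long)seed * 2654435761ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::poisson_distribution<int> pois_left(mean_left > 0 ? mean_left : 1e-12);
  std::poisson_distribution<int> pois_right(mean_right > 0 ? mean_right : 1e-12);

  std::vector<double> z;            // positions
  std::vector<signed char> side;    // last bulk side visited: -1 left, +1 right
  z.reserve(64);
  side.reserve(64);

  long long cross_lr = 0, cross_rl = 0;
  const int nbin = std::max(1, (int)std::round((hist_hi - hist_lo) / hist_bin));
  std::vector<double> hist(nbin, 0.0);
  double occ_sum = 0.0;
  long long n_samp = 0;
  bool unstable = false;
  const double q2 = (double)valence * (double)valence;

  std::vector<double> force;
  std::vector<size_t> members;
  force.reserve(64);
  members.reserve(64);

  for (long long step = 0; step < n_steps && !unstable; ++step) {
    // --- reservoir clamping ---
    for (int sideflag = 0; sideflag < 2; ++sideflag) {
      // the clamped slab stops `clamp_buffer` short of the pore face
      // (Milstein boundary displacement, ~0.8258 sqrt(D dt)), so that the
      // effective Dirichlet plane of the discrete-time scheme sits at the
      // face itself rather than inside the pore
      const bool left = (sideflag == 0);
      const double slo = left ? dom_lo : pore_hi + clamp_buffer;
      const double shi = left ? pore_lo - clamp_buffer : dom_hi;
      const double mean = left ? mean_left : mean_right;
      if (mean <= 0.0) {
        // remove everything in an empty-bath slab
        for (size_t i = z.size(); i-- > 0;)
          if (z[i] >= slo && z[i] <= shi) {
            z[i] = z.back(); z.pop_back();
            side[i] = side.back(); side.pop_back();
          }
        continue;
      }
      // clamp the slab to a Poisson-drawn target count (mean = c * slab
      // volume): top up with uniform insertions or remove random members,
      // realising a Dirichlet concentration boundary at the pore face
      int target = left ? pois_left(rng) : pois_right(rng);
      members.clear();
      for (size_t i = 0; i < z.size(); ++i)
        if (z[i] >= slo && z[i] <= shi) members.push_back(i);
      int cur = (int)members.size();
      if (cur < target) {
        for (int a = 0; a < target - cur; ++a) {
          z.push_back(slo + (shi - slo) * unif(rng));
          side.push_back(left ? -1 : +1);
        }
      } else if (cur > target) {
        for (int a = 0; a < cur - target; ++a) {
          int pick = (int)(unif(rng) * members.size());
          if (pick >= (int)members.size()) pick = (int)members.size() - 1;
          size_t idx = members[pick];
          size_t last = z.size() - 1;
          z[idx] = z[last]; side[idx] = side[last];
          z.pop_back(); side.pop_back();
          members.erase(members.begin() + pick);
          for (auto& m : members) if (m == last) m = idx;
        }
      }
    }

    const size_t n = z.size();
    if (n == 0) { if (step >= equil_steps && (step % thin) == 0) ++n_samp; continue; }

    // --- forces ---
    force.assign(n, 0.0);
    for (size_t i = 0; i < n; ++i) force[i] = Ftab(z[i]);
    if (interactions && n > 1) {
      for (size_t i = 0; i < n; ++i)
        for (size_t j = i + 1; j < n; ++j) {
          double d = z[i] - z[j];
          double ad = std::fabs(d);
          if (ad < min_dist) ad = min_dist;
          double mid = 0.5 * (z[i] + z[j]);
          double eps = (mid >= pore_lo && mid <= pore_hi) ? eps_pore : eps_res;
          double fmag = coulomb_kT_A * q2 / (eps * ad * ad);
          double s = (d >= 0) ? 1.0 : -1.0;
          force[i] += s * fmag;
          force[j] -= s * fmag;
        }
    }

    // --- update ---
    for (size_t i = 0; i < n; ++i) {
      double D = Dfun(z[i]);
      double drift = D * force[i] * dt + dDfun(z[i]) * dt;
      if (std::fabs(drift) > 1.0) { unstable = true; break; }
      double zn = z[i] + drift + std::sqrt(2.0 * D * dt) * gauss(rng);
      // reflective outer walls
      if (zn < dom_lo) zn = 2 * dom_lo - zn;
      if (zn > dom_hi) zn = 2 * dom_hi - zn;
      if (zn < dom_lo) zn = dom_lo;  // pathological double reflection
      if (zn > dom_hi) zn = dom_hi;
      z[i] = zn;
      // crossing bookkeeping (counted after equilibration only); the
      // counting planes coincide with the clamped-slab edges so that an ion
      // is registered before the bath clamp can recycle it
      if (zn < cross_lo) {
        if (side[i] == +1 && step >= equil_steps) ++cross_rl;
        side[i] = -1;
      } else if (zn > cross_hi) {
        if (side[i] == -1 && step >= equil_steps) ++cross_lr;
        side[i] = +1;
      }
    }
    if (unstable) break;

    // --- sampling ---
    if (step >= equil_steps && (step % thin) == 0) {
      ++n_samp;
      int inpore = 0;
      for (size_t i = 0; i < n; ++i) {
        if (z[i] >= pore_lo && z[i] <= pore_hi) ++inpore;
        if (z[i] >= hist_lo && z[i] < hist_hi) {
          int b = (int)((z[i] - hist_lo) / hist_bin);
          if (b >= 0 && b < nbin) hist[b] += 1.0;
        }
      }
      occ_sum += inpore;
    }
  }

  return List::create(
    _["crossings_lr"] = (double)cross_lr,
    _["crossings_rl"] = (double)cross_rl,
    _["hist_counts"] = NumericVector(hist.begin(), hist.end()),
    _["n_samples"] = (double)n_samp,
    _["occupancy_sum"] = occ_sum,
    _["unstable"] = unstable);
}
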