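#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform grid; clamped at the ends.
static inline double interp_u(const std::vector<double>& u, double z0,
                              double dz, double z) {
  if (u.empty()) return 0.0;
  double s = (z - z0) / dz;
  if (s <= 0.0) return u.front();
  int i = (int)std::floor(s);
  if (i >= (int)u.size() - 1) return u.back();
  double f = s - i;
  return u[i] * (1.0 - f) + u[i + 1] * f;
}

struct Recorder {
  std::vector<int> frame, id;
  std::vector<double> z;
  void rec(int f, int i, double zz) {
    frame.push_back(f);
    id.push_back(i);
    z.push_back(zz);
  }
  List as_list() const {
    return List::create(_["frame"] = wrap(frame), _["id"] = wrap(id),
                        _["z"] = wrap(z));
  }
};

// Discrete single-file vacancy-hopping chain.
//
// Sites 1..n_sites sit in the pore; sites 0 and n_sites+1 are reservoir
// buffer slots coupled grand-canonically (delete with prob p_ex*(1-q),
// insert into an empty buffer with prob p_ex*q, so the isolated buffer
// occupancy is Bernoulli(q)).  Particles hop to an adjacent empty site
// with attempt probability p_hop per step and Metropolis acceptance on
// the site potential (in kT units; buffers at 0).  Hard-core exclusion
// is built in, so in-pore order is preserved exactly.
//
// In addition to single-particle vacancy hops, a concerted knock-on
// move is attempted at each boundary with probability p_push per
// step: when the pore column is completely occupied, an occupied
// buffer pushes the whole column one site forward, ejecting the far
// particle into the (empty) far buffer.  The reverse move is the
// mirrored push from the other buffer, with the same attempt
// probability and zero energy difference, so the stationary
// (grand-canonical product) measure is unchanged -- the move only
// adds the concerted column-translation channel characteristic of
// tight single-file pores.
//
// Returns site indices; the caller maps sites to z coordinates.
// [[Rcpp::export]]
List cpp_sim_hopping(int n_sites, double q_buf, double p_hop, double p_ex,
                     double p_push, NumericVector u_site, int n_steps,
                     int sample_every, int burnin_steps) {
  int ntot = n_sites + 2;
  std::vector<int> occ(ntot, 0);  // 0 = empty, else particle id
  std::vector<double> u(ntot, 0.0);
  for (int i = 0; i < n_sites; ++i) u[i + 1] = u_site[i];
  double p_ins = p_ex * q_buf;
  double p_del = p_ex * (1.0 - q_buf);
  int next_id = 1;

  std::vector<int> perm(ntot);
  for (int i = 0; i < ntot; ++i) perm[i] = i;

  Recorder out;
  int frame = 0;

  // Initial fill: buffers from Bernoulli(q); pore sites from the
  // grand-canonical single-site law with the buffer activity.
  double act = (q_buf >= 1.0) ? 1e6 : q_buf / (1.0 - q_buf);
  for (int i = 0; i < ntot; ++i) {
    double qi = (i == 0 || i == ntot - 1)
                    ? q_buf
                    : act * std::exp(-u[i]) / (1.0 + act * std::exp(-u[i]));
    if (R::runif(0, 1) < qi) occ[i] = next_id++;
  }

  int total = burnin_steps + n_steps;
  for (int step = 0; step <= total; ++step) {
    if (step >= burnin_steps && ((step - burnin_steps) % sample_every) == 0) {
      for (int i = 0; i < ntot; ++i)
        if (occ[i]) out.rec(frame, occ[i], (double)i);
      ++frame;
    }
    if (step == total) break;

    // buffer birth-death
    for (int b = 0; b < 2; ++b) {
      int i = (b == 0) ? 0 : ntot - 1;
      if (occ[i]) {
        if (R::runif(0, 1) < p_del) occ[i] = 0;
      } else {
        if (R::runif(0, 1) < p_ins) occ[i] = next_id++;
      }
    }

    // random-order sequential hop attempts
    for (int i = ntot - 1; i > 0; --i) {
      int j = (int)std::floor(R::runif(0, 1) * (i + 1));
      std::swap(perm[i], perm[j]);
    }
    for (int k = 0; k < ntot; ++k) {
      int s = perm[k];
      if (!occ[s]) continue;
      if (R::runif(0, 1) >= p_hop) continue;
      int t = s + (R::runif(0, 1) < 0.5 ? -1 : 1);
      if (t < 0 || t >= ntot) continue;
      if (occ[t]) continue;
      double du = u[t] - u[s];
      if (du <= 0.0 || R::runif(0, 1) < std::exp(-du)) {
        occ[t] = occ[s];
        occ[s] = 0;
      }
    }

    // concerted full-column knock-on at the two boundaries
    for (int b = 0; b < 2; ++b) {
      if (R::runif(0, 1) >= p_push) continue;
      int buf = (b == 0) ? 0 : ntot - 1;
      int far = (b == 0) ? ntot - 1 : 0;
      int dir = (b == 0) ? 1 : -1;
      if (!occ[buf] || occ[far]) continue;
      bool full = true;
      for (int i = 1; i < ntot - 1; ++i)
        if (!occ[i]) { full = false; break; }
      if (!full) continue;
      for (int i = far; i != buf; i -= dir) occ[i] = occ[i - dir];
      occ[buf] = 0;
    }
  }
  return out.as_list();
}

// Overdamped Brownian dynamics of point/hard-core particles on a 1D
// channel axis with an external potential U(z) (kT units, uniform grid),
// optional hard-core no-passing exclusion (move rejection), reflecting
// outer walls, and grand-canonical buffer slabs of width w_buf beyond
// each pore end when rho > 0.  Exclusion applies only inside the pore
// region (extended by one core diameter): the buffer slabs represent
// bulk-like vestibule water, where molecules can pass one another.
// [[Rcpp::export]]
List cpp_sim_brownian(double z_lo, double z_hi, double w_buf, double D,
                      double dt, int n_steps, int sample_every,
                      int burnin_steps, double radius, NumericVector u_tab,
                      double u_z0, double u_dz, double rho, double v_slab,
                      double k_gc, int n_init) {
  bool open = rho > 0.0;
  double lo = open ? z_lo - w_buf : z_lo;
  double hi = open ? z_hi + w_buf : z_hi;
  std::vector<double> u(u_tab.begin(), u_tab.end());

  std::vector<double> z;
  std::vector<int> id;
  int next_id = 1;
  double dcore = 2.0 * radius;
  double zone_lo = z_lo - dcore, zone_hi = z_hi + dcore;

  auto in_zone = [&](double zz) { return zz >= zone_lo && zz <= zone_hi; };
  // overlap against particles inside the exclusion zone
  auto overlaps = [&](double zz, int skip) {
    if (dcore <= 0.0 || !in_zone(zz)) return false;
    for (size_t m = 0; m < z.size(); ++m)
      if ((int)m != skip && in_zone(z[m]) && std::fabs(z[m] - zz) < dcore)
        return true;
    return false;
  };

  // initial placement
  if (open) {
    int n0 = (int)std::round(rho * v_slab);
    for (int b = 0; b < 2; ++b)
      for (int m = 0; m < n0; ++m) {
        double zz = (b == 0) ? lo + R::runif(0, 1) * w_buf
                             : z_hi + R::runif(0, 1) * w_buf;
        if (!overlaps(zz, -1)) {
          z.push_back(zz);
          id.push_back(next_id++);
        }
      }
  } else {
    for (int m = 0; m < n_init; ++m) {
      for (int tries = 0; tries < 200; ++tries) {
        double zz = lo + R::runif(0, 1) * (hi - lo);
        if (!overlaps(zz, -1)) {
          z.push_back(zz);
          id.push_back(next_id++);
          break;
        }
      }
    }
  }

  double sd = std::sqrt(2.0 * D * dt);
  double p_del = k_gc * dt;
  double p_ins = k_gc * dt * rho * v_slab;
  double eps = (u_dz > 0) ? 0.5 * u_dz : 1e-3;

  Recorder out;
  int frame = 0;
  int total = burnin_steps + n_steps;

  for (int step = 0; step <= total; ++step) {
    if (step >= burnin_steps && ((step - burnin_steps) % sample_every) == 0) {
      for (size_t m = 0; m < z.size(); ++m) out.rec(frame, id[m], z[m]);
      ++frame;
    }
    if (step == total) break;

    // moves, random order; reject overlap or passing
    size_t n = z.size();
    for (size_t k = 0; k < n; ++k) {
      size_t m = (size_t)std::floor(R::runif(0, 1) * n);
      if (m >= n) m = n - 1;
      double zz = z[m];
      double f = 0.0;
      if (!u.empty())
        f = -(interp_u(u, u_z0, u_dz, zz + eps) -
              interp_u(u, u_z0, u_dz, zz - eps)) /
            (2.0 * eps);
      double znew = zz + D * f * dt + sd * R::norm_rand();
      // reflecting outer walls
      if (znew < lo) znew = 2.0 * lo - znew;
      if (znew > hi) znew = 2.0 * hi - znew;
      if (znew < lo) znew = lo;  // extreme step safety
      if (znew > hi) znew = hi;
      if (dcore > 0.0 && (in_zone(zz) || in_zone(znew))) {
        bool bad = false;
        for (size_t p = 0; p < z.size(); ++p) {
          if (p == m || !in_zone(z[p])) continue;
          if (in_zone(znew) && std::fabs(z[p] - znew) < dcore) {
            bad = true;
            break;
          }
          // no passing within the zone
          if (in_zone(zz) &&
              ((z[p] - zz) > 0) != ((z[p] - znew) > 0)) {
            bad = true;
            break;
          }
        }
        if (bad) continue;
      }
      z[m] = znew;
    }

    if (open) {
      // deletions (buffer occupants only)
      for (size_t m = 0; m < z.size();) {
        if ((z[m] < z_lo || z[m] > z_hi) && R::runif(0, 1) < p_del) {
          z[m] = z.back();
          id[m] = id.back();
          z.pop_back();
          id.pop_back();
        } else {
          ++m;
        }
      }
      // insertion attempt per slab
      for (int b = 0; b < 2; ++b) {
        if (R::runif(0, 1) < p_ins) {
          double zz = (b == 0) ? lo + R::runif(0, 1) * w_buf
                               : z_hi + R::runif(0, 1) * w_buf;
          if (!overlaps(zz, -1)) {
            z.push_back(zz);
            id.push_back(next_id++);
          }
        }
      }
    }
  }
  return out.as_list();
}
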