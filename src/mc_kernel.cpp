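// Meridian-plane polarized Monte Carlo photon transport through a turbid
// slab of spherical Mie scatterers.
//
// Coordinates: z is the slab depth axis (0 at the illuminated surface,
// increasing into the slab), x the lateral axis of the detector strips,
// y the out-of-plane axis.  The photon carries an orthonormal triad
// (u, v, w): u the propagation direction, v the Stokes "parallel" axis,
// w = u x v.  Carrying the frame explicitly makes every reference-plane
// rotation a plain vector operation and avoids the polar singularities
// of meridian bookkeeping; the scattering density
//   P(theta, phi) ~ [M11 S0 + M12 (S1 cos2phi + S2 sin2phi)] sin(theta)
// is covariant under frame rotations, so it can be sampled in whichever
// frame the Stokes vector is currently expressed.
//
// theta is drawn from its exact marginal (~ M11 sin(theta), tabulated
// inverse CDF), phi from its conditional by rejection with envelope
// 1 + |M12/M11| * sqrt(S1^2+S2^2) <= 2.  Absorption is handled by
// implicit capture (weight *= mu_s/mu_t per event) with Russian
// roulette below a weight threshold.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline Vec3 normalize(Vec3 a) {
  double n = std::sqrt(dot(a, a));
  return (1.0 / n) * a;
}

// side tallies within / outside a detector window, plus phi bins
struct SideTally {
  double w = 0, ws3 = 0, ws3sq = 0, wev = 0;
  long n = 0;
  double w_outside = 0;   // exits on this side missing the detector window
  std::vector<double> bin_w, bin_ws3;
  SideTally() : bin_w(9, 0.0), bin_ws3(9, 0.0) {}
};

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(NumericVector theta, NumericVector M11, NumericVector M12,
               NumericVector M33, NumericVector M34,
               double mu_a, double mu_s,
               double half_width, double depth, double strip_half,
               double refl_x0, double refl_x1,
               double trans_x0, double trans_x1,
               int n_photons, double incident_rad,
               double weight_min, double p_survive, int max_events,
               bool keep_records, bool passage,
               int px_n, int pz_n) {
  const int nt = theta.size();
  if (nt < 3) stop("phase table too small");
  const double mu_t = mu_a + mu_s;
  if (!(mu_t > 0) || !(mu_s > 0)) stop("mu_s must be > 0");
  const double albedo = mu_s / mu_t;

  // cumulative trapezoid of M11 sin(theta) -> theta inverse CDF
  std::vector<double> cdf(nt), sth(nt);
  for (int i = 0; i < nt; ++i) sth[i] = std::sin(theta[i]);
  cdf[0] = 0.0;
  for (int i = 1; i < nt; ++i) {
    double seg = 0.5 * (M11[i] * sth[i] + M11[i - 1] * sth[i - 1]) *
                 (theta[i] - theta[i - 1]);
    cdf[i] = cdf[i - 1] + seg;
  }
  const double norm = cdf[nt - 1];
  for (int i = 0; i < nt; ++i) cdf[i] /= norm;

  SideTally refl, trans;
  double absorbed = 0, lateral_escape = 0, roulette_kill = 0, roulette_gain = 0;
  long n_runaway = 0;
  double total_events = 0;

  std::vector<double> rec_side, rec_x, rec_y, rec_phi, rec_s1, rec_s2,
      rec_s3, rec_w, rec_ev;
  NumericMatrix map_refl(passage ? pz_n : 1, passage ? px_n : 1);
  NumericMatrix map_trans(passage ? pz_n : 1, passage ? px_n : 1);
  const double cell_x = 2.0 * half_width / px_n, cell_z = depth / pz_n;

  const double si = std::sin(incident_rad), ci = std::cos(incident_rad);

  std::vector<int> visit_ix, visit_iz;
  std::vector<double> visit_w;

  for (int ph = 0; ph < n_photons; ++ph) {
    Vec3 pos = {0, 0, 0};
    Vec3 u = {si, 0, ci};              // tilted within the x-z plane
    Vec3 v = {ci, 0, -si};             // any axis perpendicular to u
    Vec3 w = cross(u, v);
    double S1 = 0, S2 = 0, S3 = 1;     // S0 kept at 1, weight separate
    double wgt = 1.0;
    int events = 0;
    if (passage) { visit_ix.clear(); visit_iz.clear(); visit_w.clear(); }
    bool alive = true;

    while (alive) {
      double step = -std::log(R::unif_rand()) / mu_t;

      // nearest boundary crossing before the collision point
      double t_hit = step;
      int hit = 0;  // 0 collision, 1 top exit, 2 bottom exit, 3 lateral
      if (u.z < 0) {
        double t = -pos.z / u.z;
        if (t < t_hit) { t_hit = t; hit = 1; }
      } else if (u.z > 0) {
        double t = (depth - pos.z) / u.z;
        if (t < t_hit) { t_hit = t; hit = 2; }
      }
      if (u.x > 0) {
        double t = (half_width - pos.x) / u.x;
        if (t < t_hit) { t_hit = t; hit = 3; }
      } else if (u.x < 0) {
        double t = (-half_width - pos.x) / u.x;
        if (t < t_hit) { t_hit = t; hit = 3; }
      }
      if (u.y > 0) {
        double t = (half_width - pos.y) / u.y;
        if (t < t_hit) { t_hit = t; hit = 3; }
      } else if (u.y < 0) {
        double t = (-half_width - pos.y) / u.y;
        if (t < t_hit) { t_hit = t; hit = 3; }
      }

      pos = pos + t_hit * u;

      if (hit == 3) { lateral_escape += wgt; break; }
      if (hit == 1 || hit == 2) {
        bool top = (hit == 1);
        double cphi = top ? -u.z : u.z;          // cos of exit angle
        if (cphi < 0) cphi = 0; else if (cphi > 1) cphi = 1;
        double phi_exit = std::acos(cphi);
        SideTally &tal = top ? refl : trans;
        double x0 = top ? refl_x0 : trans_x0, x1 = top ? refl_x1 : trans_x1;
        bool in_det = (pos.x >= x0 && pos.x <= x1 &&
                       std::fabs(pos.y) <= strip_half);
        // rotate the Stokes frame so that v lies in the meridian plane
        // through the outward surface normal (S3 is invariant, S1/S2 not)
        Vec3 nrm = {0, 0, top ? -1.0 : 1.0};
        double s1d = S1, s2d = S2;
        Vec3 proj = nrm - dot(nrm, u) * u;
        double pn = std::sqrt(dot(proj, proj));
        if (pn > 1e-12) {
          proj = (1.0 / pn) * proj;
          double cpsi = dot(v, proj), spsi = dot(w, proj);
          double c2 = cpsi * cpsi - spsi * spsi, s2r = 2.0 * cpsi * spsi;
          s1d = c2 * S1 + s2r * S2;
          s2d = -s2r * S1 + c2 * S2;
        }
        if (in_det) {
          tal.w += wgt; tal.ws3 += wgt * S3; tal.ws3sq += wgt * S3 * S3;
          tal.wev += wgt * events; tal.n += 1;
          int b = (int)(phi_exit * (180.0 / M_PI) / 10.0);
          if (b > 8) b = 8;
          tal.bin_w[b] += wgt; tal.bin_ws3[b] += wgt * S3;
          if (passage) {
            NumericMatrix &mp = top ? map_refl : map_trans;
            for (size_t k = 0; k < visit_w.size(); ++k)
              mp(visit_iz[k], visit_ix[k]) += visit_w[k];
          }
        } else {
          tal.w_outside += wgt;
        }
        if (keep_records) {
          rec_side.push_back(top ? 0.0 : 1.0);
          rec_x.push_back(pos.x); rec_y.push_back(pos.y);
          rec_phi.push_back(phi_exit);
          rec_s1.push_back(s1d); rec_s2.push_back(s2d); rec_s3.push_back(S3);
          rec_w.push_back(wgt); rec_ev.push_back((double)events);
        }
        break;
      }

      // scattering event
      ++events; total_events += 1;
      if (events > max_events) { ++n_runaway; lateral_escape += wgt; break; }
      absorbed += wgt * (mu_a / mu_t);
      wgt *= albedo;

      // sample theta from the marginal via the tabulated inverse CDF
      double uu = R::unif_rand();
      int lo = 0, hi = nt - 1;
      while (hi - lo > 1) {
        int mid = (lo + hi) >> 1;
        if (cdf[mid] < uu) lo = mid; else hi = mid;
      }
      double f = (uu - cdf[lo]) / std::max(cdf[hi] - cdf[lo], 1e-300);
      if (f < 0) f = 0; else if (f > 1) f = 1;
      double th = theta[lo] + f * (theta[hi] - theta[lo]);
      double m11 = M11[lo] + f * (M11[hi] - M11[lo]);
      double m12 = M12[lo] + f * (M12[hi] - M12[lo]);
      double m33 = M33[lo] + f * (M33[hi] - M33[lo]);
      double m34 = M34[lo] + f * (M34[hi] - M34[lo]);

      // sample phi from its conditional by rejection (envelope <= 2)
      double r = m12 / m11;
      double amp = std::sqrt(S1 * S1 + S2 * S2);
      double env = 1.0 + std::fabs(r) * amp;
      double phi, c2p, s2p;
      for (;;) {
        phi = 2.0 * M_PI * R::unif_rand();
        double cp = std::cos(phi), sp = std::sin(phi);
        c2p = cp * cp - sp * sp; s2p = 2.0 * sp * cp;
        double val = 1.0 + r * (S1 * c2p + S2 * s2p);
        if (R::unif_rand() * env <= val) break;
      }

      // rotate reference frame about u by phi, then scatter by theta
      double cp = std::cos(phi), sp = std::sin(phi);
      Vec3 v1 = cp * v + sp * w;   // new perpendicular axis is u x v1
      double s1r = c2p * S1 + s2p * S2;
      double s2r = -s2p * S1 + c2p * S2;

      double cth = std::cos(th), sth_ = std::sin(th);
      Vec3 un = cth * u + sth_ * v1;
      Vec3 vn = cth * v1 - sth_ * u;

      double S0n = m11 + m12 * s1r;
      double S1n = m12 + m11 * s1r;
      double S2n = m33 * s2r + m34 * S3;
      double S3n = -m34 * s2r + m33 * S3;
      S1 = S1n / S0n; S2 = S2n / S0n; S3 = S3n / S0n;
      double dop = S1 * S1 + S2 * S2 + S3 * S3;
      if (dop > 1.0) {               // guard against interpolation noise
        double sc = 1.0 / std::sqrt(dop);
        S1 *= sc; S2 *= sc; S3 *= sc;
      }

      u = normalize(un);
      vn = vn - dot(vn, u) * u;      // defensive re-orthonormalization
      v = normalize(vn);
      w = cross(u, v);

      if (passage) {
        int ix = (int)((pos.x + half_width) / cell_x);
        int iz = (int)(pos.z / cell_z);
        if (ix >= 0 && ix < px_n && iz >= 0 && iz < pz_n) {
          visit_ix.push_back(ix); visit_iz.push_back(iz);
          visit_w.push_back(wgt);
        }
      }

      if (wgt < weight_min) {
        if (R::unif_rand() < p_survive) {
          roulette_gain += wgt * (1.0 / p_survive - 1.0);
          wgt /= p_survive;
        } else {
          roulette_kill += wgt;
          break;
        }
      }
    }
  }

  auto side_list = [&](SideTally &t) {
    return List::create(
        _["w"] = t.w, _["ws3"] = t.ws3, _["ws3sq"] = t.ws3sq,
        _["wev"] = t.wev, _["n"] = t.n, _["w_outside"] = t.w_outside,
        _["bin_w"] = NumericVector(t.bin_w.begin(), t.bin_w.end()),
        _["bin_ws3"] = NumericVector(t.bin_ws3.begin(), t.bin_ws3.end()));
  };
  List out = List::create(
      _["reflection"] = side_list(refl),
      _["transmission"] = side_list(trans),
      _["absorbed"] = absorbed,
      _["lateral_escape"] = lateral_escape,
      _["roulette_kill"] = roulette_kill,
      _["roulette_gain"] = roulette_gain,
      _["n_runaway"] = n_runaway,
      _["total_events"] = total_events,
      _["n_photons"] = n_photons);
  if (keep_records) {
    int nr = rec_side.size();
    NumericMatrix rec(nr, 9);
    for (int i = 0; i < nr; ++i) {
      rec(i, 0) = rec_side[i]; rec(i, 1) = rec_x[i]; rec(i, 2) = rec_y[i];
      rec(i, 3) = rec_phi[i]; rec(i, 4) = rec_s1[i]; rec(i, 5) = rec_s2[i];
      rec(i, 6) = rec_s3[i]; rec(i, 7) = rec_w[i]; rec(i, 8) = rec_ev[i];
    }
    colnames(rec) = CharacterVector::create("side", "x", "y", "phi_exit",
                                            "S1", "S2", "S3", "weight",
                                            "n_events");
    out["records"] = rec;
  }
  if (passage) {
    out["map_reflection"] = map_refl;
    out["map_transmission"] = map_trans;
  }
  return out;
}
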