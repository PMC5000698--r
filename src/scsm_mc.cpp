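// Polarized-photon Monte Carlo transport through a slab of mixed
// sphere + cylinder scatterers (sphere-cylinder scattering model).
//
// Conventions:
//  * The beam enters at the origin along +z; the slab occupies
//    0 <= z <= thickness; boundaries are index-matched (no Fresnel).
//  * Each photon carries a Stokes vector in a local orthonormal frame
//    (m, n, u) with n = u x m; m is the E-parallel reference axis.
//    Rotating the frame by phi (right-handed about u, m toward n)
//    transforms (S1, S2) by the 2*phi rotation.
//  * Sphere scattering: polar angle theta sampled from the s11*sin(theta)
//    marginal (tabulated CDF), azimuth phi from the polarization-dependent
//    conditional via Newton inversion; the pair is therefore drawn from the
//    exact polarized phase function and the photon weight is unchanged
//    (albedo 1), the Stokes vector being renormalized to unit intensity.
//  * Cylinder scattering: the outgoing direction lies on the cone
//    u'.a = u.a about the per-event cylinder axis a; the cone azimuth
//    Theta is sampled from the tabulated first Mueller row contracted
//    with the incident Stokes (piecewise-constant over the table grid).
//  * Detection: photons crossing z = 0 with an upward direction are
//    binned by exit position; their Stokes is rotated into the frame
//    whose parallel axis is the lab x-axis projected perpendicular to
//    the exit direction.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void rot_stokes(double S[4], double phi) {
  double c = std::cos(2.0 * phi), s = std::sin(2.0 * phi);
  double s1 = c * S[1] + s * S[2];
  double s2 = -s * S[1] + c * S[2];
  S[1] = s1; S[2] = s2;
}

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline void norm3(double a[3]) {
  double n = std::sqrt(dot3(a, a));
  a[0] /= n; a[1] /= n; a[2] /= n;
}

// linear-interpolated inverse of a tabulated CDF on an ascending grid
static double invert_cdf(const NumericVector& grid, const NumericVector& cdf,
                         double u) {
  int n = grid.size();
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid; else hi = mid;
  }
  double c0 = cdf[lo], c1 = cdf[hi];
  double t = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.5;
  return grid[lo] + t * (grid[hi] - grid[lo]);
}

// azimuth of the polarization-dependent sphere conditional:
// pdf(phi) = (1 + k1 cos 2phi + k2 sin 2phi) / (2 pi), |k| <= 1
static double sample_sphere_phi(double k1, double k2) {
  double target = unif_rand() * 2.0 * M_PI;
  // F(phi) = phi + (k1 sin 2phi - k2 (cos 2phi - 1))/2 is monotone on
  // [0, 2pi] (F' = pdf >= 0): bracketed Newton with bisection fallback
  double lo = 0.0, hi = 2.0 * M_PI;
  double phi = target;  // unpolarized solution as starting guess
  for (int it = 0; it < 100; ++it) {
    double f = phi + 0.5 * (k1 * std::sin(2.0 * phi)
                            - k2 * (std::cos(2.0 * phi) - 1.0)) - target;
    if (std::fabs(f) < 1e-12) break;
    if (f > 0) hi = phi; else lo = phi;
    double fp = 1.0 + k1 * std::cos(2.0 * phi) + k2 * std::sin(2.0 * phi);
    double cand = (fp > 1e-8) ? phi - f / fp : lo - 1.0;
    phi = (cand > lo && cand < hi) ? cand : 0.5 * (lo + hi);
    if (hi - lo < 1e-14) break;
  }
  if (phi < 0) phi = 0;
  if (phi >= 2.0 * M_PI) phi -= 2.0 * M_PI;
  return phi;
}

// [[Rcpp::export]]
List run_scsm_mc_cpp(int n_photons, double thickness,
                     double mus_s, double mus_c,
                     double cyl_mean_rad, double cyl_std_rad, bool redraw,
                     NumericVector sph_theta, NumericMatrix sph_m,
                     NumericVector sph_cdf,
                     NumericVector cz, NumericVector ct, NumericVector cm,
                     int H, int W, double extent, double accept_cos,
                     NumericMatrix in_stokes,
                     double wmin, int max_scat) {
  const double mus_t = mus_s + mus_c;
  const int nct = ct.size(), ncz = cz.size();
  const int n_states = in_stokes.ncol();
  NumericVector accum(H * W * 4 * n_states);
  IntegerVector counts(H * W * n_states);
  IntegerVector n_detected(n_states), n_transmitted(n_states);
  std::vector<double> cw(nct), ccdf(nct), Mrow(16);

  for (int st = 0; st < n_states; ++st) {
    for (int ph = 0; ph < n_photons; ++ph) {
      double pos[3] = {0.0, 0.0, 0.0};
      double u[3] = {0.0, 0.0, 1.0};
      double m[3] = {1.0, 0.0, 0.0};
      double S[4] = {in_stokes(0, st), in_stokes(1, st),
                     in_stokes(2, st), in_stokes(3, st)};
      double w = 1.0;
      double axis_fixed_alpha = cyl_mean_rad + cyl_std_rad * norm_rand();
      int nscat = 0;
      bool alive = true;
      while (alive) {
        double L = -std::log(unif_rand()) / mus_t;
        double zc = pos[2] + L * u[2];
        if (zc < 0.0 && u[2] < 0.0) {
          // exits the top surface: detect
          double t = -pos[2] / u[2];
          double xe = pos[0] + t * u[0], ye = pos[1] + t * u[1];
          if (-u[2] >= accept_cos) {
            int ix = (int)std::floor((xe + extent / 2.0) / extent * W);
            int iy = (int)std::floor((extent / 2.0 - ye) / extent * H);
            if (ix >= 0 && ix < W && iy >= 0 && iy < H) {
              // rotate Stokes: parallel axis -> lab x projected perp to u
              double ex[3] = {1.0 - u[0] * u[0], -u[0] * u[1], -u[0] * u[2]};
              double nrm = std::sqrt(dot3(ex, ex));
              if (nrm > 1e-12) {
                ex[0] /= nrm; ex[1] /= nrm; ex[2] /= nrm;
                double nv[3];
                cross3(u, m, nv);
                double phi_d = std::atan2(dot3(ex, nv), dot3(ex, m));
                rot_stokes(S, phi_d);
              }
              // express the detected Stokes in the common lab basis seen
              // from the source side (the backscattering-imaging
              // convention): the basis reflection flips U and V
              S[2] = -S[2]; S[3] = -S[3];
              int pix = iy + H * ix;
              for (int c = 0; c < 4; ++c) {
                accum[pix + H * W * (c + 4 * st)] += w * S[c];
              }
              counts[pix + H * W * st] += 1;
              n_detected[st] += 1;
            }
          }
          break;
        }
        if (zc > thickness && u[2] > 0.0) { n_transmitted[st] += 1; break; }
        pos[0] += L * u[0]; pos[1] += L * u[1]; pos[2] += L * u[2];
        // choose species
        bool is_sphere = (unif_rand() * mus_t < mus_s);
        double nv[3];
        cross3(u, m, nv);
        if (is_sphere) {
          double th = invert_cdf(sph_theta, sph_cdf, unif_rand());
          // interpolate phase elements at th
          int nt = sph_theta.size();
          double pos_t = th / M_PI * (nt - 1);
          int i0 = (int)pos_t; if (i0 > nt - 2) i0 = nt - 2;
          double f = pos_t - i0;
          double s11 = (1 - f) * sph_m(i0, 0) + f * sph_m(i0 + 1, 0);
          double s12 = (1 - f) * sph_m(i0, 1) + f * sph_m(i0 + 1, 1);
          double s33 = (1 - f) * sph_m(i0, 2) + f * sph_m(i0 + 1, 2);
          double s34 = (1 - f) * sph_m(i0, 3) + f * sph_m(i0 + 1, 3);
          double r = (s11 > 0) ? s12 / s11 : 0.0;
          double phi = sample_sphere_phi(r * S[1] / S[0], r * S[2] / S[0]);
          rot_stokes(S, phi);
          double Sn[4];
          Sn[0] = s11 * S[0] + s12 * S[1];
          Sn[1] = s12 * S[0] + s11 * S[1];
          Sn[2] = s33 * S[2] + s34 * S[3];
          Sn[3] = -s34 * S[2] + s33 * S[3];
          if (Sn[0] <= 0) break;  // numerically degenerate; drop photon
          for (int c = 0; c < 4; ++c) S[c] = Sn[c] / Sn[0];
          // geometry update
          double e1[3] = {std::cos(phi) * m[0] + std::sin(phi) * nv[0],
                          std::cos(phi) * m[1] + std::sin(phi) * nv[1],
                          std::cos(phi) * m[2] + std::sin(phi) * nv[2]};
          double cth = std::cos(th), sth = std::sin(th);
          double un[3] = {cth * u[0] + sth * e1[0],
                          cth * u[1] + sth * e1[1],
                          cth * u[2] + sth * e1[2]};
          double mn[3] = {-sth * u[0] + cth * e1[0],
                          -sth * u[1] + cth * e1[1],
                          -sth * u[2] + cth * e1[2]};
          for (int c = 0; c < 3; ++c) { u[c] = un[c]; m[c] = mn[c]; }
          norm3(u); norm3(m);
        } else {
          // cylinder event
          double alpha = redraw ? (cyl_mean_rad + cyl_std_rad * norm_rand())
                                : axis_fixed_alpha;
          double a[3] = {std::cos(alpha), std::sin(alpha), 0.0};
          double cza = dot3(u, a);
          if (cza < 0) { a[0] = -a[0]; a[1] = -a[1]; cza = -cza; }
          double zeta = std::acos(std::min(1.0, cza));
          // clamp into the tabulated tilt range
          if (zeta < cz[0]) zeta = cz[0];
          if (zeta > cz[ncz - 1]) zeta = cz[ncz - 1];
          double s = std::sqrt(std::max(1e-12, 1.0 - cza * cza));
          double e1[3] = {u[0] - cza * a[0], u[1] - cza * a[1],
                          u[2] - cza * a[2]};
          norm3(e1);
          double e2[3];
          cross3(a, e1, e2);
          // rotate Stokes frame onto the incident parallel basis
          double pi_[3] = {(a[0] - cza * u[0]) / s, (a[1] - cza * u[1]) / s,
                           (a[2] - cza * u[2]) / s};
          double phi_c = std::atan2(dot3(pi_, nv), dot3(pi_, m));
          rot_stokes(S, phi_c);
          // zeta interpolation weights
          double pz = (zeta - cz[0]) / (cz[ncz - 1] - cz[0]) * (ncz - 1);
          int iz0 = (int)pz; if (iz0 > ncz - 2) iz0 = ncz - 2;
          double fz = pz - iz0;
          // build the sampling weights over the Theta grid
          double tot = 0.0;
          for (int it = 0; it < nct; ++it) {
            double val = 0.0;
            for (int e = 0; e < 4; ++e) {
              // cm is the column-major flattening of the R array
              // [n_zeta, n_theta, 16]: index iz + ncz*(it + nct*e)
              double v = (1 - fz) * cm[iz0 + ncz * (it + nct * e)]
                       + fz * cm[(iz0 + 1) + ncz * (it + nct * e)];
              val += v * S[e];
            }
            if (val < 0) val = 0;
            cw[it] = val;
            tot += val;
            ccdf[it] = tot;
          }
          if (tot <= 0) break;
          double ur = unif_rand() * tot;
          int isel = 0, lo = 0, hi = nct - 1;
          while (hi - lo > 1) {
            int mid = (lo + hi) / 2;
            if (ccdf[mid] < ur) lo = mid; else hi = mid;
          }
          isel = (ccdf[lo] >= ur) ? lo : hi;
          double Theta = ct[isel];
          for (int e = 0; e < 16; ++e) {
            Mrow[e] = (1 - fz) * cm[iz0 + ncz * (isel + nct * e)]
                    + fz * cm[(iz0 + 1) + ncz * (isel + nct * e)];
          }
          double Sn[4] = {0, 0, 0, 0};
          for (int i = 0; i < 4; ++i) {
            for (int j = 0; j < 4; ++j) Sn[i] += Mrow[i * 4 + j] * S[j];
          }
          if (Sn[0] <= 0) break;
          for (int c = 0; c < 4; ++c) S[c] = Sn[c] / Sn[0];
          // new direction on the scattering cone
          double cT = std::cos(Theta), sT = std::sin(Theta);
          double un[3] = {cza * a[0] + s * (cT * e1[0] + sT * e2[0]),
                          cza * a[1] + s * (cT * e1[1] + sT * e2[1]),
                          cza * a[2] + s * (cT * e1[2] + sT * e2[2])};
          norm3(un);
          // scattered parallel basis
          double mn[3] = {(a[0] - cza * un[0]) / s, (a[1] - cza * un[1]) / s,
                          (a[2] - cza * un[2]) / s};
          norm3(mn);
          for (int c = 0; c < 3; ++c) { u[c] = un[c]; m[c] = mn[c]; }
        }
        // keep the frame orthonormal against drift
        double corr = dot3(m, u);
        for (int c = 0; c < 3; ++c) m[c] -= corr * u[c];
        norm3(m);
        if (++nscat >= max_scat) break;
        if (w < wmin) {
          if (unif_rand() < 0.1) w /= 0.1; else break;
        }
      }
    }
  }
  return List::create(_["accum"] = accum, _["counts"] = counts,
                      _["n_detected"] = n_detected,
                      _["n_transmitted"] = n_transmitted);
}
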