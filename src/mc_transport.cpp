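#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 2D photon-packet transport, x transverse / z axial, cell pitch in um.
// Side walls at x = +-xmax carry a refractive-index step to n_out
// (Fresnel reflection, total internal reflection beyond the critical
// angle); n_out <= 0 disables the walls (open boundary). Entrance and
// exit planes are index-matched (open).
// Contiguous identical columns form segments:
//   UNIFORM: no index gradient, uniform mus  -> analytic straight flight
//   GRADED : x-only index gradient, uniform mus -> tight substep loop
//   GENERAL: anything else -> per-cell substeps

static inline double hg_cos(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  return c > 1.0 ? 1.0 : (c < -1.0 ? -1.0 : c);
}

// unpolarised Fresnel reflectance, incidence cosine ci in medium n1 -> n2
static inline double fresnel_R(double n1, double n2, double ci) {
  double st2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

struct Segment {
  int j0, j1;
  int type;                  // 0 uniform, 1 graded, 2 general
  double mus;
  std::vector<double> kick;
};

// [[Rcpp::export]]
List mc_transport_cpp(NumericMatrix n_field, NumericMatrix dndx_field,
                      NumericMatrix mus_field, double mua, double g,
                      double cell, double src_len, double div_sigma,
                      int n_photons, bool tally_fluence, double n_out) {
  const int nx = n_field.nrow(), nz = n_field.ncol();
  const double xmin = -0.5 * nx * cell, xmax = 0.5 * nx * cell;
  const double zmax = nz * cell, max_path = 10.0 * zmax;
  const double invcell = 1.0 / cell;
  const bool walls = n_out > 0.0;
  const double *nf = REAL(n_field), *gf = REAL(dndx_field), *mf = REAL(mus_field);

  std::vector<int> colsig(nz);
  std::vector<double> colmus(nz);
  for (int j = 0; j < nz; ++j) {
    const double *mj = mf + (size_t)j * nx, *gj = gf + (size_t)j * nx;
    bool mus_uni = true, grad0 = true;
    for (int i = 1; i < nx; ++i) if (mj[i] != mj[0]) { mus_uni = false; break; }
    for (int i = 0; i < nx; ++i) if (gj[i] != 0.0) { grad0 = false; break; }
    colmus[j] = mj[0];
    colsig[j] = mus_uni ? (grad0 ? 0 : 1) : 2;
  }
  auto same_col = [&](int a, int b) {
    const double *na = nf + (size_t)a * nx, *nb = nf + (size_t)b * nx;
    const double *ga = gf + (size_t)a * nx, *gb = gf + (size_t)b * nx;
    for (int i = 0; i < nx; ++i)
      if (na[i] != nb[i] || ga[i] != gb[i]) return false;
    return true;
  };
  std::vector<Segment> segs;
  std::vector<int> segof(nz);
  for (int j = 0; j < nz;) {
    Segment s; s.j0 = j; s.type = colsig[j]; s.mus = colmus[j];
    int j2 = j + 1;
    while (j2 < nz && colsig[j2] == s.type &&
           (s.type == 2 || colmus[j2] == s.mus) &&
           (s.type == 0 || same_col(j, j2))) ++j2;
    s.j1 = j2;
    if (s.type == 1) {
      s.kick.resize(nx);
      const double *nj = nf + (size_t)j * nx, *gj = gf + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) s.kick[i] = cell / nj[i] * gj[i];
    }
    for (int t = j; t < j2; ++t) segof[t] = (int)segs.size();
    segs.push_back(std::move(s));
    j = j2;
  }

  NumericMatrix fluence(tally_fluence ? nx : 1, tally_fluence ? nz : 1);
  double *fl = REAL(fluence);
  NumericVector exit_profile(nx), exit_ballistic(nx);
  double w_exit_forward = 0, w_exit_side = 0, w_exit_back = 0, w_killed = 0,
         w_absorbed = 0;
  int n_exit_forward = 0, n_ballistic = 0;

  for (int p = 0; p < n_photons; ++p) {
    double x = (unif_rand() - 0.5) * src_len;
    double th = norm_rand() * div_sigma;
    double ux = std::sin(th), uz = std::cos(th);
    double z = 1e-9, w = 1.0, path = 0.0;
    int nscat = 0;
    double depth = -std::log(unif_rand());
    int fate = -1;  // 0 fwd, 1 side, 2 back, 3 killed

    while (true) {
      if (path > max_path) { fate = 3; break; }
      if (z >= zmax) { fate = 0; break; }
      if (z < 0) { fate = 2; break; }
      if (x <= xmin || x >= xmax) {
        if (walls) {
          int izc = (int)(z * invcell); if (izc >= nz) izc = nz - 1;
          double n_here = nf[(size_t)izc * nx + (x > 0 ? nx - 1 : 0)];
          double R = fresnel_R(n_here, n_out, std::fabs(ux));
          if (unif_rand() < R) {
            ux = -ux;
            x = x > 0 ? xmax - 1e-9 : xmin + 1e-9;
            continue;
          }
        }
        fate = 1; break;
      }
      int iz = (int)(z * invcell);
      if (iz >= nz) iz = nz - 1;
      const Segment &S = segs[segof[iz]];
      bool scatter_now = false;

      if (S.type == 0 && uz != 0.0) {
        double zstop = uz > 0 ? S.j1 * cell : S.j0 * cell;
        double s_seg = (zstop - z) / uz + 1e-9;
        double s_x = ux > 0 ? (xmax - x) / ux : (ux < 0 ? (xmin - x) / ux : 1e30);
        double s_scat = S.mus > 0 ? depth / S.mus : 1e30;
        double s = s_seg < s_x ? s_seg : s_x;
        if (s_scat < s) { s = s_scat; scatter_now = true; }
        if (tally_fluence) {
          double zc = z, xc = x, left = s;
          while (left > 0) {
            int jz = (int)(zc * invcell);
            if (jz >= nz) jz = nz - 1; if (jz < 0) jz = 0;
            int jx = (int)((xc - xmin) * invcell);
            double zedge = uz > 0 ? (jz + 1) * cell : jz * cell;
            double dsz = (zedge - zc) / uz + 1e-9;
            double ds = dsz < left ? dsz : left;
            if (jx >= 0 && jx < nx) fl[(size_t)jz * nx + jx] += w * ds;
            zc += ds * uz; xc += ds * ux; left -= ds;
          }
        }
        x += s * ux; z += s * uz; path += s;
        if (!scatter_now) depth -= s * S.mus;
        if (mua > 0) { double a = std::exp(-mua * s); w_absorbed += w * (1 - a); w *= a; }
      } else if (S.type == 1) {
        const double zlo = S.j0 * cell, zhi = S.j1 * cell;
        const double mus = S.mus;
        const double *kick = S.kick.data();
        double seg_path = 0.0;
        while (true) {
          int ix = (int)((x - xmin) * invcell);
          if (ix < 0 || ix >= nx) break;
          ux += kick[ix];
          double q = ux * ux + uz * uz;
          double inv = 1.5 - 0.5 * q;  // Newton 1/sqrt, |q-1| ~ 1e-6
          ux *= inv; uz *= inv;
          x += cell * ux; z += cell * uz; seg_path += cell;
          depth -= mus * cell;
          if (tally_fluence) {
            int jz = (int)(z * invcell), jx = (int)((x - xmin) * invcell);
            if (jz >= 0 && jz < nz && jx >= 0 && jx < nx)
              fl[(size_t)jz * nx + jx] += w * cell;
          }
          if (depth <= 0) { scatter_now = true; break; }
          if (z >= zhi || z < zlo || x <= xmin || x >= xmax ||
              path + seg_path > max_path) break;
        }
        path += seg_path;
        if (mua > 0) { double a = std::exp(-mua * seg_path); w_absorbed += w * (1 - a); w *= a; }
      } else {
        int ix = (int)((x - xmin) * invcell);
        size_t id = (size_t)iz * nx + ix;
        ux += cell / nf[id] * gf[id];
        double inv = 1.0 / std::sqrt(ux * ux + uz * uz);
        ux *= inv; uz *= inv;
        x += cell * ux; z += cell * uz; path += cell;
        depth -= mf[id] * cell;
        if (tally_fluence) fl[id] += w * cell;
        if (mua > 0) { double a = std::exp(-mua * cell); w_absorbed += w * (1 - a); w *= a; }
        if (depth <= 0) scatter_now = true;
      }

      if (scatter_now) {
        double c = hg_cos(g);
        double dth = std::acos(c) * (unif_rand() < 0.5 ? 1.0 : -1.0);
        double cs = std::cos(dth), sn = std::sin(dth);
        double nux = ux * cs - uz * sn, nuz = ux * sn + uz * cs;
        ux = nux; uz = nuz; ++nscat;
        depth = -std::log(unif_rand());
      }
    }

    if (fate == 0) {
      double xex = uz > 0 ? x - (z - zmax) / uz * ux : x;
      int ib = (int)((xex - xmin) * invcell);
      if (ib >= 0 && ib < nx) {
        exit_profile[ib] += w;
        if (nscat == 0) exit_ballistic[ib] += w;
      }
      w_exit_forward += w; ++n_exit_forward;
      if (nscat == 0) ++n_ballistic;
    } else if (fate == 1) w_exit_side += w;
    else if (fate == 2) w_exit_back += w;
    else w_killed += w;
  }

  return List::create(
    _["exit_profile"] = exit_profile, _["exit_ballistic"] = exit_ballistic,
    _["fluence"] = fluence, _["n_launched"] = n_photons,
    _["n_exit_forward"] = n_exit_forward, _["n_ballistic"] = n_ballistic,
    _["w_exit_forward"] = w_exit_forward, _["w_exit_side"] = w_exit_side,
    _["w_exit_back"] = w_exit_back, _["w_killed"] = w_killed,
    _["w_absorbed"] = w_absorbed);
}
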