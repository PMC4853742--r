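// Grid kernels for union-of-spheres geometry and the Monte Carlo
// free-area loop. All lengths in Angstrom. Grids are deterministic,
// origin-centered lattices with cell centers at (k + 0.5) * step.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3-D shell volumes: bin grid-cell centers by signed distance to the
// union-of-spheres surface, d(p) = min_i(|p - c_i| - vdw_i). Cells with
// d < 0 are inside the molecule and never counted.
// [[Rcpp::export]]
NumericVector cpp_shell_volumes(NumericMatrix coords, NumericVector vdw,
                                NumericVector breaks, double step) {
  const int na = coords.nrow();
  const int nb = breaks.size() - 1;
  NumericVector vol(nb);
  if (na == 0) return vol;
  const double rmax = breaks[nb];
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < na; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], coords(i, d) - vdw[i] - rmax);
      hi[d] = std::max(hi[d], coords(i, d) + vdw[i] + rmax);
    }
  long k0[3], k1[3];
  for (int d = 0; d < 3; ++d) {
    k0[d] = (long)std::floor(lo[d] / step);
    k1[d] = (long)std::ceil(hi[d] / step);
  }
  std::vector<long> counts(nb, 0);
  const double* br = breaks.begin();
  for (long kx = k0[0]; kx < k1[0]; ++kx) {
    const double x = (kx + 0.5) * step;
    for (long ky = k0[1]; ky < k1[1]; ++ky) {
      const double y = (ky + 0.5) * step;
      for (long kz = k0[2]; kz < k1[2]; ++kz) {
        const double z = (kz + 0.5) * step;
        double dmin = R_PosInf;
        for (int i = 0; i < na; ++i) {
          const double dx = x - coords(i, 0), dy = y - coords(i, 1),
                       dz = z - coords(i, 2);
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[i];
          if (d < dmin) dmin = d;
        }
        if (dmin < br[0] || dmin >= br[nb]) continue;
        int b = (int)(std::upper_bound(br, br + nb + 1, dmin) - br) - 1;
        if (b >= 0 && b < nb) counts[b]++;
      }
    }
  }
  const double cv = step * step * step;
  for (int b = 0; b < nb; ++b) vol[b] = counts[b] * cv;
  return vol;
}

// ---------------------------------------------------------------------------
// Areas in the y = 0 plane of bands of surface distance, binned by breaks.
// Distance at plane point (x, z) is min_i(|(x,0,z) - c_i| - vdw_i).
// [[Rcpp::export]]
NumericVector cpp_plane_band_areas(NumericMatrix coords, NumericVector vdw,
                                   NumericVector breaks, double step) {
  const int na = coords.nrow();
  const int nb = breaks.size() - 1;
  NumericVector area(nb);
  if (na == 0) return area;
  const double rmax = breaks[nb];
  double hx = 0, hz = 0;
  for (int i = 0; i < na; ++i) {
    hx = std::max(hx, std::fabs(coords(i, 0)) + vdw[i] + rmax);
    hz = std::max(hz, std::fabs(coords(i, 2)) + vdw[i] + rmax);
  }
  const long mx = (long)std::ceil(hx / step), mz = (long)std::ceil(hz / step);
  std::vector<long> counts(nb, 0);
  const double* br = breaks.begin();
  for (long kx = -mx; kx < mx; ++kx) {
    const double x = (kx + 0.5) * step;
    for (long kz = -mz; kz < mz; ++kz) {
      const double z = (kz + 0.5) * step;
      double dmin = R_PosInf;
      for (int i = 0; i < na; ++i) {
        const double dx = x - coords(i, 0), dy = coords(i, 1),
                     dz = z - coords(i, 2);
        const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[i];
        if (d < dmin) dmin = d;
      }
      if (dmin < br[0] || dmin >= br[nb]) continue;
      int b = (int)(std::upper_bound(br, br + nb + 1, dmin) - br) - 1;
      if (b >= 0 && b < nb) counts[b]++;
    }
  }
  const double ca = step * step;
  for (int b = 0; b < nb; ++b) area[b] = counts[b] * ca;
  return area;
}

// ---------------------------------------------------------------------------
// Free area of the clipped y = 0 disk outside a set of circles.
// Row/interval counting: exact in grid-cell units, no per-cell loop.

struct PlaneWindow {
  long m;            // half grid size in cells
  double step;
  double area_cell;
  std::vector<long> ilo, ihi;  // per-row disk column range (ilo > ihi: empty)
  std::vector<long> cum;       // prefix sums of per-row cell counts
};

static PlaneWindow make_window(double disk_radius, double step) {
  PlaneWindow w;
  w.m = (long)std::ceil(disk_radius / step);
  w.step = step;
  w.area_cell = step * step;
  const long n = 2 * w.m;
  w.ilo.assign(n, 1);
  w.ihi.assign(n, 0);
  w.cum.assign(n + 1, 0);
  const double d2 = disk_radius * disk_radius;
  for (long j = 0; j < n; ++j) {
    long cnt = 0;
    const double z = (j + 0.5 - w.m) * step;
    if (z * z <= d2) {
      const double wx = std::sqrt(d2 - z * z);
      long ilo = (long)std::ceil(w.m - 0.5 - wx / step);
      long ihi = (long)std::floor(w.m - 0.5 + wx / step);
      if (ilo < 0) ilo = 0;
      if (ihi > n - 1) ihi = n - 1;
      if (ihi >= ilo) {
        w.ilo[j] = ilo;
        w.ihi[j] = ihi;
        cnt = ihi - ilo + 1;
      }
    }
    w.cum[j + 1] = w.cum[j] + cnt;
  }
  return w;
}

// rows whose centers satisfy |z| <= z_window
static void window_rows(const PlaneWindow& w, double z_window, long* jlo,
                        long* jhi) {
  const long n = 2 * w.m;
  if (!R_FINITE(z_window)) {
    *jlo = 0;
    *jhi = n - 1;
    return;
  }
  *jlo = (long)std::ceil(w.m - 0.5 - z_window / w.step);
  *jhi = (long)std::floor(w.m - 0.5 + z_window / w.step);
  if (*jlo < 0) *jlo = 0;
  if (*jhi > n - 1) *jhi = n - 1;
}

// circles: center (cx, cz), squared radius r2 (> 0); only rows in
// [row_lo, row_hi] are counted
static long covered_cells(const PlaneWindow& w, long row_lo, long row_hi,
                          const std::vector<double>& cx,
                          const std::vector<double>& cz,
                          const std::vector<double>& r2) {
  const size_t nc = cx.size();
  if (nc == 0 || row_hi < row_lo) return 0;
  double zmin = R_PosInf, zmax = R_NegInf;
  for (size_t k = 0; k < nc; ++k) {
    const double r = std::sqrt(r2[k]);
    zmin = std::min(zmin, cz[k] - r);
    zmax = std::max(zmax, cz[k] + r);
  }
  long j0 = (long)std::floor(zmin / w.step - 0.5 + w.m);
  long j1 = (long)std::ceil(zmax / w.step - 0.5 + w.m);
  if (j0 < row_lo) j0 = row_lo;
  if (j1 > row_hi) j1 = row_hi;
  long covered = 0;
  std::vector<std::pair<long, long> > iv;
  for (long j = j0; j <= j1; ++j) {
    if (w.ilo[j] > w.ihi[j]) continue;
    const double z = (j + 0.5 - w.m) * w.step;
    iv.clear();
    for (size_t k = 0; k < nc; ++k) {
      const double dz = z - cz[k];
      const double h2 = r2[k] - dz * dz;
      if (h2 <= 0) continue;
      const double h = std::sqrt(h2);
      long a = (long)std::ceil((cx[k] - h) / w.step - 0.5 + w.m);
      long b = (long)std::floor((cx[k] + h) / w.step - 0.5 + w.m);
      if (a < w.ilo[j]) a = w.ilo[j];
      if (b > w.ihi[j]) b = w.ihi[j];
      if (b >= a) iv.push_back(std::make_pair(a, b));
    }
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    long cur_a = iv[0].first, cur_b = iv[0].second;
    for (size_t k = 1; k < iv.size(); ++k) {
      if (iv[k].first > cur_b + 1) {
        covered += cur_b - cur_a + 1;
        cur_a = iv[k].first;
        cur_b = iv[k].second;
      } else if (iv[k].second > cur_b) {
        cur_b = iv[k].second;
      }
    }
    covered += cur_b - cur_a + 1;
  }
  return covered;
}

// Free area of the z-clipped disk outside all inflated-sphere slices, for a
// single (already conformed) structure.
// [[Rcpp::export]]
double cpp_plane_free_area(NumericMatrix coords, NumericVector vdw,
                           double inflate, double disk_radius, double z_window,
                           double step) {
  PlaneWindow w = make_window(disk_radius, step);
  long jlo, jhi;
  window_rows(w, z_window, &jlo, &jhi);
  const long total = (jhi >= jlo) ? w.cum[jhi + 1] - w.cum[jlo] : 0;
  std::vector<double> cx, cz, r2;
  for (int i = 0; i < coords.nrow(); ++i) {
    const double R = vdw[i] + inflate;
    const double y = coords(i, 1);
    const double h2 = R * R - y * y;
    if (h2 > 0) {
      cx.push_back(coords(i, 0));
      cz.push_back(coords(i, 2));
      r2.push_back(h2);
    }
  }
  return (total - covered_cells(w, jlo, jhi, cx, cz, r2)) * w.area_cell;
}

// ---------------------------------------------------------------------------
// Monte Carlo batch: for each draw, apply dihedral deltas and azimuth to the
// template coordinates, then measure free plane areas for both ion species.
// part: 0 = rigid core, 1 = phi side (rotates about N-CA), 2 = psi side
// (rotates about CA-C). Angles in degrees; deltas are (phi - 180, psi - 180).

static inline void rodrigues(double* p, const double* o, const double* u,
                             double ca, double sa) {
  double v0 = p[0] - o[0], v1 = p[1] - o[1], v2 = p[2] - o[2];
  const double dot = u[0] * v0 + u[1] * v1 + u[2] * v2;
  const double c0 = u[1] * v2 - u[2] * v1;
  const double c1 = u[2] * v0 - u[0] * v2;
  const double c2 = u[0] * v1 - u[1] * v0;
  p[0] = o[0] + v0 * ca + c0 * sa + u[0] * dot * (1 - ca);
  p[1] = o[1] + v1 * ca + c1 * sa + u[1] * dot * (1 - ca);
  p[2] = o[2] + v2 * ca + c2 * sa + u[2] * dot * (1 - ca);
}

// The z window is re-derived for every draw from the conformed structure:
// |z| <= (terminal z extent of the `terminal`-flagged atoms) + z_margin,
// so each draw matches a direct free-area measurement of that conformation.
// [[Rcpp::export]]
NumericMatrix cpp_sample_areas(NumericMatrix coords, NumericVector vdw,
                               IntegerVector part, IntegerVector terminal,
                               NumericVector pN, NumericVector pCA,
                               NumericVector pC, NumericVector phi,
                               NumericVector psi, NumericVector azim,
                               double reff_a, double reff_b,
                               double disk_radius, double z_margin,
                               double step) {
  const int na = coords.nrow();
  const int n = phi.size();
  NumericMatrix out(n, 2);
  PlaneWindow w = make_window(disk_radius, step);
  if (na == 0) {
    long jlo, jhi;
    window_rows(w, R_FINITE(z_margin) ? z_margin : R_PosInf, &jlo, &jhi);
    const double full =
        ((jhi >= jlo) ? w.cum[jhi + 1] - w.cum[jlo] : 0) * w.area_cell;
    std::fill(out.begin(), out.end(), full);
    return out;
  }
  double uphi[3] = {0, 0, 1}, upsi[3] = {0, 0, 1};
  double oN[3] = {0, 0, 0}, oCA[3] = {0, 0, 0};
  bool have_bb = pN.size() == 3 && pCA.size() == 3 && pC.size() == 3;
  if (have_bb) {
    double nrm = 0;
    for (int d = 0; d < 3; ++d) {
      oN[d] = pN[d];
      oCA[d] = pCA[d];
      uphi[d] = pCA[d] - pN[d];
      nrm += uphi[d] * uphi[d];
    }
    nrm = std::sqrt(nrm);
    for (int d = 0; d < 3; ++d) uphi[d] /= nrm;
    nrm = 0;
    for (int d = 0; d < 3; ++d) {
      upsi[d] = pC[d] - pCA[d];
      nrm += upsi[d] * upsi[d];
    }
    nrm = std::sqrt(nrm);
    for (int d = 0; d < 3; ++d) upsi[d] /= nrm;
  }
  const double deg = M_PI / 180.0;
  std::vector<double> px(na), py(na), pz(na);
  std::vector<double> cx, cz, r2;
  cx.reserve(na); cz.reserve(na); r2.reserve(na);
  const double reff[2] = {reff_a, reff_b};
  for (int s = 0; s < n; ++s) {
    const double aphi = (phi[s] - 180.0) * deg;
    const double apsi = (psi[s] - 180.0) * deg;
    const double az = azim[s] * deg;
    const double cphi = std::cos(aphi), sphi = std::sin(aphi);
    const double cpsi = std::cos(apsi), spsi = std::sin(apsi);
    const double caz = std::cos(az), saz = std::sin(az);
    for (int i = 0; i < na; ++i) {
      double p[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
      if (have_bb) {
        if (part[i] == 1)
          rodrigues(p, oN, uphi, cphi, sphi);
        else if (part[i] == 2)
          rodrigues(p, oCA, upsi, cpsi, spsi);
      }
      px[i] = p[0] * caz - p[1] * saz;
      py[i] = p[0] * saz + p[1] * caz;
      pz[i] = p[2];
    }
    long jlo = 0, jhi = 2 * w.m - 1;
    if (R_FINITE(z_margin)) {
      double ext = 0;
      for (int i = 0; i < na; ++i) {
        if (terminal[i] && std::fabs(pz[i]) + vdw[i] > ext) {
          ext = std::fabs(pz[i]) + vdw[i];
        }
      }
      window_rows(w, ext + z_margin, &jlo, &jhi);
    }
    const long total = (jhi >= jlo) ? w.cum[jhi + 1] - w.cum[jlo] : 0;
    for (int sp = 0; sp < 2; ++sp) {
      cx.clear(); cz.clear(); r2.clear();
      for (int i = 0; i < na; ++i) {
        const double R = vdw[i] + reff[sp];
        const double h2 = R * R - py[i] * py[i];
        if (h2 > 0) {
          cx.push_back(px[i]);
          cz.push_back(pz[i]);
          r2.push_back(h2);
        }
      }
      out(s, sp) = (total - covered_cells(w, jlo, jhi, cx, cz, r2)) *
                   w.area_cell;
    }
  }
  return out;
}
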