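// Analytic evaluation of Gaussian-basis electron densities (value, gradient,
// Hessian) via a natural-orbital expansion, plus the near-grid steepest
// ascent used for Bader basin assignment.  Hot paths only; all bookkeeping
// stays in R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct BasisFlat {
  // per-AO monomial and primitive tables, flattened with offsets
  IntegerVector nmono, nprim;
  IntegerMatrix pows;      // total_mono x 3
  NumericVector mcoef;     // total_mono
  NumericVector pexp, pcoef;  // total_prim
  NumericMatrix center;    // nao x 3
  std::vector<int> moff, poff;
  std::vector<double> minexp;
  int nao;

  explicit BasisFlat(const List& b)
      : nmono(as<IntegerVector>(b["nmono"])),
        nprim(as<IntegerVector>(b["nprim"])),
        pows(as<IntegerMatrix>(b["pows"])),
        mcoef(as<NumericVector>(b["mcoef"])),
        pexp(as<NumericVector>(b["pexp"])),
        pcoef(as<NumericVector>(b["pcoef"])),
        center(as<NumericMatrix>(b["center"])) {
    nao = nmono.size();
    moff.resize(nao + 1, 0);
    poff.resize(nao + 1, 0);
    for (int a = 0; a < nao; ++a) {
      moff[a + 1] = moff[a] + nmono[a];
      poff[a + 1] = poff[a] + nprim[a];
    }
    minexp.resize(nao);
    for (int a = 0; a < nao; ++a) {
      double m = R_PosInf;
      for (int p = poff[a]; p < poff[a + 1]; ++p)
        if (pexp[p] < m) m = pexp[p];
      minexp[a] = m;
    }
  }
};

inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// Evaluate one AO and (optionally) its first/second derivatives at (x,y,z)
// relative to the AO center.  out[0]=phi, out[1..3]=d/dx,y,z,
// out[4..9]=xx,yy,zz,xy,xz,yz.
inline void eval_ao(const BasisFlat& B, int a, double dx, double dy, double dz,
                    double r2, int order, double* out) {
  double S = 0.0, S1 = 0.0, S2 = 0.0;
  for (int p = B.poff[a]; p < B.poff[a + 1]; ++p) {
    double e = B.pcoef[p] * std::exp(-B.pexp[p] * r2);
    S += e;
    if (order > 0) S1 += -B.pexp[p] * e;
    if (order > 1) S2 += B.pexp[p] * B.pexp[p] * e;
  }
  double P = 0, Px = 0, Py = 0, Pz = 0;
  double Pxx = 0, Pyy = 0, Pzz = 0, Pxy = 0, Pxz = 0, Pyz = 0;
  for (int m = B.moff[a]; m < B.moff[a + 1]; ++m) {
    int i = B.pows(m, 0), j = B.pows(m, 1), k = B.pows(m, 2);
    double c = B.mcoef[m];
    double xi = ipow(dx, i), yj = ipow(dy, j), zk = ipow(dz, k);
    P += c * xi * yj * zk;
    if (order > 0) {
      double xi1 = i > 0 ? ipow(dx, i - 1) : 0.0;
      double yj1 = j > 0 ? ipow(dy, j - 1) : 0.0;
      double zk1 = k > 0 ? ipow(dz, k - 1) : 0.0;
      Px += c * i * xi1 * yj * zk;
      Py += c * j * xi * yj1 * zk;
      Pz += c * k * xi * yj * zk1;
      if (order > 1) {
        double xi2 = i > 1 ? ipow(dx, i - 2) : 0.0;
        double yj2 = j > 1 ? ipow(dy, j - 2) : 0.0;
        double zk2 = k > 1 ? ipow(dz, k - 2) : 0.0;
        Pxx += c * i * (i - 1) * xi2 * yj * zk;
        Pyy += c * j * (j - 1) * xi * yj2 * zk;
        Pzz += c * k * (k - 1) * xi * yj * zk2;
        Pxy += c * i * j * xi1 * yj1 * zk;
        Pxz += c * i * k * xi1 * yj * zk1;
        Pyz += c * j * k * xi * yj1 * zk1;
      }
    }
  }
  out[0] = P * S;
  if (order > 0) {
    out[1] = Px * S + 2.0 * dx * P * S1;
    out[2] = Py * S + 2.0 * dy * P * S1;
    out[3] = Pz * S + 2.0 * dz * P * S1;
    if (order > 1) {
      out[4] = Pxx * S + 4.0 * dx * Px * S1 + P * (4.0 * dx * dx * S2 + 2.0 * S1);
      out[5] = Pyy * S + 4.0 * dy * Py * S1 + P * (4.0 * dy * dy * S2 + 2.0 * S1);
      out[6] = Pzz * S + 4.0 * dz * Pz * S1 + P * (4.0 * dz * dz * S2 + 2.0 * S1);
      out[7] = Pxy * S + 2.0 * (dy * Px + dx * Py) * S1 + 4.0 * dx * dy * P * S2;
      out[8] = Pxz * S + 2.0 * (dz * Px + dx * Pz) * S1 + 4.0 * dx * dz * P * S2;
      out[9] = Pyz * S + 2.0 * (dz * Py + dy * Pz) * S1 + 4.0 * dy * dz * P * S2;
    }
  }
}

const double SCREEN_LOG = 60.0;  // exp(-60) ~ 9e-27, far below any tolerance

}  // namespace

// [[Rcpp::export]]
List cpp_eval_density(NumericMatrix points, List basis, NumericMatrix cno,
                      NumericVector occ, int order) {
  BasisFlat B(basis);
  const int npt = points.nrow(), nno = cno.nrow(), nao = B.nao;
  NumericVector rho(npt);
  NumericMatrix grad(order > 0 ? npt : 0, 3);
  NumericMatrix hess(order > 1 ? npt : 0, 9);  // row-major 3x3 by columns xx..zz
  std::vector<double> aoval(nao * 10, 0.0);
  std::vector<double> psi(nno), dpsi(3 * nno), hpsi(6 * nno);
  for (int ip = 0; ip < npt; ++ip) {
    const double x = points(ip, 0), y = points(ip, 1), z = points(ip, 2);
    std::fill(psi.begin(), psi.end(), 0.0);
    std::fill(dpsi.begin(), dpsi.end(), 0.0);
    std::fill(hpsi.begin(), hpsi.end(), 0.0);
    for (int a = 0; a < nao; ++a) {
      const double dx = x - B.center(a, 0), dy = y - B.center(a, 1),
                   dz = z - B.center(a, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      double* out = &aoval[a * 10];
      if (B.minexp[a] * r2 > SCREEN_LOG) {
        for (int q = 0; q < 10; ++q) out[q] = 0.0;
        continue;
      }
      eval_ao(B, a, dx, dy, dz, r2, order, out);
    }
    for (int k = 0; k < nno; ++k) {
      double v = 0;
      for (int a = 0; a < nao; ++a) v += cno(k, a) * aoval[a * 10];
      psi[k] = v;
      if (order > 0) {
        for (int d = 0; d < 3; ++d) {
          double g = 0;
          for (int a = 0; a < nao; ++a) g += cno(k, a) * aoval[a * 10 + 1 + d];
          dpsi[3 * k + d] = g;
        }
        if (order > 1) {
          for (int d = 0; d < 6; ++d) {
            double h = 0;
            for (int a = 0; a < nao; ++a) h += cno(k, a) * aoval[a * 10 + 4 + d];
            hpsi[6 * k + d] = h;
          }
        }
      }
    }
    double r = 0;
    for (int k = 0; k < nno; ++k) r += occ[k] * psi[k] * psi[k];
    rho[ip] = r;
    if (order > 0) {
      double g[3] = {0, 0, 0};
      for (int k = 0; k < nno; ++k)
        for (int d = 0; d < 3; ++d)
          g[d] += 2.0 * occ[k] * psi[k] * dpsi[3 * k + d];
      for (int d = 0; d < 3; ++d) grad(ip, d) = g[d];
      if (order > 1) {
        // H_ab = sum_k 2 n_k (dpsi_a dpsi_b + psi * hpsi_ab)
        double H[9] = {0};
        for (int k = 0; k < nno; ++k) {
          const double n2 = 2.0 * occ[k];
          const double* dk = &dpsi[3 * k];
          const double* hk = &hpsi[6 * k];
          const double pk = psi[k];
          H[0] += n2 * (dk[0] * dk[0] + pk * hk[0]);
          H[4] += n2 * (dk[1] * dk[1] + pk * hk[1]);
          H[8] += n2 * (dk[2] * dk[2] + pk * hk[2]);
          H[1] += n2 * (dk[0] * dk[1] + pk * hk[3]);
          H[2] += n2 * (dk[0] * dk[2] + pk * hk[4]);
          H[5] += n2 * (dk[1] * dk[2] + pk * hk[5]);
        }
        H[3] = H[1]; H[6] = H[2]; H[7] = H[5];
        for (int q = 0; q < 9; ++q) hess(ip, q) = H[q];
      }
    }
  }
  List res = List::create(_["rho"] = rho);
  if (order > 0) res["grad"] = grad;
  if (order > 1) res["hess"] = hess;
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_eval_density_grid(NumericVector origin, NumericMatrix axes,
                                    IntegerVector shape, List basis,
                                    NumericMatrix cno, NumericVector occ) {
  BasisFlat B(basis);
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const int nno = cno.nrow(), nao = B.nao;
  NumericVector rho((R_xlen_t)nx * ny * nz);
  std::vector<double> aoval(nao), psi(nno);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        // x-fastest linear order matches R array dim c(nx,ny,nz)
        const double x = origin[0] + i * axes(0, 0) + j * axes(1, 0) + k * axes(2, 0);
        const double y = origin[1] + i * axes(0, 1) + j * axes(1, 1) + k * axes(2, 1);
        const double z = origin[2] + i * axes(0, 2) + j * axes(1, 2) + k * axes(2, 2);
        idx = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int a = 0; a < nao; ++a) {
          const double dx = x - B.center(a, 0), dy = y - B.center(a, 1),
                       dz = z - B.center(a, 2);
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (B.minexp[a] * r2 > SCREEN_LOG) { aoval[a] = 0.0; continue; }
          double out[10];
          eval_ao(B, a, dx, dy, dz, r2, 0, out);
          aoval[a] = out[0];
        }
        double r = 0;
        for (int n = 0; n < nno; ++n) {
          double v = 0;
          for (int a = 0; a < nao; ++a) v += cno(n, a) * aoval[a];
          r += occ[n] * v * v;
        }
        rho[idx] = r;
      }
    }
  }
  return rho;
}

// Near-grid steepest ascent with path compression.  Returns, per voxel, the
// 1-based linear index of the grid local maximum its ascent path reaches, or
// NA for voxels below the density threshold.  Ties in the ascent slope are
// broken toward the lower linear index (neighbors scanned in ascending
// linear order, strict improvement required).
// [[Rcpp::export]]
IntegerVector cpp_basin_ascent(NumericVector rho, IntegerVector shape,
                               NumericMatrix axes, double thr) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> parent(n);
  // neighbor offsets in ascending linear-offset order
  int offs[26][3];
  double dist[26];
  int m = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        offs[m][0] = di; offs[m][1] = dj; offs[m][2] = dk;
        double vx = di * axes(0, 0) + dj * axes(1, 0) + dk * axes(2, 0);
        double vy = di * axes(0, 1) + dj * axes(1, 1) + dk * axes(2, 1);
        double vz = di * axes(0, 2) + dj * axes(1, 2) + dk * axes(2, 2);
        dist[m] = std::sqrt(vx * vx + vy * vy + vz * vz);
        ++m;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (rho[v] < thr) { parent[v] = -1; continue; }
        double best = 0.0;
        R_xlen_t bestn = v;
        for (int q = 0; q < 26; ++q) {
          const int ii = i + offs[q][0], jj = j + offs[q][1], kk = k + offs[q][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          const double slope = (rho[w] - rho[v]) / dist[q];
          if (slope > best) { best = slope; bestn = w; }
        }
        parent[v] = bestn;
      }
  // path compression by pointer jumping
  bool changed = true;
  while (changed) {
    changed = false;
    for (R_xlen_t v = 0; v < n; ++v) {
      if (parent[v] < 0) continue;
      R_xlen_t p = parent[v];
      if (parent[p] >= 0 && parent[p] != p) {
        parent[v] = parent[p];
        changed = true;
      }
    }
  }
  IntegerVector out(n);
  for (R_xlen_t v = 0; v < n; ++v)
    out[v] = parent[v] < 0 ? NA_INTEGER : (int)(parent[v] + 1);
  return out;
}

// Yu-Trinkle weighted basin integration on a regular grid.  Voxels are
// processed in descending density order; each voxel distributes its weight
// among its (up to 6) Voronoi face neighbors of strictly higher density in
// proportion to (rho_nb - rho_v) * facet_area / distance.  Voxels with no
// higher face neighbor are local maxima and open new basins.  Returns the
// per-voxel argmax-weight basin label (1-based basin ids in discovery
// order), the linear index (1-based) of each basin's maximum, and the
// integrated population of each basin (sum of rho * weight; multiply by the
// voxel volume in R).
// [[Rcpp::export]]
List cpp_basin_yt(NumericVector rho, IntegerVector shape, NumericMatrix axes,
                  double thr) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // face-neighbor offsets and flux coefficients area/dist for an orthogonal
  // grid (general axes: use |a_j x a_k| / |a_i|)
  double coef[3];
  for (int d = 0; d < 3; ++d) {
    int j = (d + 1) % 3, k = (d + 2) % 3;
    double cx = axes(j, 1) * axes(k, 2) - axes(j, 2) * axes(k, 1);
    double cy = axes(j, 2) * axes(k, 0) - axes(j, 0) * axes(k, 2);
    double cz = axes(j, 0) * axes(k, 1) - axes(j, 1) * axes(k, 0);
    double area = std::sqrt(cx * cx + cy * cy + cz * cz);
    double len = std::sqrt(axes(d, 0) * axes(d, 0) + axes(d, 1) * axes(d, 1) +
                           axes(d, 2) * axes(d, 2));
    coef[d] = area / len;
  }
  // order voxels by descending density
  std::vector<int> order;
  order.reserve(n);
  for (R_xlen_t v = 0; v < n; ++v)
    if (rho[v] >= thr) order.push_back((int)v);
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return rho[a] > rho[b]; });
  std::vector<int> label(n, -1);          // basin id, or -2 = fractional
  std::vector<int> multi_slot(n, -1);
  std::vector<std::vector<std::pair<int, double> > > multi;
  std::vector<double> pop;
  std::vector<int> maxima;
  const int strides[3] = {1, nx, nx * ny};
  std::vector<std::pair<int, double> > wacc;
  for (size_t oi = 0; oi < order.size(); ++oi) {
    const int v = order[oi];
    const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    const int ijk[3] = {i, j, k};
    const int lim[3] = {nx, ny, nz};
    double ftot = 0.0;
    wacc.clear();
    for (int d = 0; d < 3; ++d) {
      for (int s = -1; s <= 1; s += 2) {
        if (ijk[d] + s < 0 || ijk[d] + s >= lim[d]) continue;
        const int w = v + s * strides[d];
        if (!(rho[w] > rho[v])) continue;
        const double f = coef[d] * (rho[w] - rho[v]);
        ftot += f;
        if (label[w] >= 0) {
          wacc.push_back(std::make_pair(label[w], f));
        } else if (label[w] == -2) {
          const std::vector<std::pair<int, double> >& mw = multi[multi_slot[w]];
          for (size_t q = 0; q < mw.size(); ++q)
            wacc.push_back(std::make_pair(mw[q].first, f * mw[q].second));
        }
        // neighbors below threshold (label -1) contribute nothing
      }
    }
    if (ftot <= 0.0) {
      // local maximum: new basin
      const int b = (int)pop.size();
      pop.push_back(rho[v]);
      maxima.push_back(v);
      label[v] = b;
      continue;
    }
    // consolidate weights
    std::sort(wacc.begin(), wacc.end());
    std::vector<std::pair<int, double> > wts;
    for (size_t q = 0; q < wacc.size(); ++q) {
      if (!wts.empty() && wts.back().first == wacc[q].first)
        wts.back().second += wacc[q].second;
      else
        wts.push_back(wacc[q]);
    }
    double wsum = 0.0;
    for (size_t q = 0; q < wts.size(); ++q) wsum += wts[q].second;
    for (size_t q = 0; q < wts.size(); ++q) wts[q].second /= wsum;
    // drop negligible fractions to keep the boundary storage small
    if (wts.size() > 1) {
      std::vector<std::pair<int, double> > kept;
      double ksum = 0.0;
      for (size_t q = 0; q < wts.size(); ++q)
        if (wts[q].second > 1e-12) { kept.push_back(wts[q]); ksum += wts[q].second; }
      for (size_t q = 0; q < kept.size(); ++q) kept[q].second /= ksum;
      wts.swap(kept);
    }
    int bestb = wts[0].first;
    double bestw = wts[0].second;
    for (size_t q = 0; q < wts.size(); ++q) {
      pop[wts[q].first] += rho[v] * wts[q].second;
      if (wts[q].second > bestw) { bestw = wts[q].second; bestb = wts[q].first; }
    }
    if (wts.size() == 1) {
      label[v] = wts[0].first;
    } else {
      label[v] = -2;
      multi_slot[v] = (int)multi.size();
      multi.push_back(wts);
    }
  }
  IntegerVector lab(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (label[v] == -1) {
      lab[v] = NA_INTEGER;
    } else if (label[v] == -2) {
      const std::vector<std::pair<int, double> >& mw = multi[multi_slot[v]];
      int bb = mw[0].first; double bw = mw[0].second;
      for (size_t q = 0; q < mw.size(); ++q)
        if (mw[q].second > bw) { bw = mw[q].second; bb = mw[q].first; }
      lab[v] = bb + 1;
    } else {
      lab[v] = label[v] + 1;
    }
  }
  IntegerVector mx(maxima.size());
  NumericVector pp(pop.size());
  for (size_t q = 0; q < maxima.size(); ++q) mx[q] = maxima[q] + 1;
  for (size_t q = 0; q < pop.size(); ++q) pp[q] = pop[q];
  return List::create(_["label"] = lab, _["maxima"] = mx,
                      _["population"] = pp);
}

// Exact-gradient refinement oracle: voxels on basin boundaries (those whose
// 26-neighborhood carries more than one label) are re-assigned by tracing
// the analytic steepest-ascent path of rho from the voxel center until it
// comes within `capture` bohr of an attractor.  Used to validate the grid
// integrators; whole-voxel assignment, no fractional weights.
// [[Rcpp::export]]
IntegerVector cpp_basin_refine(IntegerVector labels, NumericVector origin,
                               NumericMatrix axes, IntegerVector shape,
                               NumericMatrix attractors, List basis,
                               NumericMatrix cno, NumericVector occ,
                               double step, double capture, int max_steps) {
  BasisFlat B(basis);
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int natt = attractors.nrow();
  const int nno = cno.nrow(), nao = B.nao;
  IntegerVector out = clone(labels);
  std::vector<double> aoval(nao * 10), psi(nno), dpsi(3 * nno);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (labels[v] == NA_INTEGER) continue;
        bool boundary = false;
        for (int dk = -1; dk <= 1 && !boundary; ++dk)
          for (int dj = -1; dj <= 1 && !boundary; ++dj)
            for (int di = -1; di <= 1 && !boundary; ++di) {
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              const R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (labels[w] != NA_INTEGER && labels[w] != labels[v])
                boundary = true;
            }
        if (!boundary) continue;
        double x = origin[0] + i * axes(0, 0) + j * axes(1, 0) + k * axes(2, 0);
        double y = origin[1] + i * axes(0, 1) + j * axes(1, 1) + k * axes(2, 1);
        double z = origin[2] + i * axes(0, 2) + j * axes(1, 2) + k * axes(2, 2);
        int hit = -1;
        for (int it = 0; it < max_steps && hit < 0; ++it) {
          for (int a = 0; a < natt; ++a) {
            const double ddx = x - attractors(a, 0), ddy = y - attractors(a, 1),
                         ddz = z - attractors(a, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < capture * capture) {
              hit = a;
              break;
            }
          }
          if (hit >= 0) break;
          // analytic gradient of rho at (x, y, z)
          std::fill(psi.begin(), psi.end(), 0.0);
          std::fill(dpsi.begin(), dpsi.end(), 0.0);
          for (int a = 0; a < nao; ++a) {
            const double dx = x - B.center(a, 0), dy = y - B.center(a, 1),
                         dz = z - B.center(a, 2);
            const double r2 = dx * dx + dy * dy + dz * dz;
            double* o = &aoval[a * 10];
            if (B.minexp[a] * r2 > SCREEN_LOG) {
              for (int q = 0; q < 4; ++q) o[q] = 0.0;
              continue;
            }
            eval_ao(B, a, dx, dy, dz, r2, 1, o);
          }
          double g[3] = {0, 0, 0};
          for (int q = 0; q < nno; ++q) {
            double pv = 0, gx = 0, gy = 0, gz = 0;
            for (int a = 0; a < nao; ++a) {
              pv += cno(q, a) * aoval[a * 10];
              gx += cno(q, a) * aoval[a * 10 + 1];
              gy += cno(q, a) * aoval[a * 10 + 2];
              gz += cno(q, a) * aoval[a * 10 + 3];
            }
            g[0] += 2.0 * occ[q] * pv * gx;
            g[1] += 2.0 * occ[q] * pv * gy;
            g[2] += 2.0 * occ[q] * pv * gz;
          }
          const double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
          if (gn < 1e-14) break;
          x += step * g[0] / gn;
          y += step * g[1] / gn;
          z += step * g[2] / gn;
        }
        if (hit >= 0) out[v] = hit + 1;
      }
    }
  }
  return out;
}
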