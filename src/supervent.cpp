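#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Index helpers: volumes are flattened column-major (x fastest), 0-based.
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 3D median filter, cubic window, nearest-replication at edges.
// If use_mask is true, windows centred on in-mask voxels only pool in-mask
// values (so background never bleeds across the mask border); out-of-mask
// centres use the plain window.
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector data, IntegerVector dim,
                                int window, IntegerVector mask,
                                bool use_mask) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = window / 2;
  NumericVector out(data.size());
  std::vector<double> buf;
  buf.reserve((size_t)window * window * window);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        bool inmask = use_mask && mask[idx3(i, j, k, nx, ny)] != 0;
        buf.clear();
        for (int dk = -h; dk <= h; ++dk) {
          int kk = clampi(k + dk, 0, nz - 1);
          for (int dj = -h; dj <= h; ++dj) {
            int jj = clampi(j + dj, 0, ny - 1);
            for (int di = -h; di <= h; ++di) {
              int ii = clampi(i + di, 0, nx - 1);
              int w = idx3(ii, jj, kk, nx, ny);
              if (inmask && mask[w] == 0) continue;
              buf.push_back(data[w]);
            }
          }
        }
        size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        double med = buf[n / 2];
        if (n % 2 == 0) {
          // even count (cannot happen for odd cubic windows, kept for safety)
          double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
          med = 0.5 * (med + lo);
        }
        out[idx3(i, j, k, nx, ny)] = med;
      }
    }
  }
  return out;
}

// Trilinear sampling at continuous 0-based voxel coordinates (n x 3 matrix).
// Coordinates outside the grid are clamped to the border and flagged.
// [[Rcpp::export]]
List cpp_sample_trilinear(NumericVector data, IntegerVector dim,
                          NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector val(n);
  LogicalVector oob(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    bool out = (x < -1e-9 || y < -1e-9 || z < -1e-9 ||
                x > nx - 1 + 1e-9 || y > ny - 1 + 1e-9 || z > nz - 1 + 1e-9);
    oob[p] = out;
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0 = std::max(0, nx - 2);
    if (j0 == ny - 1) j0 = std::max(0, ny - 2);
    if (k0 == nz - 1) k0 = std::max(0, nz - 2);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = data[idx3(i0, j0, k0, nx, ny)];
    double c100 = data[idx3(i1, j0, k0, nx, ny)];
    double c010 = data[idx3(i0, j1, k0, nx, ny)];
    double c110 = data[idx3(i1, j1, k0, nx, ny)];
    double c001 = data[idx3(i0, j0, k1, nx, ny)];
    double c101 = data[idx3(i1, j0, k1, nx, ny)];
    double c011 = data[idx3(i0, j1, k1, nx, ny)];
    double c111 = data[idx3(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    val[p] = c0 * (1 - fz) + c1 * fz;
  }
  return List::create(_["values"] = val, _["oob"] = oob);
}

// Nearest-neighbour sampling (for masks); same clamping convention.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector data, IntegerVector dim,
                                 NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector val(n);
  for (int p = 0; p < n; ++p) {
    int i = clampi((int)std::lround(pts(p, 0)), 0, nx - 1);
    int j = clampi((int)std::lround(pts(p, 1)), 0, ny - 1);
    int k = clampi((int)std::lround(pts(p, 2)), 0, nz - 1);
    val[p] = data[idx3(i, j, k, nx, ny)];
  }
  return val;
}

// Separable Gaussian convolution, replicate edges. sigma in voxels,
// half-width hw voxels (kernel length 2*hw+1), kernel normalised to sum 1.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector data, IntegerVector dim,
                               double sigma, int hw) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> kern(2 * hw + 1);
  double s = 0.0;
  for (int t = -hw; t <= hw; ++t) {
    kern[t + hw] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + hw];
  }
  for (double& w : kern) w /= s;
  NumericVector a = clone(data), b(data.size());
  // axis 0
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = -hw; t <= hw; ++t)
          acc += kern[t + hw] * a[idx3(clampi(i + t, 0, nx - 1), j, k, nx, ny)];
        b[idx3(i, j, k, nx, ny)] = acc;
      }
  // axis 1
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = -hw; t <= hw; ++t)
          acc += kern[t + hw] * b[idx3(i, clampi(j + t, 0, ny - 1), k, nx, ny)];
        a[idx3(i, j, k, nx, ny)] = acc;
      }
  // axis 2
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = -hw; t <= hw; ++t)
          acc += kern[t + hw] * a[idx3(i, j, clampi(k + t, 0, nz - 1), nx, ny)];
        b[idx3(i, j, k, nx, ny)] = acc;
      }
  return b;
}

// Spacing-aware SLIC on a masked volume.
// seeds_pos: n_seeds x 3, 0-based voxel indices (may be fractional after
// updates); distances are computed in mm via spacing. m_fixed <= 0 selects
// the adaptive (SLIC0-style) scheme: per-cluster m = max |d_c| observed in
// the previous iteration, initialised to m_init.
// Returns 1-based seed labels per voxel (0 outside mask), the objective
// (sum of squared D over mask voxels) per iteration, final seed state,
// iteration count, and the number of voxels not covered by any window.
// [[Rcpp::export]]
List cpp_slic(NumericVector hu, IntegerVector dim, NumericVector spacing,
              IntegerVector mask, NumericMatrix seeds_pos,
              NumericVector seeds_hu, double S_mm, double S_vox,
              double m_fixed, double m_init, int max_iters, double tol_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int ns = seeds_pos.nrow();
  const size_t nvox = hu.size();
  std::vector<double> cx(ns), cy(ns), cz(ns), chu(ns), m(ns, m_init);
  for (int s = 0; s < ns; ++s) {
    cx[s] = seeds_pos(s, 0);
    cy[s] = seeds_pos(s, 1);
    cz[s] = seeds_pos(s, 2);
    chu[s] = seeds_hu[s];
  }
  if (m_fixed > 0) std::fill(m.begin(), m.end(), m_fixed);
  const int win = (int)std::ceil(S_vox);  // half-width S -> window side 2S
  std::vector<int> label(nvox, 0);
  std::vector<double> dist(nvox);
  std::vector<double> objective;
  int iters_done = 0;
  long long n_uncovered = 0;

  for (int iter = 0; iter < max_iters; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(label.begin(), label.end(), 0);
    for (int s = 0; s < ns; ++s) {
      int i0 = clampi((int)std::floor(cx[s]) - win, 0, nx - 1);
      int i1 = clampi((int)std::ceil(cx[s]) + win, 0, nx - 1);
      int j0 = clampi((int)std::floor(cy[s]) - win, 0, ny - 1);
      int j1 = clampi((int)std::ceil(cy[s]) + win, 0, ny - 1);
      int k0 = clampi((int)std::floor(cz[s]) - win, 0, nz - 1);
      int k1 = clampi((int)std::ceil(cz[s]) + win, 0, nz - 1);
      double m2 = m[s] * m[s];
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            int v = idx3(i, j, k, nx, ny);
            if (!mask[v]) continue;
            double dc = hu[v] - chu[s];
            double dxm = (i - cx[s]) * sx, dym = (j - cy[s]) * sy,
                   dzm = (k - cz[s]) * sz;
            double ds2 = dxm * dxm + dym * dym + dzm * dzm;
            double D2 = dc * dc + ds2 / (S_mm * S_mm) * m2;
            if (D2 < dist[v]) {  // strict: lower seed id wins ties
              dist[v] = D2;
              label[v] = s + 1;
            }
          }
    }
    // attach voxels outside every search window to the nearest seed by d_s
    n_uncovered = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int v = idx3(i, j, k, nx, ny);
          if (!mask[v] || label[v] != 0) continue;
          ++n_uncovered;
          double best = R_PosInf;
          int bs = 0;
          for (int s = 0; s < ns; ++s) {
            double dxm = (i - cx[s]) * sx, dym = (j - cy[s]) * sy,
                   dzm = (k - cz[s]) * sz;
            double d2 = dxm * dxm + dym * dym + dzm * dzm;
            if (d2 < best) {
              best = d2;
              bs = s + 1;
            }
          }
          label[v] = bs;
          double dc = hu[v] - chu[bs - 1];
          dist[v] = dc * dc + best / (S_mm * S_mm) * m[bs - 1] * m[bs - 1];
        }
    double obj = 0;
    for (size_t v = 0; v < nvox; ++v)
      if (mask[v]) obj += dist[v];
    objective.push_back(obj);
    iters_done = iter + 1;

    // update centers, mean HU, and adaptive compactness
    std::vector<double> sxs(ns, 0), sys(ns, 0), szs(ns, 0), shu(ns, 0),
        maxdc(ns, 0);
    std::vector<long long> cnt(ns, 0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int v = idx3(i, j, k, nx, ny);
          if (!mask[v]) continue;
          int s = label[v] - 1;
          sxs[s] += i;
          sys[s] += j;
          szs[s] += k;
          shu[s] += hu[v];
          ++cnt[s];
          double adc = std::fabs(hu[v] - chu[s]);
          if (adc > maxdc[s]) maxdc[s] = adc;
        }
    double disp = 0;
    int nne = 0;
    for (int s = 0; s < ns; ++s) {
      if (cnt[s] == 0) continue;  // empty cluster keeps its seed
      double nxp = sxs[s] / cnt[s], nyp = sys[s] / cnt[s],
             nzp = szs[s] / cnt[s];
      double dxm = (nxp - cx[s]) * sx, dym = (nyp - cy[s]) * sy,
             dzm = (nzp - cz[s]) * sz;
      disp += std::sqrt(dxm * dxm + dym * dym + dzm * dzm);
      ++nne;
      cx[s] = nxp;
      cy[s] = nyp;
      cz[s] = nzp;
      chu[s] = shu[s] / cnt[s];
      if (m_fixed <= 0) m[s] = std::max(maxdc[s], 1.0);
    }
    if (nne > 0 && disp / nne < tol_mm) break;
  }

  IntegerVector lab(nvox);
  for (size_t v = 0; v < nvox; ++v) lab[v] = label[v];
  NumericMatrix fs(ns, 4);
  for (int s = 0; s < ns; ++s) {
    fs(s, 0) = cx[s];
    fs(s, 1) = cy[s];
    fs(s, 2) = cz[s];
    fs(s, 3) = chu[s];
  }
  return List::create(_["labels"] = lab, _["objective"] = wrap(objective),
                      _["iterations"] = iters_done, _["seeds"] = fs,
                      _["n_uncovered"] = (double)n_uncovered);
}

// 26-connected component labelling of a positive-integer label field;
// components are maximal connected sets sharing one label value.
// Returns 1-based component ids (0 where labels == 0).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector labels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = labels.size();
  IntegerVector comp(nvox, 0);
  int next = 0;
  std::vector<int> stack;
  for (size_t seed = 0; seed < nvox; ++seed) {
    if (labels[seed] == 0 || comp[seed] != 0) continue;
    int lab = labels[seed];
    ++next;
    comp[seed] = next;
    stack.clear();
    stack.push_back((int)seed);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                kk >= nz)
              continue;
            int w = idx3(ii, jj, kk, nx, ny);
            if (labels[w] == lab && comp[w] == 0) {
              comp[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  return comp;
}

// One connectivity-enforcement pass: every component that is not the largest
// component of its label, or whose size is below min_size, is merged into the
// neighbouring label sharing the longest face (6-neighbour) boundary.
// Components are processed smallest-first. Returns the updated label field
// and the number of merges performed.
// [[Rcpp::export]]
List cpp_merge_components(IntegerVector labels, IntegerVector dim,
                          int min_size) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = labels.size();
  IntegerVector comp = cpp_label_components(labels, dim);
  int ncomp = 0;
  for (size_t v = 0; v < nvox; ++v) ncomp = std::max(ncomp, comp[v]);
  if (ncomp == 0)
    return List::create(_["labels"] = clone(labels), _["n_merged"] = 0);
  std::vector<long long> csize(ncomp + 1, 0);
  std::vector<int> clabel(ncomp + 1, 0);
  std::vector<std::vector<int> > cvox(ncomp + 1);
  for (size_t v = 0; v < nvox; ++v) {
    if (comp[v] == 0) continue;
    ++csize[comp[v]];
    clabel[comp[v]] = labels[v];
  }
  for (int c = 1; c <= ncomp; ++c) cvox[c].reserve(csize[c]);
  for (size_t v = 0; v < nvox; ++v)
    if (comp[v] != 0) cvox[comp[v]].push_back((int)v);
  // largest component per label (ties -> lowest component id)
  int maxlab = 0;
  for (int c = 1; c <= ncomp; ++c) maxlab = std::max(maxlab, clabel[c]);
  std::vector<int> maincomp(maxlab + 1, 0);
  for (int c = 1; c <= ncomp; ++c) {
    int L = clabel[c];
    if (maincomp[L] == 0 || csize[c] > csize[maincomp[L]]) maincomp[L] = c;
  }
  std::vector<int> order;
  for (int c = 1; c <= ncomp; ++c) order.push_back(c);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (csize[a] != csize[b]) return csize[a] < csize[b];
    return a < b;
  });
  IntegerVector cur = clone(labels);
  const int di6[6] = {1, -1, 0, 0, 0, 0};
  const int dj6[6] = {0, 0, 1, -1, 0, 0};
  const int dk6[6] = {0, 0, 0, 0, 1, -1};
  int n_merged = 0;
  for (int c : order) {
    int L = clabel[c];
    bool is_main = (maincomp[L] == c);
    if (is_main && csize[c] >= min_size) continue;
    // face-adjacency counts to other current labels
    std::vector<std::pair<int, int> > touch;  // (label, count) linear scan
    for (int v : cvox[c]) {
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        int ii = i + di6[d], jj = j + dj6[d], kk = k + dk6[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int w = idx3(ii, jj, kk, nx, ny);
        int wl = cur[w];
        if (wl == 0 || wl == cur[v]) continue;
        bool found = false;
        for (auto& t : touch)
          if (t.first == wl) {
            ++t.second;
            found = true;
            break;
          }
        if (!found) touch.push_back(std::make_pair(wl, 1));
      }
    }
    if (touch.empty()) continue;  // isolated region: keep as its own label
    int best = touch[0].first, bestn = touch[0].second;
    for (auto& t : touch)
      if (t.second > bestn || (t.second == bestn && t.first < best)) {
        best = t.first;
        bestn = t.second;
      }
    for (int v : cvox[c]) cur[v] = best;
    ++n_merged;
  }
  return List::create(_["labels"] = cur, _["n_merged"] = n_merged);
}

// Per-voxel 3x3 Jacobian determinant of x + u(x) from central differences of
// the displacement field (mm), one-sided at the volume boundary.
// u is passed as three flattened component volumes.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector ux, NumericVector uy,
                               NumericVector uz, IntegerVector dim,
                               NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(ux.size());
  const NumericVector* comp[3] = {&ux, &uy, &uz};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double J[3][3];
        int c0[3] = {i, j, k};
        int nd[3] = {nx, ny, nz};
        for (int a = 0; a < 3; ++a) {      // component
          for (int b = 0; b < 3; ++b) {    // derivative axis
            int lo[3] = {i, j, k}, hi[3] = {i, j, k};
            lo[b] = std::max(c0[b] - 1, 0);
            hi[b] = std::min(c0[b] + 1, nd[b] - 1);
            double dv = (*comp[a])[idx3(hi[0], hi[1], hi[2], nx, ny)] -
                        (*comp[a])[idx3(lo[0], lo[1], lo[2], nx, ny)];
            double dxm = (hi[b] - lo[b]) * spacing[b];
            J[a][b] = (dxm > 0 ? dv / dxm : 0.0) + (a == b ? 1.0 : 0.0);
          }
        }
        double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                     J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                     J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        out[idx3(i, j, k, nx, ny)] = det - 1.0;
      }
  return out;
}
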