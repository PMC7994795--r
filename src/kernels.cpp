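// Low-level spatial kernels for volumetric SMLM processing:
// grid-indexed DBSCAN, sparse Gaussian density deposition, connected
// components on sparse voxel sets, and small dense binary morphology
// used for bouton shell closing/filling.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <functional>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int64_t vox_key(int64_t i, int64_t j, int64_t k,
                              int64_t nj, int64_t nk) {
  return (i * nj + j) * nk + k;
}

// ---------------------------------------------------------------- DBSCAN ---

// Classic DBSCAN on 3D points. Grid cells of edge eps index the points so a
// neighbourhood query touches at most 27 cells. Labels: 0 = noise, 1..K.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, NumericVector z,
                         double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (z[i] < zmin) zmin = z[i];
  }
  std::vector<int> ci(n), cj(n), ck(n);
  int64_t ni = 0, nj = 0, nk = 0;
  for (int i = 0; i < n; ++i) {
    ci[i] = (int)std::floor((x[i] - xmin) / eps);
    cj[i] = (int)std::floor((y[i] - ymin) / eps);
    ck[i] = (int)std::floor((z[i] - zmin) / eps);
    if (ci[i] + 1 > ni) ni = ci[i] + 1;
    if (cj[i] + 1 > nj) nj = cj[i] + 1;
    if (ck[i] + 1 > nk) nk = ck[i] + 1;
  }
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i)
    grid[vox_key(ci[i], cj[i], ck[i], nj, nk)].push_back(i);

  const double eps2 = eps * eps;
  std::vector<int> nbr;
  auto region_query = [&](int p) {
    nbr.clear();
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          int64_t ii = ci[p] + di, jj = cj[p] + dj, kk = ck[p] + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= ni || jj >= nj || kk >= nk)
            continue;
          auto it = grid.find(vox_key(ii, jj, kk, nj, nk));
          if (it == grid.end()) continue;
          for (int q : it->second) {
            double dx = x[p] - x[q], dy = y[p] - y[q], dz = z[p] - z[q];
            if (dx * dx + dy * dy + dz * dz <= eps2) nbr.push_back(q);
          }
        }
  };

  // visited: 0 unvisited, 1 visited
  std::vector<char> visited(n, 0);
  int cluster = 0;
  std::vector<int> seeds;
  for (int p = 0; p < n; ++p) {
    if (visited[p]) continue;
    visited[p] = 1;
    region_query(p);
    if ((int)nbr.size() < min_pts) continue; // provisionally noise
    ++cluster;
    labels[p] = cluster;
    seeds.assign(nbr.begin(), nbr.end());
    for (size_t s = 0; s < seeds.size(); ++s) {
      int q = seeds[s];
      if (labels[q] == 0) labels[q] = cluster; // border or reclaimed noise
      if (visited[q]) continue;
      visited[q] = 1;
      region_query(q);
      if ((int)nbr.size() >= min_pts)
        seeds.insert(seeds.end(), nbr.begin(), nbr.end());
    }
  }
  return labels;
}

// ------------------------------------------------ sparse density rendering ---

// Deposit one integrated anisotropic Gaussian per localization onto a sparse
// voxel grid. Per-axis voxel weights use the Gaussian CDF over the voxel
// extent, so each localization contributes (almost exactly) unit mass within
// cutoff_sd standard deviations. Values are densities in localizations/um^3.
// [[Rcpp::export]]
List cpp_density_sparse(NumericVector x, NumericVector y, NumericVector z,
                        NumericVector origin, NumericVector voxel,
                        NumericVector sigma, double cutoff_sd) {
  const int n = x.size();
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  const double sx = sigma[0], sy = sigma[1], sz = sigma[2];
  const double voxvol_um3 = vx * vy * vz * 1e-9; // nm^3 -> um^3

  // global index bounds over all stamps
  int64_t imin = INT64_MAX, jmin = INT64_MAX, kmin = INT64_MAX;
  int64_t imax = INT64_MIN, jmax = INT64_MIN, kmax = INT64_MIN;
  if (n == 0)
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["k"] = IntegerVector(0), _["value"] = NumericVector(0),
                        _["dims"] = IntegerVector::create(0, 0, 0),
                        _["offset"] = IntegerVector::create(0, 0, 0));
  for (int p = 0; p < n; ++p) {
    int64_t i0 = (int64_t)std::floor((x[p] - cutoff_sd * sx - origin[0]) / vx);
    int64_t i1 = (int64_t)std::floor((x[p] + cutoff_sd * sx - origin[0]) / vx);
    int64_t j0 = (int64_t)std::floor((y[p] - cutoff_sd * sy - origin[1]) / vy);
    int64_t j1 = (int64_t)std::floor((y[p] + cutoff_sd * sy - origin[1]) / vy);
    int64_t k0 = (int64_t)std::floor((z[p] - cutoff_sd * sz - origin[2]) / vz);
    int64_t k1 = (int64_t)std::floor((z[p] + cutoff_sd * sz - origin[2]) / vz);
    if (i0 < imin) imin = i0;  if (i1 > imax) imax = i1;
    if (j0 < jmin) jmin = j0;  if (j1 > jmax) jmax = j1;
    if (k0 < kmin) kmin = k0;  if (k1 > kmax) kmax = k1;
  }
  const int64_t nj = jmax - jmin + 1, nk = kmax - kmin + 1;

  std::unordered_map<int64_t, double> acc;
  acc.reserve(n * 8);
  const double s2x = sx * M_SQRT2, s2y = sy * M_SQRT2, s2z = sz * M_SQRT2;
  std::vector<double> wi, wj, wk;
  for (int p = 0; p < n; ++p) {
    int64_t i0 = (int64_t)std::floor((x[p] - cutoff_sd * sx - origin[0]) / vx);
    int64_t i1 = (int64_t)std::floor((x[p] + cutoff_sd * sx - origin[0]) / vx);
    int64_t j0 = (int64_t)std::floor((y[p] - cutoff_sd * sy - origin[1]) / vy);
    int64_t j1 = (int64_t)std::floor((y[p] + cutoff_sd * sy - origin[1]) / vy);
    int64_t k0 = (int64_t)std::floor((z[p] - cutoff_sd * sz - origin[2]) / vz);
    int64_t k1 = (int64_t)std::floor((z[p] + cutoff_sd * sz - origin[2]) / vz);
    wi.clear(); wj.clear(); wk.clear();
    for (int64_t i = i0; i <= i1; ++i) {
      double a = origin[0] + i * vx, b = a + vx;
      wi.push_back(0.5 * (std::erf((b - x[p]) / s2x) - std::erf((a - x[p]) / s2x)));
    }
    for (int64_t j = j0; j <= j1; ++j) {
      double a = origin[1] + j * vy, b = a + vy;
      wj.push_back(0.5 * (std::erf((b - y[p]) / s2y) - std::erf((a - y[p]) / s2y)));
    }
    for (int64_t k = k0; k <= k1; ++k) {
      double a = origin[2] + k * vz, b = a + vz;
      wk.push_back(0.5 * (std::erf((b - z[p]) / s2z) - std::erf((a - z[p]) / s2z)));
    }
    for (size_t a = 0; a < wi.size(); ++a)
      for (size_t b = 0; b < wj.size(); ++b) {
        double wab = wi[a] * wj[b];
        if (wab <= 0) continue;
        for (size_t c = 0; c < wk.size(); ++c) {
          double w = wab * wk[c];
          if (w <= 0) continue;
          acc[vox_key(i0 + a - imin, j0 + b - jmin, k0 + c - kmin, nj, nk)] += w;
        }
      }
  }

  const size_t m = acc.size();
  IntegerVector oi(m), oj(m), ok(m);
  NumericVector val(m);
  size_t idx = 0;
  for (auto &kv : acc) {
    int64_t key = kv.first;
    int64_t kk = key % nk, rest = key / nk;
    int64_t jj = rest % nj, ii = rest / nj;
    oi[idx] = (int)ii; oj[idx] = (int)jj; ok[idx] = (int)kk;
    val[idx] = kv.second / voxvol_um3;
    ++idx;
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["k"] = ok, _["value"] = val,
                      _["dims"] = IntegerVector::create((int)(imax - imin + 1),
                                                        (int)nj, (int)nk),
                      _["offset"] = IntegerVector::create((int)imin, (int)jmin,
                                                          (int)kmin));
}

// ----------------------------------------- sparse 26-connected components ---

// [[Rcpp::export]]
IntegerVector cpp_components_sparse(IntegerVector i, IntegerVector j,
                                    IntegerVector k) {
  const int n = i.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  int64_t jmax = 0, kmax = 0;
  for (int p = 0; p < n; ++p) {
    if (j[p] > jmax) jmax = j[p];
    if (k[p] > kmax) kmax = k[p];
  }
  const int64_t nj = jmax + 2, nk = kmax + 2; // +2: room for +1 neighbours
  std::unordered_map<int64_t, int> index;
  index.reserve(n * 2);
  for (int p = 0; p < n; ++p)
    index[vox_key(i[p], j[p], k[p], nj, nk)] = p;

  // union-find
  std::vector<int> parent(n);
  for (int p = 0; p < n; ++p) parent[p] = p;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int p = 0; p < n; ++p) {
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int64_t ii = (int64_t)i[p] + di, jj = (int64_t)j[p] + dj,
                  kk = (int64_t)k[p] + dk;
          if (ii < 0 || jj < 0 || kk < 0) continue;
          auto it = index.find(vox_key(ii, jj, kk, nj, nk));
          if (it == index.end()) continue;
          int ra = find(p), rb = find(it->second);
          if (ra != rb) parent[rb] = ra;
        }
  }
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int p = 0; p < n; ++p) {
    int r = find(p);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; labels[p] = next; }
    else labels[p] = it->second;
  }
  return labels;
}

// Map query voxel coordinates to the label of the voxel they fall in
// (0 where the voxel carries no label).
// [[Rcpp::export]]
IntegerVector cpp_voxel_lookup(IntegerVector qi, IntegerVector qj,
                               IntegerVector qk, IntegerVector vi,
                               IntegerVector vj, IntegerVector vk,
                               IntegerVector labels) {
  int64_t jmax = 1, kmax = 1;
  for (int p = 0; p < vj.size(); ++p) {
    if (vj[p] > jmax) jmax = vj[p];
    if (vk[p] > kmax) kmax = vk[p];
  }
  for (int p = 0; p < qj.size(); ++p) {
    if (qj[p] > jmax) jmax = qj[p];
    if (qk[p] > kmax) kmax = qk[p];
  }
  const int64_t nj = jmax + 1, nk = kmax + 1;
  std::unordered_map<int64_t, int> map;
  map.reserve(vi.size() * 2);
  for (int p = 0; p < vi.size(); ++p)
    map[vox_key(vi[p], vj[p], vk[p], nj, nk)] = labels[p];
  IntegerVector out(qi.size(), 0);
  for (int p = 0; p < qi.size(); ++p) {
    if (qi[p] < 0 || qj[p] < 0 || qk[p] < 0) continue;
    auto it = map.find(vox_key(qi[p], qj[p], qk[p], nj, nk));
    if (it != map.end()) out[p] = it->second;
  }
  return out;
}

// ------------------------------------------------- dense binary morphology ---

static void morph1d_axis(std::vector<char> &m, const IntegerVector &dim,
                         int axis, int r, bool dilate) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  std::vector<char> out(m.size());
  int len = (axis == 0) ? d0 : (axis == 1 ? d1 : d2);
  std::vector<char> line(len);
  int n0 = (axis == 0) ? d1 : d0;
  int n1 = (axis == 2) ? d1 : d2;
  for (int a = 0; a < n0; ++a)
    for (int b = 0; b < n1; ++b) {
      for (int t = 0; t < len; ++t) {
        size_t idx;
        if (axis == 0) idx = (size_t)t + (size_t)d0 * (a + (size_t)d1 * b);
        else if (axis == 1) idx = (size_t)a + (size_t)d0 * (t + (size_t)d1 * b);
        else idx = (size_t)a + (size_t)d0 * (b + (size_t)d1 * t);
        line[t] = m[idx];
      }
      for (int t = 0; t < len; ++t) {
        char v = dilate ? 0 : 1;
        int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        for (int u = lo; u <= hi; ++u) {
          if (dilate) { if (line[u]) { v = 1; break; } }
          else { if (!line[u]) { v = 0; break; } }
        }
        size_t idx;
        if (axis == 0) idx = (size_t)t + (size_t)d0 * (a + (size_t)d1 * b);
        else if (axis == 1) idx = (size_t)a + (size_t)d0 * (t + (size_t)d1 * b);
        else idx = (size_t)a + (size_t)d0 * (b + (size_t)d1 * t);
        out[idx] = v;
      }
    }
  m.swap(out);
}

// Binary closing with a box structuring element of half-width r (separable).
// [[Rcpp::export]]
LogicalVector cpp_close_box(LogicalVector mask, IntegerVector dim, int r) {
  std::vector<char> m(mask.size());
  for (R_xlen_t p = 0; p < mask.size(); ++p) m[p] = mask[p] ? 1 : 0;
  for (int axis = 0; axis < 3; ++axis) morph1d_axis(m, dim, axis, r, true);
  for (int axis = 0; axis < 3; ++axis) morph1d_axis(m, dim, axis, r, false);
  LogicalVector out(mask.size());
  for (R_xlen_t p = 0; p < mask.size(); ++p) out[p] = m[p] != 0;
  return out;
}

// Binary erosion with a box structuring element of half-width r (separable).
// [[Rcpp::export]]
LogicalVector cpp_erode_box(LogicalVector mask, IntegerVector dim, int r) {
  std::vector<char> m(mask.size());
  for (R_xlen_t p = 0; p < mask.size(); ++p) m[p] = mask[p] ? 1 : 0;
  for (int axis = 0; axis < 3; ++axis) morph1d_axis(m, dim, axis, r, false);
  LogicalVector out(mask.size());
  for (R_xlen_t p = 0; p < mask.size(); ++p) out[p] = m[p] != 0;
  return out;
}

// Fill interior cavities: voxels not 6-connected to the array border through
// background become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const size_t n = (size_t)d0 * d1 * d2;
  std::vector<char> reach(n, 0);
  std::queue<size_t> q;
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)d0 * (j + (size_t)d1 * k);
  };
  auto push = [&](int i, int j, int k) {
    size_t p = idx(i, j, k);
    if (!reach[p] && !mask[p]) { reach[p] = 1; q.push(p); }
  };
  for (int j = 0; j < d1; ++j)
    for (int k = 0; k < d2; ++k) { push(0, j, k); push(d0 - 1, j, k); }
  for (int i = 0; i < d0; ++i)
    for (int k = 0; k < d2; ++k) { push(i, 0, k); push(i, d1 - 1, k); }
  for (int i = 0; i < d0; ++i)
    for (int j = 0; j < d1; ++j) { push(i, j, 0); push(i, j, d2 - 1); }
  while (!q.empty()) {
    size_t p = q.front(); q.pop();
    int k = (int)(p / ((size_t)d0 * d1));
    int j = (int)((p / d0) % d1);
    int i = (int)(p % d0);
    if (i > 0) push(i - 1, j, k);
    if (i < d0 - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < d1 - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < d2 - 1) push(i, j, k + 1);
  }
  LogicalVector out(mask.size());
  for (size_t p = 0; p < n; ++p) out[p] = mask[p] || !reach[p];
  return out;
}

// Maximum pairwise Euclidean distance (3D Feret diameter) of a point set.
// [[Rcpp::export]]
double cpp_max_pairwise(NumericVector x, NumericVector y, NumericVector z) {
  const int n = x.size();
  double best = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
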