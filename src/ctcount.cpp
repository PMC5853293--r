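#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays with dim = (nz, ny, nx): z is the fastest-varying
// (page) axis, linear index = z + nz*(y + ny*x), all 0-based here.

static inline int reflect_idx(int i, int n) {
  // symmetric boundary: ...2 1 0 | 0 1 2 ... n-1 | n-1 n-2...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Connected-component labelling of a 3D logical mask, 6- or 26-adjacency.
// Labels are assigned in raster-scan order of each component's first voxel,
// which makes the output deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector lab(n);
  std::vector<int> dz, dy, dx;
  for (int ix = -1; ix <= 1; ++ix)
    for (int iy = -1; iy <= 1; ++iy)
      for (int iz = -1; iz <= 1; ++iz) {
        if (ix == 0 && iy == 0 && iz == 0) continue;
        if (connectivity == 6 && std::abs(ix) + std::abs(iy) + std::abs(iz) != 1) continue;
        dz.push_back(iz); dy.push_back(iy); dx.push_back(ix);
      }
  const int nn = (int)dz.size();
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (m[i] != TRUE || L[i] != 0) continue;
    ++cur;
    L[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z = (int)(p % nz);
      R_xlen_t r = p / nz;
      int y = (int)(r % ny), x = (int)(r / ny);
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (m[q] == TRUE && L[q] == 0) { L[q] = cur; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_labels") = cur;
  return lab;
}

// 3D median filter, cubic kernel k x k x k, symmetric (mirror) padding.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim, int k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vol.size() != n) stop("volume length does not match dim");
  if (k < 1 || k % 2 == 0) stop("kernel size must be odd and >= 1");
  if (k == 1) return clone(vol);
  const int h = k / 2;
  NumericVector out(n);
  const double *v = REAL(vol);
  double *o = REAL(out);
  std::vector<double> buf((size_t)k * k * k);
  const size_t mid = buf.size() / 2;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t b = 0;
        for (int ix = -h; ix <= h; ++ix) {
          R_xlen_t ox = (R_xlen_t)nz * ny * reflect_idx(x + ix, nx);
          for (int iy = -h; iy <= h; ++iy) {
            R_xlen_t oy = ox + (R_xlen_t)nz * reflect_idx(y + iy, ny);
            for (int iz = -h; iz <= h; ++iz)
              buf[b++] = v[oy + reflect_idx(z + iz, nz)];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        o[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = buf[mid];
      }
  return out;
}

// One separable convolution pass along `axis` (0=z, 1=y, 2=x) with an odd
// symmetric-padded kernel; applied three times by the R wrapper.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vol.size() != n) stop("volume length does not match dim");
  const int k = (int)kernel.size();
  if (k % 2 == 0) stop("kernel length must be odd");
  const int h = k / 2;
  NumericVector out(n);
  const double *v = REAL(vol);
  const double *w = REAL(kernel);
  double *o = REAL(out);
  const int nax = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  const R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nz : (R_xlen_t)nz * ny;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const int pos = (axis == 0) ? z : (axis == 1) ? y : x;
        const R_xlen_t base0 = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)
          - (R_xlen_t)pos * stride;
        double acc = 0.0;
        for (int j = -h; j <= h; ++j)
          acc += w[j + h] * v[base0 + (R_xlen_t)reflect_idx(pos + j, nax) * stride];
        o[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = acc;
      }
  return out;
}

// Paint solid spheres into a background volume: voxel centres sit at
// (i + 0.5) * spacing along each axis; a voxel is foreground when its centre
// lies inside any sphere. `centers` are in micrometres relative to `origin`.
// [[Rcpp::export]]
NumericVector cpp_render_spheres(NumericVector base, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix centers, NumericVector radii,
                                 double fg) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (base.size() != n) stop("base length does not match dim");
  NumericVector out = clone(base);
  double *o = REAL(out);
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  for (int s = 0; s < centers.nrow(); ++s) {
    const double cz = centers(s, 0) - origin[0];
    const double cy = centers(s, 1) - origin[1];
    const double cx = centers(s, 2) - origin[2];
    const double r = radii[s], r2 = r * r;
    int z0 = std::max(0, (int)std::floor((cz - r) / sz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + r) / sz));
    int y0 = std::max(0, (int)std::floor((cy - r) / sy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + r) / sy));
    int x0 = std::max(0, (int)std::floor((cx - r) / sx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + r) / sx));
    for (int x = x0; x <= x1; ++x) {
      const double ddx = (x + 0.5) * sx - cx;
      for (int y = y0; y <= y1; ++y) {
        const double ddy = (y + 0.5) * sy - cy;
        const double rem = r2 - ddx * ddx - ddy * ddy;
        if (rem < 0) continue;
        for (int z = z0; z <= z1; ++z) {
          const double ddz = (z + 0.5) * sz - cz;
          if (ddz * ddz <= rem)
            o[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = fg;
        }
      }
    }
  }
  return out;
}

// Incremental merge tree (max-tree) of the descending threshold sweep.
// Voxels enter at the first threshold not above their grey value; components
// grow and merge as the threshold drops.  Returns, per voxel, the branch
// node it attached to and its entry level, and, per node, the parent branch,
// creation level and the per-level voxel-count profile.  Everything is
// deterministic given the input.
// [[Rcpp::export]]
List cpp_threshold_sweep(NumericVector vol, IntegerVector dim,
                         LogicalVector mask, NumericVector thresholds,
                         int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int K = (int)thresholds.size();
  if (vol.size() != n || mask.size() != n) stop("length mismatch");
  std::vector<int> dzs, dys, dxs;
  for (int ix = -1; ix <= 1; ++ix)
    for (int iy = -1; iy <= 1; ++iy)
      for (int iz = -1; iz <= 1; ++iz) {
        if (ix == 0 && iy == 0 && iz == 0) continue;
        if (connectivity == 6 && std::abs(ix) + std::abs(iy) + std::abs(iz) != 1) continue;
        dzs.push_back(iz); dys.push_back(iy); dxs.push_back(ix);
      }
  const int nn = (int)dzs.size();
  const double *v = REAL(vol);
  const int *msk = LOGICAL(mask);

  // entry level per voxel: first (brightest) threshold <= value; -1 = never
  std::vector<int> appear(n, -1);
  std::vector<R_xlen_t> levCount(K + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (msk[i] != TRUE) continue;
    // binary search in descending thresholds: first k with thr[k] <= v[i]
    int lo = 0, hi = K;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (thresholds[mid] <= v[i]) hi = mid; else lo = mid + 1;
    }
    if (lo < K) { appear[i] = lo; ++levCount[lo]; }
  }
  // counting sort of voxels by entry level
  std::vector<R_xlen_t> offs(K + 1, 0);
  for (int k = 1; k <= K; ++k) offs[k] = offs[k - 1] + levCount[k - 1];
  std::vector<R_xlen_t> order(offs[K]);
  {
    std::vector<R_xlen_t> cur(offs);
    for (R_xlen_t i = 0; i < n; ++i)
      if (appear[i] >= 0) order[cur[appear[i]]++] = i;
  }

  // union-find
  std::vector<R_xlen_t> uf(n, -1);   // -1 = not yet added; else parent or self
  std::vector<R_xlen_t> sz(n, 0);
  std::function<R_xlen_t(R_xlen_t)> find = [&](R_xlen_t a) {
    while (uf[a] != a) { uf[a] = uf[uf[a]]; a = uf[a]; }
    return a;
  };

  // merge-tree nodes (1-based ids)
  std::vector<int> nodeParent(1, 0), nodeStart(1, 0), nodeRepLevel(1, 0);
  std::vector<char> nodeDefunct(1, 0), nodeIsMerge(1, 0);
  std::vector<std::vector<double>> profiles(1);
  std::vector<R_xlen_t> nodeRep(1, 0);
  std::vector<int> rootNode(1, 0);         // per-root node id; index into map
  std::vector<int> voxNode;                 // lazily: rootNode stored per voxel index
  voxNode.assign(n, 0);                     // node id of root voxel (valid when root)
  std::vector<int> attach(n, 0);
  std::vector<int> alive;                   // alive node ids

  int nnode = 0;
  auto newNode = [&](int level, R_xlen_t rep, char isMerge) {
    nodeParent.push_back(0); nodeStart.push_back(level);
    nodeDefunct.push_back(0); nodeIsMerge.push_back(isMerge);
    profiles.push_back(std::vector<double>());
    nodeRep.push_back(rep); nodeRepLevel.push_back(level);
    ++nnode;
    alive.push_back(nnode);
    return nnode;
  };

  R_xlen_t p0 = 0;
  for (int k = 0; k < K; ++k) {
    R_xlen_t p1 = p0 + levCount[k];
    // add voxels of this level
    for (R_xlen_t pi = p0; pi < p1; ++pi) {
      R_xlen_t i = order[pi];
      uf[i] = i; sz[i] = 1; voxNode[i] = 0;
    }
    // union with present neighbours
    for (R_xlen_t pi = p0; pi < p1; ++pi) {
      R_xlen_t i = order[pi];
      int z = (int)(i % nz);
      R_xlen_t r = i / nz;
      int y = (int)(r % ny), x = (int)(r / ny);
      for (int t = 0; t < nn; ++t) {
        int zz = z + dzs[t], yy = y + dys[t], xx = x + dxs[t];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (uf[q] < 0) continue;
        R_xlen_t ra = find(i), rb = find(q);
        if (ra == rb) continue;
        int na = voxNode[ra], nb = voxNode[rb];
        if (sz[ra] < sz[rb]) std::swap(ra, rb);
        uf[rb] = ra; sz[ra] += sz[rb];
        int nres;
        if (na == 0 && nb == 0) nres = 0;
        else if (na == 0) nres = nb;
        else if (nb == 0) nres = na;
        else if (na == nb) nres = na;
        else if (nodeIsMerge[na] && nodeStart[na] == k) {
          // absorb nb into the merge node created at this level
          if (nodeIsMerge[nb] && nodeStart[nb] == k) {
            nodeDefunct[nb] = 1;
            for (int j = 1; j <= nnode; ++j)
              if (nodeParent[j] == nb) nodeParent[j] = na;
          } else nodeParent[nb] = na;
          nres = na;
        } else if (nodeIsMerge[nb] && nodeStart[nb] == k) {
          if (nodeIsMerge[na] && nodeStart[na] == k) {
            nodeDefunct[na] = 1;
            for (int j = 1; j <= nnode; ++j)
              if (nodeParent[j] == na) nodeParent[j] = nb;
          } else nodeParent[na] = nb;
          nres = nb;
        } else {
          nres = newNode(k, nodeRep[na], 1);
          nodeParent[na] = nres; nodeParent[nb] = nres;
        }
        voxNode[ra] = nres;
      }
    }
    // new components become leaf nodes; record attachment
    for (R_xlen_t pi = p0; pi < p1; ++pi) {
      R_xlen_t i = order[pi];
      R_xlen_t r = find(i);
      if (voxNode[r] == 0) voxNode[r] = newNode(k, i, 0);
    }
    for (R_xlen_t pi = p0; pi < p1; ++pi) {
      R_xlen_t i = order[pi];
      attach[i] = voxNode[find(i)];
    }
    // append profiles for alive nodes; drop merged/defunct ones
    std::vector<int> stillAlive;
    stillAlive.reserve(alive.size());
    for (int id : alive) {
      if (nodeDefunct[id]) continue;
      R_xlen_t r = find(nodeRep[id]);
      if (voxNode[r] != id) continue;          // merged into another branch
      profiles[id].push_back((double)sz[r]);
      stillAlive.push_back(id);
    }
    alive.swap(stillAlive);
    p0 = p1;
  }

  List prof(nnode);
  IntegerVector par(nnode), start(nnode);
  LogicalVector defunct(nnode);
  for (int id = 1; id <= nnode; ++id) {
    prof[id - 1] = NumericVector(profiles[id].begin(), profiles[id].end());
    par[id - 1] = nodeParent[id];
    start[id - 1] = nodeStart[id] + 1;  // 1-based level of first profile entry
    defunct[id - 1] = nodeDefunct[id] == 1;
  }
  return List::create(_["attach"] = IntegerVector(attach.begin(), attach.end()),
                      _["appear"] = IntegerVector(appear.begin(), appear.end()),
                      _["parent"] = par, _["startLevel"] = start,
                      _["profile"] = prof, _["defunct"] = defunct);
}
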