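// 3D SLIC supervoxels on a masked volume, plus 26-connectivity utilities
// and the minimum-size merge pass. Distances follow
//   D^2 = d_intensity^2 + (d_spatial / S)^2 * compactness^2
// with cluster search restricted to a +/- 2S window around each center.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <map>
#include <set>
#include <algorithm>
using namespace Rcpp;

static const int NB26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
  {-1,1,-1},{0,1,-1},{1,1,-1},{-1,-1,0},{0,-1,0},{1,-1,0},
  {-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
  {-1,1,1},{0,1,1},{1,1,1}};

struct Grid {
  int nx, ny, nz;
  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  }
  inline bool in(int x, int y, int z) const {
    return x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz;
  }
};

// squared intensity gradient from in-mask axial neighbours
static double grad2(const double* img, const int* mask, const Grid& g,
                    int x, int y, int z) {
  double s = 0.0;
  const double v = img[g.idx(x, y, z)];
  const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < 6; ++k) {
    int xx = x + d[k][0], yy = y + d[k][1], zz = z + d[k][2];
    if (g.in(xx, yy, zz) && mask[g.idx(xx, yy, zz)]) {
      double dd = img[g.idx(xx, yy, zz)] - v;
      s += dd * dd;
    }
  }
  return s;
}

// [[Rcpp::export]]
List cpp_slic3d(NumericVector img, IntegerVector mask, IntegerVector dim,
                int n_superpixels, double compactness, int max_iter) {
  Grid g{dim[0], dim[1], dim[2]};
  const R_xlen_t nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  if (img.size() != nvox || mask.size() != nvox) stop("dimension mismatch");
  const double* I = img.begin();
  const int* M = mask.begin();
  R_xlen_t nmask = 0;
  for (R_xlen_t i = 0; i < nvox; ++i) if (M[i]) ++nmask;
  if (nmask == 0) stop("slic3d: empty mask");
  if (n_superpixels < 1) stop("slic3d: n_superpixels must be >= 1");
  if ((R_xlen_t)n_superpixels > nmask)
    stop("slic3d: n_superpixels exceeds the number of in-mask voxels");

  const double S = std::cbrt((double)nmask / (double)n_superpixels);

  // seed centers on a regular grid with spacing S, perturbed to the
  // lowest-gradient in-mask voxel in a 3x3x3 neighbourhood
  std::vector<double> cx, cy, cz, ci;
  for (double z0 = S / 2.0; z0 < g.nz; z0 += S)
    for (double y0 = S / 2.0; y0 < g.ny; y0 += S)
      for (double x0 = S / 2.0; x0 < g.nx; x0 += S) {
        int x = (int)std::floor(x0), y = (int)std::floor(y0),
            z = (int)std::floor(z0);
        if (!g.in(x, y, z)) continue;
        int bx = -1, by = -1, bz = -1;
        double bg = R_PosInf;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!g.in(xx, yy, zz) || !M[g.idx(xx, yy, zz)]) continue;
              double gr = grad2(I, M, g, xx, yy, zz);
              if (gr < bg) { bg = gr; bx = xx; by = yy; bz = zz; }
            }
        if (bx < 0) continue;  // no in-mask voxel near this grid node
        cx.push_back(bx); cy.push_back(by); cz.push_back(bz);
        ci.push_back(I[g.idx(bx, by, bz)]);
      }
  if (cx.empty()) {  // degenerate tiny mask: seed at first in-mask voxel
    for (R_xlen_t i = 0; i < nvox && cx.empty(); ++i)
      if (M[i]) {
        int z = (int)(i / ((R_xlen_t)g.nx * g.ny));
        int r = (int)(i % ((R_xlen_t)g.nx * g.ny));
        cx.push_back(r % g.nx); cy.push_back(r / g.nx); cz.push_back(z);
        ci.push_back(I[i]);
      }
  }
  int K = (int)cx.size();

  std::vector<int> lab(nvox, 0);       // 1..K, 0 = background/unassigned
  std::vector<double> dist(nvox);
  const double m2S2 = (compactness * compactness) / (S * S);
  const int win = (int)std::ceil(2.0 * S);
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < K; ++c) {
      if (!R_finite(ci[c])) continue;  // dead cluster
      const int x0 = std::max(0, (int)std::floor(cx[c]) - win);
      const int x1 = std::min(g.nx - 1, (int)std::floor(cx[c]) + win);
      const int y0 = std::max(0, (int)std::floor(cy[c]) - win);
      const int y1 = std::min(g.ny - 1, (int)std::floor(cy[c]) + win);
      const int z0 = std::max(0, (int)std::floor(cz[c]) - win);
      const int z1 = std::min(g.nz - 1, (int)std::floor(cz[c]) + win);
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y)
          for (int x = x0; x <= x1; ++x) {
            const R_xlen_t i = g.idx(x, y, z);
            if (!M[i]) continue;
            const double di = I[i] - ci[c];
            const double dx = x - cx[c], dy = y - cy[c], dz = z - cz[c];
            const double D2 = di * di + (dx * dx + dy * dy + dz * dz) * m2S2;
            if (D2 < dist[i]) { dist[i] = D2; lab[i] = c + 1; }
          }
    }
    // voxels outside every window: nearest center spatially
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          const R_xlen_t i = g.idx(x, y, z);
          if (!M[i] || R_finite(dist[i])) continue;
          double bd = R_PosInf; int bc = 1;
          for (int c = 0; c < K; ++c) {
            if (!R_finite(ci[c])) continue;
            double dx = x - cx[c], dy = y - cy[c], dz = z - cz[c];
            double d = dx * dx + dy * dy + dz * dz;
            if (d < bd) { bd = d; bc = c + 1; }
          }
          lab[i] = bc;
        }
    // update centers
    std::vector<double> sx(K, 0), sy(K, 0), sz(K, 0), si(K, 0), sn(K, 0);
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          const R_xlen_t i = g.idx(x, y, z);
          if (!M[i]) continue;
          const int c = lab[i] - 1;
          sx[c] += x; sy[c] += y; sz[c] += z; si[c] += I[i]; sn[c] += 1.0;
        }
    double shift = 0.0;
    for (int c = 0; c < K; ++c) {
      if (sn[c] == 0) { ci[c] = R_PosInf; continue; }  // lost all voxels
      double nxp = sx[c] / sn[c], nyp = sy[c] / sn[c], nzp = sz[c] / sn[c];
      shift += std::fabs(nxp - cx[c]) + std::fabs(nyp - cy[c]) +
               std::fabs(nzp - cz[c]);
      cx[c] = nxp; cy[c] = nyp; cz[c] = nzp; ci[c] = si[c] / sn[c];
    }
    if (shift < 1e-9) break;  // assignments can no longer change
  }

  IntegerVector labels(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) labels[i] = lab[i];
  return List::create(_["labels"] = labels, _["n_centers"] = K,
                      _["n_iter"] = std::min(iter, max_iter),
                      _["S"] = S);
}

// connected components (26-neighbourhood) of equal-label in-mask voxels;
// returns 1-based component ids, 0 outside the mask
// [[Rcpp::export]]
IntegerVector cpp_components26(IntegerVector labels, IntegerVector dim) {
  Grid g{dim[0], dim[1], dim[2]};
  const R_xlen_t nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  IntegerVector comp(nvox, 0);
  int nc = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (labels[s] == 0 || comp[s] != 0) continue;
    const int L = labels[s];
    ++nc;
    comp[s] = nc;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      int z = (int)(i / ((R_xlen_t)g.nx * g.ny));
      R_xlen_t r = i % ((R_xlen_t)g.nx * g.ny);
      int y = (int)(r / g.nx), x = (int)(r % g.nx);
      for (int k = 0; k < 26; ++k) {
        int xx = x + NB26[k][0], yy = y + NB26[k][1], zz = z + NB26[k][2];
        if (!g.in(xx, yy, zz)) continue;
        R_xlen_t j = g.idx(xx, yy, zz);
        if (labels[j] == L && comp[j] == 0) { comp[j] = nc; stack.push_back(j); }
      }
    }
  }
  return comp;
}

// keep, per label, its largest 26-connected component; absorb every other
// ("orphan") component into the adjacent kept label with the largest
// boundary contact (ties: lower label id); isolated islands keep their label
// [[Rcpp::export]]
IntegerVector cpp_enforce_connectivity(IntegerVector labels, IntegerVector dim) {
  Grid g{dim[0], dim[1], dim[2]};
  const R_xlen_t nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  IntegerVector comp = cpp_components26(labels, dim);
  int nc = 0;
  for (R_xlen_t i = 0; i < nvox; ++i) nc = std::max(nc, (int)comp[i]);
  std::vector<R_xlen_t> csize(nc + 1, 0);
  std::vector<int> clab(nc + 1, 0);
  for (R_xlen_t i = 0; i < nvox; ++i)
    if (comp[i]) { ++csize[comp[i]]; clab[comp[i]] = labels[i]; }
  // largest component per label is kept
  std::map<int, int> keep;  // label -> component id
  for (int c = 1; c <= nc; ++c) {
    auto it = keep.find(clab[c]);
    if (it == keep.end() || csize[c] > csize[it->second] ||
        (csize[c] == csize[it->second] && c < it->second))
      keep[clab[c]] = c;
  }
  std::vector<char> kept(nc + 1, 0);
  for (auto& kv : keep) kept[kv.second] = 1;
  std::vector<int> newlab(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) newlab[i] = labels[i];
  // iterate since an orphan may initially touch only other orphans
  bool any = true;
  int guard = 0;
  while (any && ++guard <= nc + 1) {
    any = false;
    std::vector<std::map<int, R_xlen_t>> contact(nc + 1);
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          const R_xlen_t i = g.idx(x, y, z);
          const int c = comp[i];
          if (c == 0 || kept[c]) continue;
          for (int k = 0; k < 26; ++k) {
            int xx = x + NB26[k][0], yy = y + NB26[k][1], zz = z + NB26[k][2];
            if (!g.in(xx, yy, zz)) continue;
            R_xlen_t j = g.idx(xx, yy, zz);
            if (comp[j] != 0 && kept[comp[j]])
              ++contact[c][newlab[j]];
          }
        }
    std::vector<int> target(nc + 1, 0);
    for (int c = 1; c <= nc; ++c) {
      if (kept[c] || contact[c].empty()) continue;
      int best = 0; R_xlen_t bestn = 0;
      for (auto& kv : contact[c])
        if (kv.second > bestn || (kv.second == bestn && kv.first < best)) {
          best = kv.first; bestn = kv.second;
        }
      target[c] = best;
    }
    for (R_xlen_t i = 0; i < nvox; ++i) {
      const int c = comp[i];
      if (c && !kept[c] && target[c]) { newlab[i] = target[c]; any = true; }
    }
    for (int c = 1; c <= nc; ++c)
      if (!kept[c] && target[c]) kept[c] = 1;  // absorbed into a kept label
  }
  // leftover orphan components (isolated mask islands) keep their own label
  IntegerVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = newlab[i];
  return out;
}

// merge labels smaller than min_size into the 26-adjacent label with the
// closest mean reference intensity (ties: larger neighbour, then lower id)
// [[Rcpp::export]]
IntegerVector cpp_enforce_min_size(IntegerVector labels, NumericVector img,
                                   IntegerVector dim, int min_size) {
  Grid g{dim[0], dim[1], dim[2]};
  const R_xlen_t nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  int K = 0;
  for (R_xlen_t i = 0; i < nvox; ++i) K = std::max(K, (int)labels[i]);
  if (K == 0) return labels;
  std::vector<R_xlen_t> size(K + 1, 0);
  std::vector<double> sum(K + 1, 0.0);
  std::vector<std::set<int>> adj(K + 1);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        const R_xlen_t i = g.idx(x, y, z);
        const int L = labels[i];
        if (!L) continue;
        ++size[L];
        sum[L] += img[i];
        for (int k = 0; k < 26; ++k) {
          int xx = x + NB26[k][0], yy = y + NB26[k][1], zz = z + NB26[k][2];
          if (!g.in(xx, yy, zz)) continue;
          const int Ln = labels[g.idx(xx, yy, zz)];
          if (Ln && Ln != L) adj[L].insert(Ln);
        }
      }
  std::vector<int> remap(K + 1);
  for (int l = 0; l <= K; ++l) remap[l] = l;
  auto resolve = [&](int l) { while (remap[l] != l) l = remap[l]; return l; };
  R_xlen_t total = 0;
  for (int l = 1; l <= K; ++l) total += size[l];
  if (total < (R_xlen_t)min_size)
    stop("enforce_min_size: only %d in-mask voxels, cannot reach min_size %d",
         (int)total, min_size);
  while (true) {
    // smallest undersized live label (tie: lower id)
    int small = 0;
    for (int l = 1; l <= K; ++l)
      if (remap[l] == l && size[l] > 0 && size[l] < (R_xlen_t)min_size &&
          (small == 0 || size[l] < size[small])) small = l;
    if (!small) break;
    const double mu = sum[small] / size[small];
    int best = 0;
    double bestd = R_PosInf;
    for (int a0 : adj[small]) {
      int a = resolve(a0);
      if (a == small || size[a] == 0) continue;
      double d = std::fabs(sum[a] / size[a] - mu);
      if (d < bestd - 1e-15 ||
          (std::fabs(d - bestd) <= 1e-15 && best != 0 &&
           (size[a] > size[best] || (size[a] == size[best] && a < best)))) {
        bestd = d; best = a;
      }
    }
    if (!best) break;  // no live neighbour (isolated small island): leave it
    // merge small -> best
    size[best] += size[small];
    sum[best] += sum[small];
    size[small] = 0;
    for (int a0 : adj[small]) {
      int a = resolve(a0);
      if (a != best && a != small) { adj[best].insert(a); adj[a].insert(best); }
    }
    remap[small] = best;
  }
  IntegerVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i)
    out[i] = labels[i] ? resolve(labels[i]) : 0;
  return out;
}
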