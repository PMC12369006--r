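// 3D binary-image primitives used by the segmentation stage.
// Volumes are R logical/integer arrays in column-major order with
// dim = (nz, ny, nx); connectivity is 6 (faces) or 26 (faces+edges+corners).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

namespace {

struct Grid {
  int d1, d2, d3;
  Grid(const IntegerVector &dim) : d1(dim[0]), d2(dim[1]), d3(dim[2]) {}
  inline R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
  }
};

// neighbour offsets as (di, dj, dk) triplets
void neighbour_offsets(int connectivity, std::vector<std::array<int, 3>> &off) {
  off.clear();
  if (connectivity == 6) {
    off = {{{-1, 0, 0}}, {{1, 0, 0}}, {{0, -1, 0}}, {{0, 1, 0}}, {{0, 0, -1}}, {{0, 0, 1}}};
  } else {
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk)
          if (di || dj || dk) off.push_back({{di, dj, dk}});
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);
  int next_label = 0;
  std::queue<std::array<int, 3>> q;
  for (int k = 0; k < g.d3; ++k)
    for (int j = 0; j < g.d2; ++j)
      for (int i = 0; i < g.d1; ++i) {
        R_xlen_t p = g.idx(i, j, k);
        if (mask[p] != TRUE || labels[p] != 0) continue;
        labels[p] = ++next_label;
        q.push({{i, j, k}});
        while (!q.empty()) {
          std::array<int, 3> c = q.front();
          q.pop();
          for (const auto &o : off) {
            int ni = c[0] + o[0], nj = c[1] + o[1], nk = c[2] + o[2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= g.d1 || nj >= g.d2 || nk >= g.d3) continue;
            R_xlen_t np = g.idx(ni, nj, nk);
            if (mask[np] == TRUE && labels[np] == 0) {
              labels[np] = next_label;
              q.push({{ni, nj, nk}});
            }
          }
        }
      }
  labels.attr("dim") = dim;
  return labels;
}

// Fill cavities: background voxels not 6-connected to the array border
// become foreground.
// [[Rcpp::export(name = ".cpp_fill_holes")]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = mask.size();
  std::vector<char> outside(n, 0);
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(6, off);
  std::queue<std::array<int, 3>> q;
  auto seed = [&](int i, int j, int k) {
    R_xlen_t p = g.idx(i, j, k);
    if (mask[p] != TRUE && !outside[p]) {
      outside[p] = 1;
      q.push({{i, j, k}});
    }
  };
  for (int j = 0; j < g.d2; ++j)
    for (int i = 0; i < g.d1; ++i) { seed(i, j, 0); seed(i, j, g.d3 - 1); }
  for (int k = 0; k < g.d3; ++k)
    for (int i = 0; i < g.d1; ++i) { seed(i, 0, k); seed(i, g.d2 - 1, k); }
  for (int k = 0; k < g.d3; ++k)
    for (int j = 0; j < g.d2; ++j) { seed(0, j, k); seed(g.d1 - 1, j, k); }
  while (!q.empty()) {
    std::array<int, 3> c = q.front();
    q.pop();
    for (const auto &o : off) {
      int ni = c[0] + o[0], nj = c[1] + o[1], nk = c[2] + o[2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= g.d1 || nj >= g.d2 || nk >= g.d3) continue;
      R_xlen_t np = g.idx(ni, nj, nk);
      if (mask[np] != TRUE && !outside[np]) {
        outside[np] = 1;
        q.push({{ni, nj, nk}});
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) out[p] = (mask[p] == TRUE) || !outside[p];
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".cpp_dilate")]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, int connectivity, int iter) {
  Grid g(dim);
  R_xlen_t n = mask.size();
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t p = 0; p < n; ++p) cur[p] = (mask[p] == TRUE);
  for (int it = 0; it < iter; ++it) {
    nxt = cur;
    for (int k = 0; k < g.d3; ++k)
      for (int j = 0; j < g.d2; ++j)
        for (int i = 0; i < g.d1; ++i) {
          R_xlen_t p = g.idx(i, j, k);
          if (cur[p]) continue;
          for (const auto &o : off) {
            int ni = i + o[0], nj = j + o[1], nk = k + o[2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= g.d1 || nj >= g.d2 || nk >= g.d3) continue;
            if (cur[g.idx(ni, nj, nk)]) { nxt[p] = 1; break; }
          }
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) out[p] = (cur[p] != 0);
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".cpp_erode")]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim, int connectivity, int iter) {
  Grid g(dim);
  R_xlen_t n = mask.size();
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t p = 0; p < n; ++p) cur[p] = (mask[p] == TRUE);
  for (int it = 0; it < iter; ++it) {
    nxt = cur;
    for (int k = 0; k < g.d3; ++k)
      for (int j = 0; j < g.d2; ++j)
        for (int i = 0; i < g.d1; ++i) {
          R_xlen_t p = g.idx(i, j, k);
          if (!cur[p]) continue;
          for (const auto &o : off) {
            int ni = i + o[0], nj = j + o[1], nk = k + o[2];
            // voxels outside the array count as background
            if (ni < 0 || nj < 0 || nk < 0 || ni >= g.d1 || nj >= g.d2 || nk >= g.d3 ||
                !cur[g.idx(ni, nj, nk)]) {
              nxt[p] = 0;
              break;
            }
          }
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) out[p] = (cur[p] != 0);
  out.attr("dim") = dim;
  return out;
}

// Count exposed voxel faces (6-neighbourhood); used for the surface-area
// estimate behind sphericity.
// [[Rcpp::export(name = ".cpp_exposed_faces")]]
double cpp_exposed_faces(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  double faces = 0.0;
  for (int k = 0; k < g.d3; ++k)
    for (int j = 0; j < g.d2; ++j)
      for (int i = 0; i < g.d1; ++i) {
        if (mask[g.idx(i, j, k)] != TRUE) continue;
        const int di[6] = {-1, 1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, -1, 1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, -1, 1};
        for (int m = 0; m < 6; ++m) {
          int ni = i + di[m], nj = j + dj[m], nk = k + dk[m];
          if (ni < 0 || nj < 0 || nk < 0 || ni >= g.d1 || nj >= g.d2 || nk >= g.d3 ||
              mask[g.idx(ni, nj, nk)] != TRUE)
            faces += 1.0;
        }
      }
  return faces;
}
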