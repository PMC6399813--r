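#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Shared helpers for 2D [Y,X] / 3D [Y,X,Z] grids stored column-major.

struct Grid {
  int ny, nx, nz;
  R_xlen_t sy, sx, sz, n;
  Grid(IntegerVector dm) {
    ny = dm[0]; nx = dm[1]; nz = (dm.size() > 2) ? dm[2] : 1;
    sy = 1; sx = ny; sz = (R_xlen_t)ny * nx;
    n = (R_xlen_t)ny * nx * nz;
  }
  void coords(R_xlen_t p, int &i, int &j, int &k) const {
    k = (int)(p / sz);
    R_xlen_t r = p % sz;
    j = (int)(r / sx);
    i = (int)(r % sx);
  }
};

// neighbour coordinate deltas for a connectivity code:
// 2D: 4 or 8; 3D: 6 or 26
static std::vector<std::array<int, 3>> neigh_deltas(int nz, int conn) {
  std::vector<std::array<int, 3>> d;
  if (nz == 1) {
    if (conn == 4) {
      d = {{{-1, 0, 0}}, {{1, 0, 0}}, {{0, -1, 0}}, {{0, 1, 0}}};
    } else {
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          if (di || dj) d.push_back({{di, dj, 0}});
    }
  } else {
    if (conn == 6) {
      d = {{{-1, 0, 0}}, {{1, 0, 0}}, {{0, -1, 0}},
           {{0, 1, 0}},  {{0, 0, -1}}, {{0, 0, 1}}};
    } else {
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          for (int dk = -1; dk <= 1; ++dk)
            if (di || dj || dk) d.push_back({{di, dj, dk}});
    }
  }
  return d;
}

// Morphological reconstruction by dilation (hybrid raster + FIFO algorithm).
// marker <= mask pointwise; returns the reconstruction.
// [[Rcpp::export]]
NumericVector morpho_reconstruct_dilate(NumericVector marker, NumericVector mask,
                                        int conn) {
  IntegerVector dm = marker.attr("dim");
  Grid g(dm);
  NumericVector J = clone(marker);
  std::vector<std::array<int, 3>> nb = neigh_deltas(g.nz, conn);
  // split neighbourhood into scan-order halves
  std::vector<std::array<int, 3>> nminus, nplus;
  for (auto &d : nb) {
    // raster order: k, then j, then i (matches linear index order)
    if (d[2] < 0 || (d[2] == 0 && (d[1] < 0 || (d[1] == 0 && d[0] < 0))))
      nminus.push_back(d);
    else
      nplus.push_back(d);
  }
  auto at = [&](int i, int j, int k) { return i + j * g.sx + k * g.sz; };
  // forward pass
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.nx; ++j)
      for (int i = 0; i < g.ny; ++i) {
        R_xlen_t p = at(i, j, k);
        double m = J[p];
        for (auto &d : nminus) {
          int ii = i + d[0], jj = j + d[1], kk = k + d[2];
          if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
            continue;
          double v = J[at(ii, jj, kk)];
          if (v > m) m = v;
        }
        J[p] = std::min(m, mask[p]);
      }
  // backward pass + queue init
  std::queue<R_xlen_t> fifo;
  for (int k = g.nz - 1; k >= 0; --k)
    for (int j = g.nx - 1; j >= 0; --j)
      for (int i = g.ny - 1; i >= 0; --i) {
        R_xlen_t p = at(i, j, k);
        double m = J[p];
        for (auto &d : nplus) {
          int ii = i + d[0], jj = j + d[1], kk = k + d[2];
          if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
            continue;
          double v = J[at(ii, jj, kk)];
          if (v > m) m = v;
        }
        J[p] = std::min(m, mask[p]);
        for (auto &d : nplus) {
          int ii = i + d[0], jj = j + d[1], kk = k + d[2];
          if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
            continue;
          R_xlen_t q = at(ii, jj, kk);
          if (J[q] < J[p] && J[q] < mask[q]) {
            fifo.push(p);
            break;
          }
        }
      }
  // propagation
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front();
    fifo.pop();
    int i, j, k;
    g.coords(p, i, j, k);
    for (auto &d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
        continue;
      R_xlen_t q = at(ii, jj, kk);
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dm;
  return J;
}

// Label the regional minima plateaus of an image: connected plateaus of equal
// value none of whose neighbours is lower.  Returns integer labels 1..K in
// first-encounter (row-major within slice, slice-major) order, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector regional_minima_labels(NumericVector img, int conn) {
  IntegerVector dm = img.attr("dim");
  Grid g(dm);
  std::vector<std::array<int, 3>> nb = neigh_deltas(g.nz, conn);
  IntegerVector lab(g.n);
  std::vector<signed char> state(g.n, 0);  // 0 unvisited, 1 visited
  auto at = [&](int i, int j, int k) { return i + j * g.sx + k * g.sz; };
  int next = 0;
  std::vector<R_xlen_t> plateau;
  std::queue<R_xlen_t> bfs;
  for (R_xlen_t p0 = 0; p0 < g.n; ++p0) {
    if (state[p0]) continue;
    double v = img[p0];
    bool is_min = true;
    plateau.clear();
    bfs.push(p0);
    state[p0] = 1;
    while (!bfs.empty()) {
      R_xlen_t p = bfs.front();
      bfs.pop();
      plateau.push_back(p);
      int i, j, k;
      g.coords(p, i, j, k);
      for (auto &d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
          continue;
        R_xlen_t q = at(ii, jj, kk);
        if (img[q] == v) {
          if (!state[q]) {
            state[q] = 1;
            bfs.push(q);
          }
        } else if (img[q] < v) {
          is_min = false;
        }
      }
    }
    if (is_min) {
      ++next;
      for (R_xlen_t p : plateau) lab[p] = next;
    }
  }
  lab.attr("dim") = dm;
  return lab;
}

// Meyer-style marker-controlled watershed with watershed lines.
// relief: flooding surface; markers: 0 / 1..K seed labels; floodable:
// 1 = inside the flooding domain.  Output: 0 outside the domain,
// 1 on watershed lines, 2..K+1 for basins of markers 1..K.
// [[Rcpp::export]]
IntegerVector watershed_flood(NumericVector relief, IntegerVector markers,
                              IntegerVector floodable, int conn) {
  IntegerVector dm = relief.attr("dim");
  Grid g(dm);
  std::vector<std::array<int, 3>> nb = neigh_deltas(g.nz, conn);
  IntegerVector out(g.n);
  std::vector<char> queued(g.n, 0);
  auto at = [&](int i, int j, int k) { return i + j * g.sx + k * g.sz; };

  typedef std::tuple<double, unsigned long long, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  unsigned long long cnt = 0;

  for (R_xlen_t p = 0; p < g.n; ++p)
    if (floodable[p] && markers[p] > 0) out[p] = markers[p] + 1;

  for (R_xlen_t p = 0; p < g.n; ++p) {
    if (out[p] < 2) continue;
    int i, j, k;
    g.coords(p, i, j, k);
    for (auto &d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
        continue;
      R_xlen_t q = at(ii, jj, kk);
      if (floodable[q] && out[q] == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push(QE(relief[q], cnt++, q));
      }
    }
  }

  while (!pq.empty()) {
    R_xlen_t p = std::get<2>(pq.top());
    pq.pop();
    if (out[p] != 0) continue;
    int i, j, k;
    g.coords(p, i, j, k);
    int lab = 0;
    bool conflict = false;
    for (auto &d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
        continue;
      int v = out[at(ii, jj, kk)];
      if (v >= 2) {
        if (lab == 0)
          lab = v;
        else if (lab != v)
          conflict = true;
      }
    }
    out[p] = conflict ? 1 : (lab > 0 ? lab : 1);
    for (auto &d : nb) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
        continue;
      R_xlen_t q = at(ii, jj, kk);
      if (floodable[q] && out[q] == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push(QE(relief[q], cnt++, q));
      }
    }
  }
  out.attr("dim") = dm;
  return out;
}

// Connected-component labelling (used for marker handling and the
// thin-line partition checks).  Returns labels 1..K, 0 where input is 0.
// [[Rcpp::export]]
IntegerVector label_components(IntegerVector fg, int conn) {
  IntegerVector dm = fg.attr("dim");
  Grid g(dm);
  std::vector<std::array<int, 3>> nb = neigh_deltas(g.nz, conn);
  IntegerVector lab(g.n);
  auto at = [&](int i, int j, int k) { return i + j * g.sx + k * g.sz; };
  int next = 0;
  std::queue<R_xlen_t> bfs;
  for (R_xlen_t p0 = 0; p0 < g.n; ++p0) {
    if (!fg[p0] || lab[p0]) continue;
    ++next;
    lab[p0] = next;
    bfs.push(p0);
    while (!bfs.empty()) {
      R_xlen_t p = bfs.front();
      bfs.pop();
      int i, j, k;
      g.coords(p, i, j, k);
      for (auto &d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= g.ny || jj < 0 || jj >= g.nx || kk < 0 || kk >= g.nz)
          continue;
        R_xlen_t q = at(ii, jj, kk);
        if (fg[q] && !lab[q]) {
          lab[q] = next;
          bfs.push(q);
        }
      }
    }
  }
  lab.attr("dim") = dm;
  return lab;
}
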