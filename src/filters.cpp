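#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Median filter with a square (2r+1)^2 window, edge pixels use the clipped
// window.  Exact (no histogram quantisation); meant for z-maps, not large
// photographic images.
// [[Rcpp::export]]
NumericMatrix median_filter_2d(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> w;
  w.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < nc; ++j) {
    int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      w.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) w.push_back(img(ii, jj));
      size_t m = w.size() / 2;
      std::nth_element(w.begin(), w.begin() + m, w.end());
      double med = w[m];
      if (w.size() % 2 == 0) {
        std::nth_element(w.begin(), w.begin() + m - 1, w.begin() + m);
        med = 0.5 * (med + w[m - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Mean filter with a square window (clipped at edges).
// [[Rcpp::export]]
NumericMatrix mean_filter_2d(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      double s = 0;
      int n = 0;
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) {
          s += img(ii, jj);
          ++n;
        }
      out(i, j) = s / n;
    }
  }
  return out;
}

// Fill invalid pixels with the value of the nearest valid pixel
// (Euclidean distance, multi-source Dijkstra propagating seed coordinates).
// [[Rcpp::export]]
NumericMatrix fill_nearest_2d(NumericMatrix values, LogicalMatrix valid) {
  int nr = values.nrow(), nc = values.ncol();
  NumericMatrix out = clone(values);
  std::vector<double> best(static_cast<size_t>(nr) * nc, R_PosInf);
  std::vector<int> seed_i(static_cast<size_t>(nr) * nc, -1),
      seed_j(static_cast<size_t>(nr) * nc, -1);
  typedef std::tuple<double, int, int> QE;  // dist, i, j
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (valid(i, j)) {
        size_t p = i + static_cast<size_t>(j) * nr;
        best[p] = 0;
        seed_i[p] = i;
        seed_j[p] = j;
        pq.push(QE(0.0, i, j));
      }
  if (pq.empty()) stop("no valid pixels to fill from");
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    double d = std::get<0>(top);
    int i = std::get<1>(top), j = std::get<2>(top);
    size_t p = i + static_cast<size_t>(j) * nr;
    if (d > best[p]) continue;
    for (int t = 0; t < 8; ++t) {
      int ii = i + di[t], jj = j + dj[t];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      size_t q = ii + static_cast<size_t>(jj) * nr;
      double dy = ii - seed_i[p], dx = jj - seed_j[p];
      double nd = std::sqrt(dy * dy + dx * dx);
      if (nd < best[q]) {
        best[q] = nd;
        seed_i[q] = seed_i[p];
        seed_j[q] = seed_j[p];
        out(ii, jj) = values(seed_i[p], seed_j[p]);
        pq.push(QE(nd, ii, jj));
      }
    }
  }
  return out;
}
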