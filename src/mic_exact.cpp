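#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive maximal-information search, independent of the approximate
// code path: enumerate every axis partition that respects value ties
// (cuts only between distinct values), for every grid size pair
// (qx, qy) with qx, qy >= 2 and qx * qy <= B, and evaluate the
// normalized mutual information directly from the cell counts.
// Feasible only for small n and small B; used as the oracle.

static inline double xlog2e(double p) { return (p > 0.0) ? p * std::log2(p) : 0.0; }

// run index (distinct sorted value group) per observation
static std::vector<int> runIndex(const NumericVector& v, int& nruns) {
  int n = v.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  std::vector<int> run(n);
  int r = 0;
  run[idx[0]] = 0;
  for (int i = 1; i < n; ++i) {
    if (v[idx[i]] != v[idx[i - 1]]) ++r;
    run[idx[i]] = r;
  }
  nruns = r + 1;
  return run;
}

// [[Rcpp::export(name = ".micExactCpp")]]
double micExactCpp(NumericVector x, NumericVector y, double alpha) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  if (n > 50) stop("exact mode is limited to n <= 50");
  int B = std::max((int)std::floor(std::pow((double)n, alpha)), 4);
  if (B > 16) stop("exact mode is limited to B <= 16");

  int kx, ky;
  std::vector<int> rx = runIndex(x, kx);
  std::vector<int> ry = runIndex(y, ky);
  // run-level joint counts
  std::vector<double> runCnt((size_t)kx * ky, 0.0);
  for (int i = 0; i < n; ++i) runCnt[(size_t)rx[i] * ky + ry[i]] += 1.0;

  double best = 0.0;
  for (int qx = 2; qx <= B / 2; ++qx) {
    if (qx > kx) break;
    for (int qy = 2; qx * qy <= B; ++qy) {
      if (qy > ky) break;
      double lognorm = std::log2((double)std::min(qx, qy));
      // enumerate x-cut combinations: qx-1 cut positions among kx-1 boundaries
      std::vector<int> xc(qx - 1);
      for (int i = 0; i < qx - 1; ++i) xc[i] = i;
      bool moreX = true;
      std::vector<double> A((size_t)qx * ky);
      std::vector<double> M((size_t)qx * qy);
      std::vector<double> mx(qx), my(qy);
      while (moreX) {
        // A[b][j] = count of points with x-bin b and y-run j
        std::fill(A.begin(), A.end(), 0.0);
        {
          int b = 0;
          for (int r = 0; r < kx; ++r) {
            while (b < qx - 1 && r > xc[b]) ++b;
            for (int j = 0; j < ky; ++j)
              A[(size_t)b * ky + j] += runCnt[(size_t)r * ky + j];
          }
        }
        // enumerate y-cut combinations
        std::vector<int> yc(qy - 1);
        for (int i = 0; i < qy - 1; ++i) yc[i] = i;
        bool moreY = true;
        while (moreY) {
          std::fill(M.begin(), M.end(), 0.0);
          {
            int b = 0;
            for (int j = 0; j < ky; ++j) {
              while (b < qy - 1 && j > yc[b]) ++b;
              for (int a = 0; a < qx; ++a)
                M[(size_t)a * qy + b] += A[(size_t)a * ky + j];
            }
          }
          std::fill(mx.begin(), mx.end(), 0.0);
          std::fill(my.begin(), my.end(), 0.0);
          for (int a = 0; a < qx; ++a)
            for (int b = 0; b < qy; ++b) {
              mx[a] += M[(size_t)a * qy + b];
              my[b] += M[(size_t)a * qy + b];
            }
          double mi = 0.0;
          for (int a = 0; a < qx; ++a)
            for (int b = 0; b < qy; ++b) {
              double p = M[(size_t)a * qy + b] / n;
              if (p > 0.0)
                mi += p * std::log2(p / ((mx[a] / n) * (my[b] / n)));
            }
          double v = mi / lognorm;
          if (v > best) best = v;
          // next y combination
          int i = qy - 2;
          while (i >= 0 && yc[i] == ky - 1 - (qy - 1 - i)) --i;
          if (i < 0) {
            moreY = false;
          } else {
            ++yc[i];
            for (int j = i + 1; j < qy - 1; ++j) yc[j] = yc[j - 1] + 1;
          }
        }
        // next x combination
        int i = qx - 2;
        while (i >= 0 && xc[i] == kx - 1 - (qx - 1 - i)) --i;
        if (i < 0) {
          moreX = false;
        } else {
          ++xc[i];
          for (int j = i + 1; j < qx - 1; ++j) xc[j] = xc[j - 1] + 1;
        }
      }
    }
  }
  if (best > 1.0) best = 1.0;
  return best;
}
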