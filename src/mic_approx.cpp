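#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// p * log2(p), with 0 log 0 = 0
static inline double xlog2(double p) { return (p > 0.0) ? p * std::log2(p) : 0.0; }

static std::vector<int> orderOf(const std::vector<double>& v) {
  std::vector<int> idx(v.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// Partition sorted values into at most q roughly equal bins; tied values are
// never split across bins.  Returns the bin id of each sorted position.
static std::vector<int> equipartition(const std::vector<double>& sorted, int q,
                                      int& nbins) {
  int n = (int)sorted.size();
  std::vector<int> bin(n);
  int i = 0, s = 0, placed = 0, p = 0;
  double desired = (double)n / q;
  while (p < n) {
    int t = 1;
    while (p + t < n && sorted[p + t] == sorted[p]) ++t;
    if (s != 0 && i < q - 1 &&
        std::fabs(s + t - desired) >= std::fabs(s - desired)) {
      ++i;
      s = 0;
      desired = (double)(n - placed) / (q - i);
    }
    for (int u = 0; u < t; ++u) bin[p + u] = i;
    s += t;
    placed += t;
    p += t;
  }
  nbins = i + 1;
  return bin;
}

// Clump end positions for points sorted by the optimized axis: tied values
// stay together, and adjacent runs lying entirely in one and the same
// fixed-axis bin are merged (an optimal partition never cuts inside either).
static std::vector<int> clumpCuts(const std::vector<double>& ov,
                                  const std::vector<int>& qb) {
  int n = (int)ov.size();
  std::vector<int> cuts;
  int prevQ = -2;
  int p = 0;
  while (p < n) {
    int t = p + 1, q0 = qb[p];
    bool pure = true;
    while (t < n && ov[t] == ov[p]) {
      if (qb[t] != q0) pure = false;
      ++t;
    }
    int runQ = pure ? q0 : -1;
    if (!cuts.empty() && runQ >= 0 && runQ == prevQ)
      cuts.back() = t;
    else
      cuts.push_back(t);
    prevQ = runQ;
    p = t;
  }
  return cuts;
}

// Reduce candidate cuts to at most cmax, greedily keeping roughly
// equal-count superclumps; the final cut (== n) is always retained.
static std::vector<int> superclump(const std::vector<int>& cuts, int n,
                                   int cmax) {
  std::vector<int> out;
  double target = (double)n / cmax;
  double next = target;
  for (size_t i = 0; i < cuts.size(); ++i) {
    bool last = (i + 1 == cuts.size());
    if (last || (double)cuts[i] >= next - 1e-9) {
      out.push_back(cuts[i]);
      next = (double)cuts[i] + target;
    }
  }
  return out;
}

struct DpResult {
  // per l (1-based index l-1): mutual information in bits, and the bin id of
  // every point in ORIGINAL index order (empty when l is infeasible)
  std::vector<double> I;
  std::vector<std::vector<int>> part;
};

// Exact DP over clump cut positions on the optimized axis, given a fixed
// binning of the other axis:
// I(P;Q) = H(Q) + sum over P-bins of [ -(m/n)log2(m/n) + sum_j (m_j/n)log2(m_j/n) ],
// additive over bins, so interval DP with traceback applies.
//   oVals: optimized-axis values (original order); fbin: fixed-axis bin per
//   point (original order), q bins; maxl: max bins on the optimized axis.
static DpResult dpOptimize(const std::vector<double>& oVals,
                           const std::vector<int>& fbin, int q, int maxl,
                           int clump) {
  int n = (int)oVals.size();
  std::vector<int> ord = orderOf(oVals);
  std::vector<double> ov(n);
  std::vector<int> qb(n);
  for (int i = 0; i < n; ++i) {
    ov[i] = oVals[ord[i]];
    qb[i] = fbin[ord[i]];
  }
  std::vector<int> cuts = clumpCuts(ov, qb);
  int cmax = std::max(1, clump * maxl);
  if ((int)cuts.size() > cmax) cuts = superclump(cuts, n, cmax);
  int k = (int)cuts.size();

  std::vector<double> cum((size_t)(k + 1) * q, 0.0);
  {
    int pos = 0;
    for (int t = 1; t <= k; ++t) {
      for (int j = 0; j < q; ++j)
        cum[(size_t)t * q + j] = cum[(size_t)(t - 1) * q + j];
      for (; pos < cuts[t - 1]; ++pos) cum[(size_t)t * q + qb[pos]] += 1.0;
    }
  }
  std::vector<int> end(k + 1, 0);
  for (int t = 1; t <= k; ++t) end[t] = cuts[t - 1];
  double HQ = 0.0;
  for (int j = 0; j < q; ++j) HQ -= xlog2(cum[(size_t)k * q + j] / n);

  // per-bin contribution g(s, t) for clumps (s, t]
  std::vector<double> G((size_t)(k + 1) * (k + 1), 0.0);
  for (int s = 0; s < k; ++s)
    for (int t = s + 1; t <= k; ++t) {
      double m = (double)(end[t] - end[s]);
      double val = -xlog2(m / n);
      for (int j = 0; j < q; ++j)
        val += xlog2((cum[(size_t)t * q + j] - cum[(size_t)s * q + j]) / n);
      G[(size_t)s * (k + 1) + t] = val;
    }

  int lmax = std::min(maxl, k);
  DpResult res;
  res.I.assign(maxl, R_NegInf);
  res.part.assign(maxl, std::vector<int>());
  // best[l][t], back[l][t]
  std::vector<std::vector<double>> best(lmax + 1,
                                        std::vector<double>(k + 1, R_NegInf));
  std::vector<std::vector<int>> back(lmax + 1, std::vector<int>(k + 1, -1));
  for (int t = 1; t <= k; ++t) best[1][t] = G[t];
  for (int l = 2; l <= lmax; ++l)
    for (int t = l; t <= k; ++t) {
      double b = R_NegInf;
      int arg = -1;
      for (int s = l - 1; s < t; ++s) {
        double v = best[l - 1][s] + G[(size_t)s * (k + 1) + t];
        if (v > b) { b = v; arg = s; }
      }
      best[l][t] = b;
      back[l][t] = arg;
    }
  for (int l = 1; l <= lmax; ++l) {
    if (!std::isfinite(best[l][k])) continue;
    res.I[l - 1] = best[l][k] + HQ;
    // traceback to bin assignment in original order
    std::vector<int> bounds;  // clump indices of bin ends, reversed
    int t = k;
    for (int ll = l; ll >= 1; --ll) {
      bounds.push_back(t);
      t = (ll > 1) ? back[ll][t] : 0;
    }
    std::reverse(bounds.begin(), bounds.end());
    std::vector<int> binSorted(n);
    int b = 0, pos = 0;
    for (int bi = 0; bi < (int)bounds.size(); ++bi) {
      for (; pos < end[bounds[bi]]; ++pos) binSorted[pos] = b;
      ++b;
    }
    std::vector<int> binOrig(n);
    for (int i = 0; i < n; ++i) binOrig[ord[i]] = binSorted[i];
    res.part[l - 1] = binOrig;
  }
  return res;
}

static inline double chooseApprox(int n, int k) {
  if (k < 0 || k > n) return 0.0;
  double r = 1.0;
  for (int i = 1; i <= k; ++i) r = r * (n - k + i) / i;
  return r;
}

// Approximate maximal information coefficient.  Grid budget
// B = max(floor(n^alpha), 4).  For each orientation and each bin count q on
// the fixed axis: when enumerating every admissible q-bin partition of that
// axis fits the work budget, all of them are tried (the other axis is then
// optimized exactly by dynamic programming, so those grid sizes are searched
// exhaustively); otherwise the fixed axis is equipartitioned and the DP
// solution seeds a coordinate-ascent refinement that alternately freezes one
// axis and re-optimizes the other.  Every candidate evaluated is an
// admissible grid, so the result never exceeds the exhaustive maximum.
// [[Rcpp::export(name = ".micApproxCpp")]]
double micApproxCpp(NumericVector x, NumericVector y, double alpha,
                    int clump, int maxIter = 6, double workBudget = 5e7) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  int B = std::max((int)std::floor(std::pow((double)n, alpha)), 4);
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double best = 0.0;
  for (int orient = 0; orient < 2; ++orient) {
    const std::vector<double>& f0 = (orient == 0) ? yv : xv;
    const std::vector<double>& oAxis = (orient == 0) ? xv : yv;
    for (int q = 2; 2 * q <= B; ++q) {
      std::vector<int> fOrd = orderOf(f0);
      std::vector<double> fSorted(n);
      for (int i = 0; i < n; ++i) fSorted[i] = f0[fOrd[i]];
      // distinct-value runs of the fixed axis (candidate cut boundaries)
      std::vector<int> runOfSorted(n);
      int kf = 0;
      runOfSorted[0] = 0;
      for (int i = 1; i < n; ++i) {
        if (fSorted[i] != fSorted[i - 1]) ++kf;
        runOfSorted[i] = kf;
      }
      ++kf;  // number of runs
      int maxlQ = B / q;
      double nCombos = chooseApprox(kf - 1, q - 1);
      double work = nCombos * (double)n * n * maxlQ;
      if (q <= kf && nCombos >= 1.0 && work <= workBudget && maxlQ >= 2) {
        // exhaustive over all q-bin partitions of the fixed axis
        std::vector<int> cutc(q - 1);
        for (int i = 0; i < q - 1; ++i) cutc[i] = i;
        bool more = true;
        std::vector<int> fbinE(n);
        while (more) {
          for (int i = 0; i < n; ++i) {
            int r = runOfSorted[i];
            int b = 0;
            while (b < q - 1 && r > cutc[b]) ++b;
            fbinE[fOrd[i]] = b;
          }
          DpResult r = dpOptimize(oAxis, fbinE, q, maxlQ, clump);
          for (int l = 2; l <= maxlQ; ++l) {
            if (!std::isfinite(r.I[l - 1])) continue;
            double v = r.I[l - 1] / std::log2((double)std::min(l, q));
            if (v > best) best = v;
          }
          int i = q - 2;
          while (i >= 0 && cutc[i] == kf - 1 - (q - 1 - i)) --i;
          if (i < 0) {
            more = false;
          } else {
            ++cutc[i];
            for (int j = i + 1; j < q - 1; ++j) cutc[j] = cutc[j - 1] + 1;
          }
        }
        continue;
      }
      // heuristic branch: equipartition the fixed axis into q bins
      int nb;
      std::vector<int> binSorted = equipartition(fSorted, q, nb);
      std::vector<int> fbin(n);
      for (int i = 0; i < n; ++i) fbin[fOrd[i]] = binSorted[i];

      // first DP pass given the equipartition, then one ascent chain per
      // bin count l: alternately freeze the newly optimized partition and
      // re-optimize the other axis, while the chain keeps improving
      int maxl0 = B / nb;
      if (maxl0 < 2 || nb < 2) continue;
      const std::vector<double>& o0 = (orient == 0) ? xv : yv;
      DpResult r0 = dpOptimize(o0, fbin, nb, maxl0, clump);
      for (int l0 = 2; l0 <= maxl0; ++l0) {
        if (!std::isfinite(r0.I[l0 - 1])) continue;
        double v0 = r0.I[l0 - 1] / std::log2((double)std::min(l0, nb));
        if (v0 > best) best = v0;
        int curFixed = 1 - orient;  // the freshly optimized axis is frozen
        std::vector<int> curBins = r0.part[l0 - 1];
        int curQ = l0;
        double chainBest = v0;
        for (int iter = 0; iter < maxIter; ++iter) {
          int maxl = B / curQ;
          if (maxl < 2 || curQ < 2) break;
          const std::vector<double>& o = (curFixed == 0) ? xv : yv;
          DpResult r = dpOptimize(o, curBins, curQ, maxl, clump);
          int bestL = -1;
          double bestHere = -1.0;
          for (int l = 2; l <= maxl; ++l) {
            if (!std::isfinite(r.I[l - 1])) continue;
            double v = r.I[l - 1] / std::log2((double)std::min(l, curQ));
            if (v > bestHere) { bestHere = v; bestL = l; }
            if (v > best) best = v;
          }
          if (bestL < 0 || bestHere <= chainBest + 1e-12) break;
          chainBest = bestHere;
          curBins = r.part[bestL - 1];
          curQ = bestL;
          curFixed = 1 - curFixed;
        }
      }
    }
  }
  if (best > 1.0) best = 1.0;
  if (best < 0.0) best = 0.0;
  return best;
}
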