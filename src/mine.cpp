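// Equicharacteristic-matrix estimators MIC_e / TIC_e.
//
// For a grid dimension pair (k, l) with k*l <= B(n) = max(4, floor(n^alpha)),
// one axis is mass-equipartitioned into l bins and the other is optimised
// into at most k bins by dynamic programming over clump boundaries.  The
// entry value is the maximal normalised mutual information I / log(min(k,l))
// over the two axis orientations.  MIC_e is the maximal entry, TIC_e the sum
// of all admissible entries.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double xlogx(double c) { return c > 0.0 ? c * std::log(c) : 0.0; }

// Adaptive mass equipartition of ordered tie-blocks into l bins.
// sizes: block sizes in axis order.  Returns bin id (0-based) per block.
static std::vector<int> equipartition_blocks(const std::vector<int>& sizes, int l) {
  int nb = (int)sizes.size();
  long n = 0;
  for (int s : sizes) n += s;
  std::vector<int> bin(nb);
  int curr = 0;
  long before = 0, cnt = 0;
  for (int b = 0; b < nb; ++b) {
    double desired = (double)(n - before) / (double)(l - curr);
    if (cnt > 0 && curr < l - 1 &&
        std::fabs((double)cnt + (double)sizes[b] - desired) >
        std::fabs((double)cnt - desired)) {
      ++curr;
      before += cnt;
      cnt = 0;
    }
    bin[b] = curr;
    cnt += sizes[b];
  }
  return bin;
}

// Tie blocks of a sorted vector: sizes of runs of equal values.
static std::vector<int> tie_blocks(const std::vector<double>& sorted_vals) {
  std::vector<int> sizes;
  int n = (int)sorted_vals.size();
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && sorted_vals[j] == sorted_vals[i]) ++j;
    sizes.push_back(j - i);
    i = j;
  }
  return sizes;
}

// One orientation: axis u optimised (<= k bins), axis v equipartitioned
// (l bins).  Fills M(i, l) (1-based storage offset handled by caller) with
// the normalised value for every i = 2..kmax at every l; takes max with the
// existing matrix content.
static void fill_orientation(const std::vector<double>& u,
                             const std::vector<double>& v,
                             int B, double cfac, NumericMatrix& M) {
  const int n = (int)u.size();
  const int lmaxdim = M.ncol();  // columns indexed l-2

  // order of points by v, then tie blocks on v
  std::vector<int> ov(n);
  for (int i = 0; i < n; ++i) ov[i] = i;
  std::stable_sort(ov.begin(), ov.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  std::vector<double> vs(n);
  for (int i = 0; i < n; ++i) vs[i] = v[ov[i]];
  std::vector<int> vblocks = tie_blocks(vs);

  // order of points by u and u tie-block index per sorted position
  std::vector<int> ou(n);
  for (int i = 0; i < n; ++i) ou[i] = i;
  std::stable_sort(ou.begin(), ou.end(),
                   [&](int a, int b) { return u[a] < u[b]; });

  std::vector<int> rowv(n);  // filled per l (row id per original index)

  for (int l = 2; l <= B / 2 && l - 2 < lmaxdim; ++l) {
    int kmax = B / l;
    if (kmax < 2) break;

    // assign v-rows
    std::vector<int> vbin = equipartition_blocks(vblocks, l);
    {
      int pos = 0;
      for (size_t b = 0; b < vblocks.size(); ++b)
        for (int t = 0; t < vblocks[b]; ++t, ++pos)
          rowv[ov[pos]] = vbin[b];
    }
    // row totals and H(Q)
    std::vector<long> nq(l, 0);
    for (int i = 0; i < n; ++i) nq[rowv[i]]++;
    double sum_xlx = 0.0;
    for (int q = 0; q < l; ++q) sum_xlx += xlogx((double)nq[q]);
    const double HQ = std::log((double)n) - sum_xlx / (double)n;

    // u tie blocks with row label (common row or -1 if mixed)
    // then clumps: merge consecutive blocks sharing the same non-mixed row
    std::vector<int> csize;          // clump sizes (points)
    std::vector<std::vector<long> > chist;  // per-clump row histogram
    {
      int i = 0;
      int prev_row = -2;  // -2: nothing yet; -1: previous block mixed
      while (i < n) {
        int j = i + 1;
        while (j < n && u[ou[j]] == u[ou[i]]) ++j;
        int r = rowv[ou[i]];
        bool mixed = false;
        for (int t = i + 1; t < j; ++t)
          if (rowv[ou[t]] != r) { mixed = true; break; }
        int lab = mixed ? -1 : r;
        if (lab >= 0 && lab == prev_row) {
          // extend previous clump
          csize.back() += j - i;
          for (int t = i; t < j; ++t) chist.back()[rowv[ou[t]]]++;
        } else {
          csize.push_back(j - i);
          chist.push_back(std::vector<long>(l, 0));
          for (int t = i; t < j; ++t) chist.back()[rowv[ou[t]]]++;
        }
        prev_row = lab;
        i = j;
      }
    }
    int m = (int)csize.size();

    // superclumps: cap number of clumps at floor(cfac * kmax)
    if (R_finite(cfac)) {
      int cap = (int)std::floor(cfac * (double)kmax);
      if (cap < 2) cap = 2;
      if (m > cap) {
        std::vector<int> sbin = equipartition_blocks(csize, cap);
        std::vector<int> nsize;
        std::vector<std::vector<long> > nhist;
        for (int c = 0; c < m; ++c) {
          if (!nsize.empty() && sbin[c] == sbin[c - 1]) {
            nsize.back() += csize[c];
            for (int q = 0; q < l; ++q) nhist.back()[q] += chist[c][q];
          } else {
            nsize.push_back(csize[c]);
            nhist.push_back(chist[c]);
          }
        }
        csize.swap(nsize);
        chist.swap(nhist);
        m = (int)csize.size();
      }
    }

    // cumulative counts and histograms over clumps (index 0..m)
    std::vector<long> cum(m + 1, 0);
    std::vector<std::vector<long> > ch(m + 1, std::vector<long>(l, 0));
    for (int t = 1; t <= m; ++t) {
      cum[t] = cum[t - 1] + csize[t - 1];
      for (int q = 0; q < l; ++q) ch[t][q] = ch[t - 1][q] + chist[t - 1][q];
    }

    // W(s,t) = sum_q a_q log a_q - A log A for points in clumps s+1..t
    std::vector<std::vector<double> > W(m + 1, std::vector<double>(m + 1, 0.0));
    for (int s = 0; s <= m; ++s)
      for (int t = s + 1; t <= m; ++t) {
        double acc = 0.0;
        for (int q = 0; q < l; ++q)
          acc += xlogx((double)(ch[t][q] - ch[s][q]));
        W[s][t] = acc - xlogx((double)(cum[t] - cum[s]));
      }

    // DP over exactly-i column partitions of the clump sequence
    std::vector<double> Gprev(m + 1), Gcur(m + 1);
    for (int t = 1; t <= m; ++t) Gprev[t] = W[0][t];  // i = 1
    double running = -1.0;  // running max of normalised entry over i
    for (int i = 2; i <= kmax; ++i) {
      double val;
      if (i <= m) {
        for (int t = i; t <= m; ++t) {
          double best = R_NegInf;
          for (int s = i - 1; s <= t - 1; ++s) {
            double cand = Gprev[s] + W[s][t];
            if (cand > best) best = cand;
          }
          Gcur[t] = best;
        }
        val = HQ + Gcur[m] / (double)n;
        std::swap(Gprev, Gcur);
      } else {
        // cannot use more columns than clumps; value saturates
        val = HQ + Gprev[m] / (double)n;
      }
      if (val < 0.0) val = 0.0;
      double norm = val / std::log((double)std::min(i, l));
      if (norm > 1.0) norm = 1.0;
      if (norm > running) running = norm;
      // entry (k = i, l): grid admissible iff i * l <= B
      if ((long)i * (long)l <= (long)B && i - 2 < M.nrow()) {
        if (running > M(i - 2, l - 2)) M(i - 2, l - 2) = running;
      }
    }
  }
}

static int grid_bound(int n, double alpha) {
  int B = (int)std::floor(std::pow((double)n, alpha));
  if (B < 4) B = 4;
  return B;
}

// Returns the equicharacteristic entry matrix: rows k = 2..floor(B/2),
// cols l = 2..floor(B/2); inadmissible (k*l > B) entries are NA.
// [[Rcpp::export]]
NumericMatrix mine_matrix_cpp(NumericVector x, NumericVector y,
                              double alpha, double clump_factor) {
  int n = x.size();
  int B = grid_bound(n, alpha);
  int dim = std::max(B / 2 - 1, 1);
  NumericMatrix M(dim, dim);
  std::fill(M.begin(), M.end(), -1.0);
  std::vector<double> xs(x.begin(), x.end());
  std::vector<double> ys(y.begin(), y.end());
  fill_orientation(xs, ys, B, clump_factor, M);  // optimise x, equipartition y
  fill_orientation(ys, xs, B, clump_factor, M);  // optimise y, equipartition x
  for (int i = 0; i < dim; ++i)
    for (int j = 0; j < dim; ++j)
      if ((long)(i + 2) * (long)(j + 2) > (long)B || M(i, j) < 0.0)
        M(i, j) = NA_REAL;
  return M;
}

// [[Rcpp::export]]
List mine_stat_cpp(NumericVector x, NumericVector y,
                   double alpha, double clump_factor) {
  NumericMatrix M = mine_matrix_cpp(x, y, alpha, clump_factor);
  double mic = 0.0, tic = 0.0;
  for (int i = 0; i < M.nrow(); ++i)
    for (int j = 0; j < M.ncol(); ++j) {
      double e = M(i, j);
      if (!NumericMatrix::is_na(e)) {
        tic += e;
        if (e > mic) mic = e;
      }
    }
  return List::create(_["mic"] = mic, _["tic"] = tic,
                      _["B"] = grid_bound(x.size(), alpha));
}
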