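#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double sqdist3(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Row-major copy of an R matrix so each point is contiguous.
static std::vector<double> rowmajor(const NumericMatrix &m) {
  int n = m.nrow();
  std::vector<double> out(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    out[3 * (size_t)i]     = m(i, 0);
    out[3 * (size_t)i + 1] = m(i, 1);
    out[3 * (size_t)i + 2] = m(i, 2);
  }
  return out;
}

// For each row of A, index (1-based) and squared distance of its nearest row of B.
// Ties broken by lower index.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  std::vector<double> a = rowmajor(A), b = rowmajor(B);
  IntegerVector idx(na);
  NumericVector d2(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int bj = -1;
    const double *pi = &a[3 * (size_t)i];
    for (int j = 0; j < nb; ++j) {
      double d = sqdist3(pi, &b[3 * (size_t)j]);
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["index"] = idx, _["dist2"] = d2);
}

// k nearest neighbours of each point among the others (self excluded),
// ties broken by lower index.  Returns an N x k matrix of 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix P, int k) {
  int n = P.nrow();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of points");
  std::vector<double> p = rowmajor(P);
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    const double *pi = &p[3 * (size_t)i];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      cand[m++] = std::make_pair(sqdist3(pi, &p[3 * (size_t)j]), j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int q = 0; q < k; ++q) out(i, q) = cand[q].second + 1;
  }
  return out;
}

// Minimum spanning tree of the complete Euclidean graph, Prim's algorithm with
// on-the-fly distances (O(N^2) time, O(N) memory).  Equal-weight candidate
// edges resolve to the lowest-index pair by scan order.
// [[Rcpp::export]]
List cpp_prim_mst(NumericMatrix P) {
  int n = P.nrow();
  if (n < 1) stop("need at least one point");
  if (n == 1)
    return List::create(_["from"] = IntegerVector(0),
                        _["to"] = IntegerVector(0),
                        _["length"] = NumericVector(0));
  std::vector<double> p = rowmajor(P);
  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, -1);
  std::vector<char> used(n, 0);
  IntegerVector ef(n - 1), et(n - 1);
  NumericVector ew(n - 1);
  int cur = 0;
  used[0] = 1;
  for (int step = 0; step < n - 1; ++step) {
    const double *pc = &p[3 * (size_t)cur];
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      double d = sqdist3(pc, &p[3 * (size_t)j]);
      if (d < best[j]) { best[j] = d; from[j] = cur; }
    }
    int nxt = -1;
    double bd = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (!used[j] && best[j] < bd) { bd = best[j]; nxt = j; }
    }
    if (nxt < 0) stop("internal error: disconnected in Prim");
    int a = from[nxt], b = nxt;
    ef[step] = std::min(a, b) + 1;
    et[step] = std::max(a, b) + 1;
    ew[step] = std::sqrt(bd);
    used[nxt] = 1;
    cur = nxt;
  }
  return List::create(_["from"] = ef, _["to"] = et, _["length"] = ew);
}

// Mean distance from each point to its listed neighbours (row i of nb, 1-based),
// evaluated at positions X.  Used for the local-extent bookkeeping of the
// contraction loop.
// [[Rcpp::export]]
NumericVector cpp_neighbor_extent(NumericMatrix X, IntegerMatrix nb) {
  int n = X.nrow(), k = nb.ncol();
  std::vector<double> p = rowmajor(X);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double *pi = &p[3 * (size_t)i];
    double s = 0.0;
    for (int q = 0; q < k; ++q) {
      int j = nb(i, q) - 1;
      s += std::sqrt(sqdist3(pi, &p[3 * (size_t)j]));
    }
    out[i] = s / k;
  }
  return out;
}

// Batched branch-and-bound bound evaluation for the globally optimal ICP.
// For each candidate transform k (rows 3k..3k+2 of Rs stacked, row k of ts):
// d_i = nearest-neighbour distance of R_k s_i + t_k to T; upper bound =
// trimmed mean of d_i^2, lower bound = trimmed mean of
// max(d_i - gr_scale_k * ||s_i|| - gt_k, 0)^2.  Returns a K x 2 matrix
// (lower, upper).
// [[Rcpp::export]]
NumericMatrix cpp_goicp_bounds(NumericMatrix S, NumericMatrix Tg,
                               NumericMatrix Rs, NumericMatrix ts,
                               NumericVector gr_scale, NumericVector gt,
                               double trim) {
  int n = S.nrow(), nt = Tg.nrow(), K = ts.nrow();
  std::vector<double> s = rowmajor(S), tgt = rowmajor(Tg);
  std::vector<double> nrm(n);
  for (int i = 0; i < n; ++i) {
    const double *p = &s[3 * (size_t)i];
    nrm[i] = std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
  }
  int m = (int)std::ceil((1.0 - trim) * n);
  if (m < 1) m = 1;
  NumericMatrix out(K, 2);
  std::vector<double> d(n), lo(n), up(n);
  for (int k = 0; k < K; ++k) {
    double R00 = Rs(3 * k, 0), R01 = Rs(3 * k, 1), R02 = Rs(3 * k, 2);
    double R10 = Rs(3 * k + 1, 0), R11 = Rs(3 * k + 1, 1), R12 = Rs(3 * k + 1, 2);
    double R20 = Rs(3 * k + 2, 0), R21 = Rs(3 * k + 2, 1), R22 = Rs(3 * k + 2, 2);
    double tx = ts(k, 0), ty = ts(k, 1), tz = ts(k, 2);
    for (int i = 0; i < n; ++i) {
      const double *p = &s[3 * (size_t)i];
      double q[3];
      q[0] = R00 * p[0] + R01 * p[1] + R02 * p[2] + tx;
      q[1] = R10 * p[0] + R11 * p[1] + R12 * p[2] + ty;
      q[2] = R20 * p[0] + R21 * p[1] + R22 * p[2] + tz;
      double best = R_PosInf;
      for (int j = 0; j < nt; ++j) {
        double dd = sqdist3(q, &tgt[3 * (size_t)j]);
        if (dd < best) best = dd;
      }
      d[i] = std::sqrt(best);
      double slack = d[i] - gr_scale[k] * nrm[i] - gt[k];
      lo[i] = slack > 0 ? slack * slack : 0.0;
      up[i] = best;
    }
    std::partial_sort(lo.begin(), lo.begin() + m, lo.end());
    std::partial_sort(up.begin(), up.begin() + m, up.end());
    double slo = 0, sup = 0;
    for (int i = 0; i < m; ++i) { slo += lo[i]; sup += up[i]; }
    out(k, 0) = slo / m;
    out(k, 1) = sup / m;
  }
  return out;
}
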