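#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Spanning-tree sums over weights spanning hundreds of orders of
// magnitude. Strategy: if the "dominant" edges (within TREE_SPREAD log
// units of the maximum) connect all nodes, the minor determinant of the
// uniformly rescaled Laplacian is computed directly (neglected edges
// contribute < exp(-TREE_SPREAD) relatively); otherwise the maximum edge
// e is removed by the exact deletion-contraction identity
//   D(R) = R_e * D(R / e) + D(R - e)
// (contract e = merge its endpoints, parallel edge weights add) and the
// two branches are combined by log-sum-exp. Contraction strictly reduces
// the node count, so the recursion terminates.
static const double TREE_SPREAD = 20.0;

static double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double d = a - b;
  if (d > 37.0) return a;          // below double resolution
  if (d < -37.0) return b;
  double m = d > 0 ? a : b;
  return m + std::log1p(std::exp(-std::fabs(d)));
}

static int uf_find(std::vector<int>& up, int x) {
  while (up[x] != x) { up[x] = up[up[x]]; x = up[x]; }
  return x;
}

// do the edges with logA > cmax - TREE_SPREAD connect all l nodes?
static bool strong_connected(const std::vector<double>& logA, int l,
                             double cmax) {
  static std::vector<int> up;
  up.resize(l);
  for (int i = 0; i < l; ++i) up[i] = i;
  int ncomp = l;
  for (int i = 0; i < l && ncomp > 1; ++i)
    for (int j = i + 1; j < l; ++j)
      if (logA[i * l + j] > cmax - TREE_SPREAD) {
        int a = uf_find(up, i), b = uf_find(up, j);
        if (a != b) { up[a] = b; --ncomp; }
      }
  return ncomp == 1;
}

// direct evaluation: principal minor (row/col `drop`) of the Laplacian of
// exp(logA - cmax), LU in long double, compensation (l-1)*cmax (exact:
// every spanning tree has l-1 edges). NaN on a non-positive determinant.
// Once the dominant edges connect the graph, plain doubles suffice:
// pivots stay within TREE_SPREAD of the rescaled maximum and entries that
// underflow are provably negligible. Scratch buffers are reused across
// calls (R is single-threaded) -- this sits in the per-segment hot loop.
static double direct_tree_logdet(const std::vector<double>& logA, int l,
                                 double cmax, int drop) {
  int n = l - 1;
  static std::vector<double> W, M;
  W.assign((size_t) l * l, 0.0);
  M.assign((size_t) n * n, 0.0);
  for (int i = 0; i < l; ++i)
    for (int j = i + 1; j < l; ++j) {
      double d = logA[i * l + j];
      double w = (d == R_NegInf) ? 0.0 : std::exp(d - cmax);
      W[i * l + j] = w; W[j * l + i] = w;
    }
  for (int i = 0, ri = 0; i < l; ++i) {
    if (i == drop) continue;
    double rs = 0.0;
    for (int j = 0; j < l; ++j) rs += W[i * l + j];
    for (int j = 0, rj = 0; j < l; ++j) {
      if (j == drop) continue;
      M[ri * n + rj] = (i == j) ? rs : -W[i * l + j];
      ++rj;
    }
    ++ri;
  }
  // LU with partial pivoting on the minor
  int sign = 1;
  double logdet = 0.0;
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double amax = std::fabs(M[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(M[i * n + k]);
      if (v > amax) { amax = v; piv = i; }
    }
    if (amax == 0.0) return R_NegInf;
    if (piv != k) {
      for (int j = k; j < n; ++j) std::swap(M[k * n + j], M[piv * n + j]);
      sign = -sign;
    }
    double pv = M[k * n + k];
    if (pv < 0) sign = -sign;
    logdet += std::log(std::fabs(pv));
    for (int i = k + 1; i < n; ++i) {
      double f = M[i * n + k] / pv;
      for (int j = k + 1; j < n; ++j) M[i * n + j] -= f * M[k * n + j];
    }
  }
  if (sign < 0) return R_NaN;
  return logdet + (l - 1) * cmax;
}

// contract edge (bi, bj), bi < bj: node bj merges into bi, parallel edge
// weights add in log space; returns the (l-1) x (l-1) log-weight matrix.
static std::vector<double> contract_edge(const std::vector<double>& logA,
                                         int l, int bi, int bj) {
  int m = l - 1;
  std::vector<int> map(l);
  for (int k = 0, r = 0; k < l; ++k) map[k] = (k == bj) ? -1 : r++;
  std::vector<double> C((size_t) m * m, R_NegInf);
  for (int i = 0; i < l; ++i) {
    if (i == bj) continue;
    for (int j = i + 1; j < l; ++j) {
      if (j == bj) continue;
      double v = logA[i * l + j];
      if (i == bi) v = logsumexp2(v, logA[bj * l + j]);
      if (j == bi) v = logsumexp2(v, logA[std::min(i, bj) * l + std::max(i, bj)]);
      int a = map[i], b = map[j];
      C[a * m + b] = v; C[b * m + a] = v;
    }
  }
  return C;
}

// log of the spanning-tree sum (drop used only on the direct path; the
// value is minor-independent).
static double tree_logsum(const std::vector<double>& logA, int l,
                          int drop = -1) {
  if (l <= 1) return 0.0;
  if (l == 2) return logA[1];
  double cmax = R_NegInf;
  int bi = 0, bj = 1;
  for (int i = 0; i < l; ++i)
    for (int j = i + 1; j < l; ++j)
      if (logA[i * l + j] > cmax) { cmax = logA[i * l + j]; bi = i; bj = j; }
  if (cmax == R_NegInf) return R_NegInf;   // no edges: no spanning tree
  if (strong_connected(logA, l, cmax))
    return direct_tree_logdet(logA, l, cmax, drop < 0 ? l - 1 : drop);
  std::vector<double> C = contract_edge(logA, l, bi, bj);
  double dc = tree_logsum(C, l - 1);
  // deletion-branch bound: swapping the top edge e into any tree that
  // lacks it (removing a cycle edge f) multiplies its weight by
  // R_e/R_f >= exp(cmax - second), so D_delete / (R_e * D_contract)
  // <= l^2 * exp(second - cmax); beyond DELETE_GAP that is far below
  // double precision and the branch is dropped
  double second = R_NegInf;
  for (int i = 0; i < l; ++i)
    for (int j = i + 1; j < l; ++j)
      if (!(i == bi && j == bj) && logA[i * l + j] > second)
        second = logA[i * l + j];
  const double DELETE_GAP = 60.0;
  if (cmax - second > DELETE_GAP) return cmax + dc;
  std::vector<double> D = logA;
  D[bi * l + bj] = R_NegInf; D[bj * l + bi] = R_NegInf;
  double dd = tree_logsum(D, l);
  return logsumexp2(cmax + dc, dd);
}

// [[Rcpp::export]]
double cpp_tree_logdet(NumericMatrix logR, int drop) {
  int l = logR.nrow();
  std::vector<double> A((size_t) l * l);
  for (int i = 0; i < l; ++i)
    for (int j = 0; j < l; ++j) A[i * l + j] = (i == j) ? R_NegInf : logR(i, j);
  return tree_logsum(A, l, drop);
}

// Edge posteriors of the current graph: P(i,j) = R_ij * d log D / d R_ij.
// Direct path: effective resistances from the Gauss-Jordan inverse of the
// rescaled Laplacian minor (long double). Recursive path mirrors
// tree_logsum: P = pc * P(contracted, split over parallel edges) +
// (1 - pc) * P(deleted), with pc = R_e D_contract / D the posterior of
// the contracted edge itself.
struct TreeRes { double logD; std::vector<double> P; };

static TreeRes tree_post_rec(const std::vector<double>& logA, int l) {
  TreeRes res;
  res.P.assign((size_t) l * l, 0.0);
  if (l <= 1) { res.logD = 0.0; return res; }
  if (l == 2) { res.logD = logA[1]; res.P[1] = res.P[2] = 1.0; return res; }
  double cmax = R_NegInf;
  int bi = 0, bj = 1;
  for (int i = 0; i < l; ++i)
    for (int j = i + 1; j < l; ++j)
      if (logA[i * l + j] > cmax) { cmax = logA[i * l + j]; bi = i; bj = j; }
  if (cmax == R_NegInf) { res.logD = R_NegInf; return res; }
  if (strong_connected(logA, l, cmax)) {
    res.logD = direct_tree_logdet(logA, l, cmax, l - 1);
    int n = l - 1;
    std::vector<long double> W((size_t) l * l, 0.0L),
      M((size_t) n * n, 0.0L), I((size_t) n * n, 0.0L);
    for (int i = 0; i < l; ++i)
      for (int j = i + 1; j < l; ++j) {
        long double w = (logA[i * l + j] == R_NegInf) ? 0.0L :
          expl((long double)(logA[i * l + j] - cmax));
        W[i * l + j] = w; W[j * l + i] = w;
      }
    for (int i = 0; i < n; ++i) {
      long double rs = 0.0L;
      for (int j = 0; j < l; ++j) rs += W[i * l + j];
      for (int j = 0; j < n; ++j)
        M[i * n + j] = (i == j) ? rs : -W[i * l + j];
      I[i * n + i] = 1.0L;
    }
    for (int k = 0; k < n; ++k) {       // Gauss-Jordan, partial pivoting
      int piv = k;
      long double amax = fabsl(M[k * n + k]);
      for (int i = k + 1; i < n; ++i)
        if (fabsl(M[i * n + k]) > amax) { amax = fabsl(M[i * n + k]); piv = i; }
      if (amax == 0.0L) { res.logD = R_NaN; return res; }
      if (piv != k)
        for (int j = 0; j < n; ++j) {
          std::swap(M[k * n + j], M[piv * n + j]);
          std::swap(I[k * n + j], I[piv * n + j]);
        }
      long double pv = M[k * n + k];
      for (int j = 0; j < n; ++j) { M[k * n + j] /= pv; I[k * n + j] /= pv; }
      for (int i = 0; i < n; ++i) {
        if (i == k) continue;
        long double f = M[i * n + k];
        if (f == 0.0L) continue;
        for (int j = 0; j < n; ++j) {
          M[i * n + j] -= f * M[k * n + j];
          I[i * n + j] -= f * I[k * n + j];
        }
      }
    }
    for (int i = 0; i < l - 1; ++i)
      for (int j = i + 1; j < l; ++j) {
        long double r;
        if (j == l - 1) r = I[i * n + i];
        else r = I[i * n + i] + I[j * n + j] - I[i * n + j] - I[j * n + i];
        double p = (double)(W[i * l + j] * r);
        if (p < 0) p = 0; else if (p > 1) p = 1;
        res.P[i * l + j] = p; res.P[j * l + i] = p;
      }
    return res;
  }
  std::vector<double> C = contract_edge(logA, l, bi, bj);
  TreeRes rc = tree_post_rec(C, l - 1);
  std::vector<double> D = logA;
  D[bi * l + bj] = R_NegInf; D[bj * l + bi] = R_NegInf;
  TreeRes rd = tree_post_rec(D, l);
  res.logD = logsumexp2(cmax + rc.logD, rd.logD);
  double pc = (res.logD == R_NegInf) ? 0.0 :
    std::exp(cmax + rc.logD - res.logD);
  double pd = 1.0 - pc;
  int m = l - 1;
  std::vector<int> map(l);
  for (int k = 0, r = 0; k < l; ++k) map[k] = (k == bj) ? -1 : r++;
  for (int i = 0; i < l; ++i)
    for (int j = i + 1; j < l; ++j) {
      double p = pd * rd.P[i * l + j];
      if (i == bi && j == bj) {
        p += pc;                      // every contract-branch tree has e
      } else if (i == bi || i == bj || j == bi || j == bj) {
        // posterior of the merged parallel edge splits by weight
        int other = (i == bi || i == bj) ? j : i;
        double pmerge = rc.P[map[bi] * m + map[other]];
        double w1 = logA[bi * l + other];
        double w2 = logA[bj * l + other];
        double tot = logsumexp2(w1, w2);
        double mine = (i == bi || j == bi) ? w1 : w2;
        if (tot != R_NegInf && mine != R_NegInf)
          p += pc * pmerge * std::exp(mine - tot);
      } else {
        p += pc * rc.P[map[i] * m + map[j]];
      }
      res.P[i * l + j] = p; res.P[j * l + i] = p;
    }
  return res;
}

// [[Rcpp::export]]
NumericMatrix cpp_edge_posteriors(NumericMatrix logR) {
  int l = logR.nrow();
  std::vector<double> A((size_t) l * l);
  for (int i = 0; i < l; ++i)
    for (int j = 0; j < l; ++j) A[i * l + j] = (i == j) ? R_NegInf : logR(i, j);
  TreeRes res = tree_post_rec(A, l);
  if (ISNAN(res.logD)) {
    NumericMatrix bad(1, 1); bad(0, 0) = R_NaN; return bad;
  }
  NumericMatrix P(l, l);
  for (int i = 0; i < l; ++i)
    for (int j = 0; j < l; ++j) P(i, j) = res.P[i * l + j];
  return P;
}

static inline double delta_at(const double* delta, int l, int a, int b,
                              int i, int j) {
  // delta has dim (4, 4, l, l)
  return delta[a + 4 * b + 16 * (i + l * j)];
}


// ---------------------------------------------------------------------------
// Scan plan: per-model preprocessing that makes per-segment DWT scoring
// cheap. Pairs whose log edge weight exceeds every other pair's maximum
// possible weight by DELETE_GAP for every letter combination ("dominant"
// pairs, typically the strongly coupled positions) are contracted up
// front; their deletion branches are provably negligible. For the
// remaining (reduced) graph a lookup table holds exp(logR + delta - C)
// at a fixed model-level scale C, so a segment's Laplacian can be built
// by table adds alone (parallel edges of contracted groups simply add in
// the linear domain) and one small LU finishes the job. Segments whose
// reduced graph is not dominated-connected fall back to the exact
// recursion.
static long g_fallbacks = 0, g_calls = 0;

struct ScanPlan {
  int l, m;                     // motif length, number of groups
  int kind;
  std::vector<int> grp;         // node -> group index
  std::vector<int> Hi, Hj;      // contracted (dominant) pairs
  bool inH(int i, int j) const {
    for (size_t k = 0; k < Hi.size(); ++k)
      if (Hi[k] == i && Hj[k] == j) return true;
    return false;
  }
  double Cglob;                 // scale of the table
  std::vector<double> T;        // 25 entries per (i<j) pair: letters 0..4
  std::vector<int> pi, pj, Ti;  // reduced cross pairs and their table rows
  std::vector<double> logw_, delta_, logR_;
  double logD0;
};

static ScanPlan build_scan_plan(const double* logw, const double* delta,
                                const double* logR, int l, int kind,
                                double logD0) {
  ScanPlan P;
  P.l = l; P.kind = kind; P.logD0 = logD0;
  P.logw_.assign(logw, logw + 4 * l);
  P.delta_.assign(delta, delta + 16 * l * l);
  P.logR_.assign(logR, logR + (size_t) l * l);
  P.grp.resize(l);
  for (int i = 0; i < l; ++i) P.grp[i] = i;
  P.m = l;
  if (kind != 2) return P;
  int np = l * (l - 1) / 2;
  std::vector<double> lo(np), hi(np);
  std::vector<int> ii(np), jj(np);
  {
    int k = 0;
    for (int i = 0; i < l; ++i)
      for (int j = i + 1; j < l; ++j, ++k) {
        ii[k] = i; jj[k] = j;
        double mn = 0.0, mx = 0.0;        // include 0: N pairs keep raw R
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            double d = delta_at(delta, l, a, b, i, j);
            if (d < mn) mn = d;
            if (d > mx) mx = d;
          }
        lo[k] = logR[i + (size_t) l * j] + mn;
        hi[k] = logR[i + (size_t) l * j] + mx;
      }
  }
  const double GAP = 60.0;
  // Dominant set H: the largest prefix of pairs (sorted by their minimum
  // possible weight) whose members all exceed the maximum possible
  // weight of every remaining pair by GAP. Members need not dominate
  // each other: the deletion-branch bound only involves non-H edges
  // (the cycle closed by re-inserting an H edge into a tree always
  // contains a non-H edge, H being a forest).
  std::vector<bool> inH(np, false);
  {
    std::vector<int> ord(np);
    for (int k = 0; k < np; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return lo[a] > lo[b]; });
    std::vector<double> maxhi_after(np + 1, R_NegInf);
    for (int t = np - 1; t >= 0; --t)
      maxhi_after[t] = std::max(maxhi_after[t + 1], hi[ord[t]]);
    int best_t = 0;
    for (int t = 1; t <= np; ++t) {
      double minlo = lo[ord[t - 1]];
      double rest = (t == np) ? 0.0 : maxhi_after[t];
      if (minlo > rest + GAP) best_t = t;   // prefix lo is non-increasing
    }
    for (int t = 0; t < best_t; ++t) inH[ord[t]] = true;
  }
  // contracted pairs must form a forest; otherwise use the generic path
  {
    std::vector<int> up(l);
    for (int i = 0; i < l; ++i) up[i] = i;
    for (int k = 0; k < np; ++k) {
      if (!inH[k]) continue;
      int a = uf_find(up, ii[k]), b = uf_find(up, jj[k]);
      if (a == b) { for (int q = 0; q < np; ++q) inH[q] = false; break; }
      up[a] = b;
    }
    if (std::count(inH.begin(), inH.end(), true) > 0) {
      for (int i = 0; i < l; ++i) uf_find(up, i);
      std::vector<int> relab(l, -1);
      int m = 0;
      for (int i = 0; i < l; ++i) {
        int r = uf_find(up, i);
        if (relab[r] < 0) relab[r] = m++;
        P.grp[i] = relab[r];
      }
      P.m = m;
      for (int k = 0; k < np; ++k)
        if (inH[k]) { P.Hi.push_back(ii[k]); P.Hj.push_back(jj[k]); }
    }
  }
  // table of exp(logR + delta - Cglob) for non-contracted cross pairs
  P.Cglob = R_NegInf;
  for (int k = 0; k < np; ++k)
    if (!inH[k] && P.grp[ii[k]] != P.grp[jj[k]] && hi[k] > P.Cglob)
      P.Cglob = hi[k];
  if (!R_FINITE(P.Cglob)) P.Cglob = 0.0;
  P.T.assign((size_t) np * 25, 0.0);
  for (int k = 0; k < np; ++k) {
    if (inH[k] || P.grp[ii[k]] == P.grp[jj[k]]) continue;
    P.pi.push_back(ii[k]); P.pj.push_back(jj[k]);
    double base = P.logR_[ii[k] + (size_t) l * jj[k]];
    for (int a = 0; a < 5; ++a)
      for (int b = 0; b < 5; ++b) {
        double d = (a < 4 && b < 4) ?
          delta_at(delta, l, a, b, ii[k], jj[k]) : 0.0;
        double v = base + d - P.Cglob;
        P.T[(size_t) k * 25 + a * 5 + b] = (v < -745.0) ? 0.0 : std::exp(v);
      }
  }
  // remember table row per cross pair (parallel arrays with pi/pj)
  P.Ti.clear();
  for (int k = 0; k < np; ++k)
    if (!inH[k] && P.grp[ii[k]] != P.grp[jj[k]]) P.Ti.push_back(k);
  return P;
}

// DWT log determinant term for one segment under a plan; falls back to
// the exact recursion when the reduced graph is not dominated-connected.
static double plan_tree_term(const ScanPlan& P, const int* s, int off) {
  int l = P.l, m = P.m;
  double hsum = 0.0;
  for (size_t k = 0; k < P.Hi.size(); ++k) {
    int i = P.Hi[k], j = P.Hj[k];
    int a = s[off + i], b = s[off + j];
    double v = P.logR_[i + (size_t) l * j];
    if (a < 4 && b < 4) v += delta_at(P.delta_.data(), l, a, b, i, j);
    hsum += v;
  }
  if (m == 1) return hsum - P.logD0;
  static std::vector<double> W;
  W.assign((size_t) m * m, 0.0);
  for (size_t q = 0; q < P.pi.size(); ++q) {
    int i = P.pi[q], j = P.pj[q];
    int g1 = P.grp[i], g2 = P.grp[j];
    double w = P.T[(size_t) P.Ti[q] * 25 + s[off + i] * 5 + s[off + j]];
    W[g1 * m + g2] += w;
    W[g2 * m + g1] += w;
  }
  // dominated-connectivity check in the linear domain
  double wmax = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      if (W[i * m + j] > wmax) wmax = W[i * m + j];
  double thr = wmax * 2.061154e-9;     // exp(-TREE_SPREAD)
  {
    static std::vector<int> up;
    up.resize(m);
    for (int i = 0; i < m; ++i) up[i] = i;
    int ncomp = m;
    for (int i = 0; i < m && ncomp > 1; ++i)
      for (int j = i + 1; j < m; ++j)
        if (W[i * m + j] > thr) {
          int a = uf_find(up, i), b = uf_find(up, j);
          if (a != b) { up[a] = b; --ncomp; }
        }
    ++g_calls;
    if (ncomp > 1) {
      // gray zone: rebuild the reduced graph exactly in log domain and
      // recurse (still skipping the pre-contracted dominant pairs, whose
      // deletion branches are bounded by exp(-GAP))
      ++g_fallbacks;
      static std::vector<double> A;
      A.assign((size_t) m * m, R_NegInf);
      for (size_t q = 0; q < P.pi.size(); ++q) {
        int i = P.pi[q], j = P.pj[q];
        int g1 = P.grp[i], g2 = P.grp[j];
        int a = s[off + i], b = s[off + j];
        double v = P.logR_[i + (size_t) l * j];
        if (a < 4 && b < 4) v += delta_at(P.delta_.data(), l, a, b, i, j);
        double cur = A[g1 * m + g2];
        double nv = logsumexp2(cur, v);
        A[g1 * m + g2] = nv; A[g2 * m + g1] = nv;
      }
      double ld = tree_logsum(A, m);
      if (!R_FINITE(ld))
        ::Rf_error("non-positive tree determinant while scoring a segment");
      return hsum + ld - P.logD0;
    }
  }
  // LU of the Laplacian minor of W (drop last group)
  int n = m - 1;
  static std::vector<double> M;
  M.assign((size_t) n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < m; ++j) rs += W[i * m + j];
    for (int j = 0; j < n; ++j) M[i * n + j] = (i == j) ? rs : -W[i * m + j];
  }
  double logdet = 0.0;
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double amax = std::fabs(M[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(M[i * n + k]);
      if (v > amax) { amax = v; piv = i; }
    }
    if (amax == 0.0)
      ::Rf_error("singular Laplacian while scoring a segment");
    if (piv != k)
      for (int j = k; j < n; ++j) std::swap(M[k * n + j], M[piv * n + j]);
    double pv = M[k * n + k];
    logdet += std::log(pv);            // SPD minor: pivots positive
    for (int i = k + 1; i < n; ++i) {
      double f = M[i * n + k] / pv;
      for (int j = k + 1; j < n; ++j) M[i * n + j] -= f * M[k * n + j];
    }
  }
  return hsum + logdet + (m - 1) * P.Cglob - P.logD0;
}

// Predictive log-probability of one length-l segment starting at `off`
// (0-based) of encoded sequence `s` (0..3 = ACGT, 4 = N) under a plan.
// kind: 0 = PSWM, 1 = ADJ, 2 = DWT. N positions are ratio-neutral: they
// contribute nothing to the PSWM term and pairs involving them keep the
// training R.
static double segment_logprob(const ScanPlan& P, const int* s, int off) {
  int l = P.l;
  double lp = 0.0;
  for (int i = 0; i < l; ++i) {
    int a = s[off + i];
    if (a < 4) lp += P.logw_[a + 4 * i];
  }
  if (P.kind == 1) {          // adjacent chain
    for (int i = 1; i < l; ++i) {
      int a = s[off + i - 1], b = s[off + i];
      if (a < 4 && b < 4) lp += delta_at(P.delta_.data(), l, a, b, i - 1, i);
    }
  } else if (P.kind == 2) {   // full DWT: ratio of tree determinants
    lp += plan_tree_term(P, s, off);
  }
  return lp;
}

// [[Rcpp::export]]
NumericVector cpp_score_sites(IntegerMatrix sites, NumericMatrix logw,
                              NumericVector delta, NumericMatrix logR,
                              int kind, double logD0) {
  int l = sites.nrow(), m = sites.ncol();
  NumericVector out(m);
  ScanPlan P = build_scan_plan(REAL(logw), REAL(delta), REAL(logR), l,
                               kind, logD0);
  std::vector<int> buf(l);
  for (int k = 0; k < m; ++k) {
    for (int i = 0; i < l; ++i) buf[i] = sites(i, k);
    out[k] = segment_logprob(P, buf.data(), 0);
  }
  return out;
}

// Per-offset binding energies E(s) = log P(s|M) - log P(s|B) for one
// strand of one encoded sequence; N positions contribute 0 to both terms.
// [[Rcpp::export]]
NumericVector cpp_scan_energies(IntegerVector seq, NumericMatrix logw,
                                NumericVector delta, NumericMatrix logR,
                                int kind, double logD0, NumericVector logbg) {
  int L = seq.size();
  int l = logw.ncol();
  int K = L - l + 1;
  if (K < 1) return NumericVector(0);
  NumericVector out(K);
  const int* s = INTEGER(seq);
  const double* bg = REAL(logbg);
  // sliding background log-prob with N-neutral positions
  std::vector<double> bgpref(L + 1, 0.0);
  for (int i = 0; i < L; ++i)
    bgpref[i + 1] = bgpref[i] + (s[i] < 4 ? bg[s[i]] : 0.0);
  ScanPlan P = build_scan_plan(REAL(logw), REAL(delta), REAL(logR), l,
                               kind, logD0);
  for (int off = 0; off < K; ++off)
    out[off] = segment_logprob(P, s, off) - (bgpref[off + l] - bgpref[off]);
  return out;
}

// Accumulate posterior-weighted dinucleotide counts of all length-l
// segments of `seq` into `tensor` (dim 4,4,l,l; modified copy returned is
// handled on the R side -- here we mutate in place for speed).
// N positions are soft-imputed from the model marginals `wmarg` (4 x l).
// [[Rcpp::export]]
void cpp_accumulate_scan(NumericVector tensor, IntegerVector seq,
                         NumericVector post, NumericMatrix wmarg, int l) {
  int L = seq.size();
  int K = L - l + 1;
  double* T = REAL(tensor);
  const int* s = INTEGER(seq);
  for (int off = 0; off < K; ++off) {
    double p = post[off];
    if (p <= 0) continue;
    for (int i = 0; i < l; ++i) {
      int a = s[off + i];
      for (int j = i + 1; j < l; ++j) {
        int b = s[off + j];
        if (a < 4 && b < 4) {
          T[a + 4 * b + 16 * (i + l * j)] += p;
          T[b + 4 * a + 16 * (j + l * i)] += p;
        } else if (a < 4) {
          for (int bb = 0; bb < 4; ++bb) {
            double w = p * wmarg(bb, j);
            T[a + 4 * bb + 16 * (i + l * j)] += w;
            T[bb + 4 * a + 16 * (j + l * i)] += w;
          }
        } else if (b < 4) {
          for (int aa = 0; aa < 4; ++aa) {
            double w = p * wmarg(aa, i);
            T[aa + 4 * b + 16 * (i + l * j)] += w;
            T[b + 4 * aa + 16 * (j + l * i)] += w;
          }
        } else {
          for (int aa = 0; aa < 4; ++aa)
            for (int bb = 0; bb < 4; ++bb) {
              double w = p * wmarg(aa, i) * wmarg(bb, j);
              T[aa + 4 * bb + 16 * (i + l * j)] += w;
              T[bb + 4 * aa + 16 * (j + l * i)] += w;
            }
        }
      }
    }
  }
}

// Exact pair counts of a site matrix (l x m, letters 0..3 or 4 = N) with
// per-site weights; N handled as in cpp_accumulate_scan.
// [[Rcpp::export]]
NumericVector cpp_accumulate_counts(NumericVector tensor, IntegerMatrix sites,
                                    NumericVector weights, NumericMatrix wmarg) {
  NumericVector out = clone(tensor);
  int l = sites.nrow(), m = sites.ncol();
  std::vector<int> buf(l);
  for (int k = 0; k < m; ++k) {
    IntegerVector col = sites(_, k);
    IntegerVector one(l);
    for (int i = 0; i < l; ++i) one[i] = col[i];
    NumericVector p(1); p[0] = weights[k];
    cpp_accumulate_scan(out, one, p, wmarg, l);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fallback_stats() {
  NumericVector v(2); v[0] = g_calls; v[1] = g_fallbacks;
  g_calls = g_fallbacks = 0;
  return v;
}
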