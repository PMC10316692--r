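#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fixed-point helpers: `bits`-wide two's-complement arithmetic with either
// wraparound (hardware accumulator semantics) or saturation.  All arithmetic
// is done in 64-bit and renormalized into the word width afterwards;
// renormalizations that change the value count as overflow events.
// ---------------------------------------------------------------------------

struct FxCtx {
  int bits;
  bool wrap;
  long long lo, hi;
  long long n_overflow;
  FxCtx(int bits_, bool wrap_)
      : bits(bits_), wrap(wrap_),
        lo(-(1LL << (bits_ - 1))), hi((1LL << (bits_ - 1)) - 1),
        n_overflow(0) {}
  inline long long norm(long long v) {
    if (v >= lo && v <= hi) return v;
    ++n_overflow;
    if (!wrap) return v > hi ? hi : lo;
    long long mod = 1LL << bits;
    v &= (mod - 1);
    if (v > hi) v -= mod;
    return v;
  }
  inline long long abs_diff(long long a, long long b) {
    long long d = norm(a - b);
    return d < 0 ? norm(-d) : d;
  }
  inline long long add(long long a, long long b) { return norm(a + b); }
};

static inline long long min3ll(long long a, long long b, long long c) {
  long long m = a;
  if (b < m) m = b;
  if (c < m) m = c;
  return m;
}

// Best and second-best minimum of a last-row buffer.  Best takes the
// smallest index on ties; second is the minimum over indices farther than
// `excl` from the best (NA if none exists).
template <typename T>
static List best_second(const std::vector<T>& row, int excl) {
  int n = (int)row.size();
  int bi = 0;
  for (int j = 1; j < n; ++j)
    if (row[j] < row[bi]) bi = j;
  int si = -1;
  for (int j = 0; j < n; ++j) {
    if (std::abs((double)j - bi) <= excl) continue;
    if (si < 0 || row[j] < row[si]) si = j;
  }
  return List::create(
      _["score"] = (double)row[bi], _["end"] = bi,
      _["second_score"] = si < 0 ? NA_REAL : (double)row[si],
      _["second_end"] = si < 0 ? NA_INTEGER : si);
}

static void check_sizes(int M, int N) {
  if (M < 1 || N < 1)
    stop("sDTW requires non-empty query and reference");
  if (M > N)
    stop("sDTW requires query length M <= reference length N");
}

// ---------------------------------------------------------------------------
// Full-matrix float engine with backtracking (the oracle).
// Recurrence: g(i,j) = |x[i]-y[j]| + min(g(i-1,j), g(i-1,j-1), g(i,j-1))
// with g(0,j) = 0 and g(i,0) = +Inf.  End = argmin of the last row
// (smallest index on ties); path recovered preferring diagonal, then left
// (j-1), then up (i-1) on ties, stopping in row 1 (free start).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sdtw_oracle_cpp(NumericVector x, NumericVector y, int exclusion) {
  int M = x.size(), N = y.size();
  check_sizes(M, N);
  if ((double)(M + 1) * (N + 1) > 2.5e8)
    stop("full-matrix engine refuses > 2.5e8 cells; use the linear engine");
  std::vector<double> G((size_t)(M + 1) * (N + 1));
  std::vector<signed char> P((size_t)(M + 1) * (N + 1), 0);
  size_t W = N + 1;
  for (int j = 0; j <= N; ++j) G[j] = 0.0;
  for (int i = 1; i <= M; ++i) G[(size_t)i * W] = R_PosInf;
  for (int j = 1; j <= N; ++j) {
    for (int i = 1; i <= M; ++i) {
      double d = std::fabs(x[i - 1] - y[j - 1]);
      double diag = G[(size_t)(i - 1) * W + (j - 1)];
      double left = G[(size_t)i * W + (j - 1)];
      double up = G[(size_t)(i - 1) * W + j];
      double m = diag;
      signed char p = 0;          // 0 = diag, 1 = left, 2 = up
      if (left < m) { m = left; p = 1; }
      if (up < m) { m = up; p = 2; }
      G[(size_t)i * W + j] = d + m;
      P[(size_t)i * W + j] = p;
    }
  }
  std::vector<double> last(N);
  for (int j = 1; j <= N; ++j) last[j - 1] = G[(size_t)M * W + j];
  List bs = best_second(last, exclusion);
  int end = as<int>(bs["end"]);

  // backtrack from (M, end+1) to row 1
  std::vector<std::pair<int, int>> rev;
  int i = M, j = end + 1;
  for (;;) {
    rev.push_back(std::make_pair(i - 1, j - 1));  // 0-based
    if (i == 1) break;
    signed char p = P[(size_t)i * W + j];
    if (p == 0) { --i; --j; }
    else if (p == 1) { --j; }
    else { --i; }
  }
  int L = (int)rev.size();
  IntegerMatrix path(L, 2);
  for (int t = 0; t < L; ++t) {
    path(t, 0) = rev[L - 1 - t].first;
    path(t, 1) = rev[L - 1 - t].second;
  }
  bs["start"] = rev.back().second;  // j of the row-1 cell, 0-based
  bs["path"] = path;
  return bs;
}

// ---------------------------------------------------------------------------
// Linear-space float engine: a single cost array of M + 1 entries, outer
// loop over the reference, inner loop over the query; tracks the running
// minimum of the last row only (no backtracking).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sdtw_linear_cpp(NumericVector x, NumericVector y, int exclusion) {
  int M = x.size(), N = y.size();
  check_sizes(M, N);
  std::vector<double> cost(M + 1, R_PosInf);
  cost[0] = 0.0;                       // g(0, j) = 0 for all j
  std::vector<double> last(N);
  for (int j = 1; j <= N; ++j) {
    double diag = cost[0];             // g(0, j-1) = 0
    for (int i = 1; i <= M; ++i) {
      double up_left = cost[i];        // g(i, j-1)
      double d = std::fabs(x[i - 1] - y[j - 1]);
      double m = diag;                 // g(i-1, j-1)
      if (up_left < m) m = up_left;
      if (cost[i - 1] < m) m = cost[i - 1];  // g(i-1, j)
      diag = up_left;
      cost[i] = d + m;
    }
    last[j - 1] = cost[M];
  }
  return best_second(last, exclusion);
}

// ---------------------------------------------------------------------------
// Sequential fixed-point evaluation of the linear-space algorithm.  The
// "infinity" boundary is the maximum representable value; all adds,
// subtractions and the absolute value run in the configured word width.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sdtw_fixed_seq_cpp(IntegerVector x, IntegerVector y, int bits,
                        bool wrap, int exclusion) {
  int M = x.size(), N = y.size();
  check_sizes(M, N);
  FxCtx fx(bits, wrap);
  for (int i = 0; i < M; ++i)
    if (x[i] < fx.lo || x[i] > fx.hi) stop("query value out of fixed-point range");
  for (int j = 0; j < N; ++j)
    if (y[j] < fx.lo || y[j] > fx.hi) stop("reference value out of fixed-point range");
  std::vector<long long> cost(M + 1, fx.hi);   // g(i, 0) = "infinity"
  cost[0] = 0;
  std::vector<long long> last(N);
  for (int j = 1; j <= N; ++j) {
    long long diag = cost[0];
    for (int i = 1; i <= M; ++i) {
      long long up_left = cost[i];
      long long d = fx.abs_diff(x[i - 1], y[j - 1]);
      long long m = min3ll(diag, up_left, cost[i - 1]);
      diag = up_left;
      cost[i] = fx.add(d, m);
    }
    last[j - 1] = cost[M];
  }
  List bs = best_second(last, exclusion);
  bs["n_overflow"] = (double)fx.n_overflow;
  return bs;
}

// ---------------------------------------------------------------------------
// Wavefront (PE-chain) fixed-point engine.  Models a chain of M processing
// elements computing one oblique anti-diagonal per step: at step t
// (0-based), PE i (1-based) computes cell (i, t - i + 2) when that column
// is in range.  Shared neighbor values live in two register arrays of size
// M: L1 holds each PE's previous cost (column j-1) and L2 the one before
// (column j-2, supplying the diagonal for the PE below).  The arithmetic is
// identical to the sequential fixed-point engine, so results are
// bit-identical; only the schedule differs.  The full search takes
// M + N - 1 steps.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sdtw_fixed_wave_cpp(IntegerVector x, IntegerVector y, int bits,
                         bool wrap, int exclusion) {
  int M = x.size(), N = y.size();
  check_sizes(M, N);
  FxCtx fx(bits, wrap);
  for (int i = 0; i < M; ++i)
    if (x[i] < fx.lo || x[i] > fx.hi) stop("query value out of fixed-point range");
  for (int j = 0; j < N; ++j)
    if (y[j] < fx.lo || y[j] > fx.hi) stop("reference value out of fixed-point range");

  std::vector<long long> L1(M + 1, fx.hi), L2(M + 1, fx.hi);
  L1[0] = 0; L2[0] = 0;                 // row-0 boundary g(0, j) = 0
  std::vector<long long> cur(M + 1);
  std::vector<long long> last(N);
  int steps = M + N - 1;
  for (int t = 0; t < steps; ++t) {
    // active PEs at step t compute cells (i, j) on one oblique column,
    // j = t - i + 2; at the same step PE i-1 is already one column ahead,
    // so all three neighbors of PE i come from the register arrays:
    //   g(i, j-1)   = L1[i]    (PE i's own previous cost)
    //   g(i-1, j)   = L1[i-1]  (PE i-1's previous cost)
    //   g(i-1, j-1) = L2[i-1]  (PE i-1's cost two steps back)
    int i_lo = std::max(1, t + 2 - N);
    int i_hi = std::min(M, t + 1);
    for (int i = i_lo; i <= i_hi; ++i) {
      int j = t - i + 2;
      long long up = L1[i - 1];
      long long n_ = L1[i];
      long long nw = L2[i - 1];
      long long d = fx.abs_diff(x[i - 1], y[j - 1]);
      long long m = min3ll(nw, n_, up);
      cur[i] = fx.add(d, m);
      if (i == M) last[j - 1] = cur[M];
    }
    // end of step: costs shift L1 -> L2 and the new costs enter L1
    for (int i = i_hi; i >= i_lo; --i) {
      L2[i] = L1[i];
      L1[i] = cur[i];
    }
  }
  List bs = best_second(last, exclusion);
  bs["n_overflow"] = (double)fx.n_overflow;
  bs["steps"] = steps;
  return bs;
}

// ---------------------------------------------------------------------------
// Fixed-point Manhattan distance (exposed for tests of the word-width
// arithmetic semantics).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List manhattan_fixed_cpp(IntegerVector a, IntegerVector b, int bits,
                         bool wrap) {
  if (a.size() != b.size()) stop("length mismatch");
  FxCtx fx(bits, wrap);
  IntegerVector out(a.size());
  for (int i = 0; i < a.size(); ++i)
    out[i] = (int)fx.abs_diff(a[i], b[i]);
  return List::create(_["value"] = out, _["n_overflow"] = (double)fx.n_overflow);
}
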