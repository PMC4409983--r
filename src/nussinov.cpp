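#include <Rcpp.h>
using namespace Rcpp;

// Maximum-score nested pairing (Nussinov-style DP) on an arbitrary
// column-pair score matrix. Pairing of (i, j) is allowed iff S(i, j) > 0
// and j - i > min_loop. Traceback is deterministic: at [i, j] the unpaired
// option is taken only when no pairing of i attains the optimum, and among
// optimal partners of i the largest j is preferred (smallest-i, largest-j
// tie-break).

// nucleotide pair score used for single sequences: GC=3, AU/AT=2, GU/GT=1
static inline double nt_pair_score(int a, int b) {
  // codes: A=0, C=1, G=2, T/U=3, other=-1
  if (a < 0 || b < 0) return 0.0;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.0;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.0;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0;
  return 0.0;
}

static void run_dp(const std::vector<double>& S, int n, int min_loop,
                   std::vector<double>& M) {
  // M is n*n row-major, upper triangle used
  for (int len = 1; len < n; ++len) {
    for (int i = 0; i + len < n; ++i) {
      int j = i + len;
      double best = M[(i + 1) * n + j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double ps = S[i * n + k];
        if (ps <= 0) continue;
        double v = ps;
        if (k - 1 >= i + 1) v += M[(i + 1) * n + (k - 1)];
        if (k + 1 <= j) v += M[(k + 1) * n + j];
        if (v > best) best = v;
      }
      M[i * n + j] = best;
    }
  }
}

static void traceback(const std::vector<double>& S, const std::vector<double>& M,
                      int n, int min_loop, std::vector<int>& partner) {
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    double target = M[i * n + j];
    if (target <= eps) continue;
    // prefer pairing i; among optimal k prefer the largest
    int best_k = -1;
    for (int k = j; k >= i + min_loop + 1; --k) {
      double ps = S[i * n + k];
      if (ps <= 0) continue;
      double v = ps;
      if (k - 1 >= i + 1) v += M[(i + 1) * n + (k - 1)];
      if (k + 1 <= j) v += M[(k + 1) * n + j];
      if (v >= target - eps) { best_k = k; break; }
    }
    if (best_k >= 0) {
      partner[i] = best_k;
      partner[best_k] = i;
      if (best_k - 1 >= i + 1) stack.push_back(std::make_pair(i + 1, best_k - 1));
      if (best_k + 1 <= j) stack.push_back(std::make_pair(best_k + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
}

// [[Rcpp::export(name = ".nussinov_matrix_cpp")]]
List nussinov_matrix_cpp(NumericMatrix S, int min_loop) {
  int n = S.nrow();
  if (n == 0) return List::create(_["score"] = 0.0,
                                  _["pairs"] = IntegerMatrix(0, 2));
  std::vector<double> Sv(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Sv[i * n + j] = S(i, j);
  std::vector<double> M(n * n, 0.0);
  run_dp(Sv, n, min_loop, M);
  std::vector<int> partner(n, -1);
  traceback(Sv, M, n, min_loop, partner);
  int np = 0;
  for (int i = 0; i < n; ++i) if (partner[i] > i) ++np;
  IntegerMatrix pairs(np, 2);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) { pairs(r, 0) = i; pairs(r, 1) = partner[i]; ++r; }
  }
  return List::create(_["score"] = M[n - 1], _["pairs"] = pairs);
}

// [[Rcpp::export(name = ".fold_score_cpp")]]
double fold_score_cpp(IntegerVector codes, int min_loop) {
  int n = codes.size();
  if (n < 2) return 0.0;
  std::vector<double> Sv(n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      Sv[i * n + j] = nt_pair_score(codes[i], codes[j]);
  std::vector<double> M(n * n, 0.0);
  run_dp(Sv, n, min_loop, M);
  return M[n - 1];
}

// [[Rcpp::export(name = ".fold_full_cpp")]]
List fold_full_cpp(IntegerVector codes, int min_loop) {
  int n = codes.size();
  NumericMatrix S(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      S(i, j) = (j > i) ? nt_pair_score(codes[i], codes[j]) : 0.0;
  return nussinov_matrix_cpp(S, min_loop);
}

// consensus column-pair score matrix: mean per-row contribution (pair score
// when the row can pair, -mismatch_penalty when both characters are bases
// but cannot pair, 0 when either is a gap) plus covar_bonus per row pair
// showing a compensatory double substitution that preserves pairability.
// The penalty keeps unrelated-but-foldable rows from accumulating spurious
// consensus structure.
// [[Rcpp::export(name = ".consensus_matrix_cpp")]]
NumericMatrix consensus_matrix_cpp(IntegerMatrix codes, double covar_bonus,
                                   double mismatch_penalty) {
  int R = codes.nrow(), n = codes.ncol();
  NumericMatrix S(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double mean_score = 0.0;
      for (int r = 0; r < R; ++r) {
        double psc = nt_pair_score(codes(r, a), codes(r, b));
        if (psc > 0) mean_score += psc;
        else if (codes(r, a) >= 0 && codes(r, b) >= 0)
          mean_score -= mismatch_penalty;
      }
      mean_score /= R;
      // covariation: fraction of row pairs showing a compensatory double
      // substitution (averaged so the bonus does not grow as R^2)
      int n_comp = 0;
      for (int r = 0; r < R; ++r) {
        if (nt_pair_score(codes(r, a), codes(r, b)) <= 0) continue;
        for (int s = r + 1; s < R; ++s) {
          if (nt_pair_score(codes(s, a), codes(s, b)) <= 0) continue;
          if (codes(r, a) != codes(s, a) && codes(r, b) != codes(s, b))
            ++n_comp;
        }
      }
      double bonus = (R >= 2)
        ? covar_bonus * (double)n_comp / (R * (R - 1) / 2.0) : 0.0;
      S(a, b) = mean_score + bonus;
    }
  }
  return S;
}
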