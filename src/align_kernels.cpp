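#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine gap convention used throughout: a run of k gap characters costs
// gap_open + (k - 1) * gap_extend (both non-positive); the opening penalty
// covers the first gap character. Traceback ties are broken
// diagonal > up (gap in b) > left (gap in a), applied to both the state
// choice at a cell and the predecessor-state choice, so alignments are
// bit-reproducible.

static const double NEG_INF = -1e18;

static inline double sub_score(char x, char y, double match, double mismatch) {
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  // states: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: predecessor state for each state at each cell
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
      tY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_ext;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_ext;
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: consume a[i-1], b[j-1]
      double s = sub_score(a[i - 1], b[j - 1], match, mismatch);
      double best = M[d]; signed char bt = 0;
      if (X[d] > best) { best = X[d]; bt = 1; }
      if (Y[d] > best) { best = Y[d]; bt = 2; }
      M[c] = best + s; tM[c] = bt;
      // X: gap in b (move up)
      double open_x = M[u] + gap_open;
      double ext_x = X[u] + gap_ext;
      double from_y = Y[u] + gap_open;
      best = open_x; bt = 0;
      if (ext_x > best) { best = ext_x; bt = 1; }
      if (from_y > best) { best = from_y; bt = 2; }
      X[c] = best; tX[c] = bt;
      // Y: gap in a (move left)
      double open_y = M[l] + gap_open;
      double from_x = X[l] + gap_open;
      double ext_y = Y[l] + gap_ext;
      best = open_y; bt = 0;
      if (from_x > best) { best = from_x; bt = 1; }
      if (ext_y > best) { best = ext_y; bt = 2; }
      Y[c] = best; tY[c] = bt;
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = tX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = tY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["row_a"] = ra, _["row_b"] = rb, _["score"] = score);
}

// [[Rcpp::export]]
double sw_score_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, 0.0), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = sub_score(a[i - 1], b[j - 1], match, mismatch);
      double diag = std::max(M[d], std::max(X[d], Y[d]));
      M[c] = std::max(0.0, diag + s);
      X[c] = std::max(M[u] + gap_open,
                      std::max(X[u] + gap_ext, Y[u] + gap_open));
      Y[c] = std::max(M[l] + gap_open,
                      std::max(X[l] + gap_open, Y[l] + gap_ext));
      if (M[c] > best) best = M[c];
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericMatrix sw_score_matrix_cpp(CharacterVector seqs,
                                  double match, double mismatch,
                                  double gap_open, double gap_ext) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double sc = sw_score_cpp(ss[i], ss[j], match, mismatch, gap_open, gap_ext);
      out(i, j) = sc; out(j, i) = sc;
    }
  }
  return out;
}

// Pairwise site-pattern counts over an encoded alignment matrix.
// codes: 1=A, 2=C, 3=G, 4=T, 0=gap, -1=ambiguity. Columns with gap or
// ambiguity in either row of a pair are excluded (pairwise deletion).
// [[Rcpp::export]]
List pair_counts_cpp(IntegerMatrix codes) {
  const int n = codes.nrow(), L = codes.ncol();
  IntegerMatrix S(n, n), V(n, n), N(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int s = 0, v = 0, nn = 0;
      for (int k = 0; k < L; ++k) {
        int x = codes(i, k), y = codes(j, k);
        if (x < 1 || y < 1) continue;
        ++nn;
        if (x == y) continue;
        // purines 1 (A), 3 (G); pyrimidines 2 (C), 4 (T)
        bool px = (x == 1 || x == 3), py = (y == 1 || y == 3);
        if (px == py) ++s; else ++v;
      }
      S(i, j) = S(j, i) = s;
      V(i, j) = V(j, i) = v;
      N(i, j) = N(j, i) = nn;
    }
    N(i, i) = L;
  }
  return List::create(_["s"] = S, _["v"] = V, _["n"] = N);
}

// Profile-profile global alignment with affine gaps ("once a gap, always a
// gap": existing columns are never split). Profiles are 6 x L count matrices,
// rows A, C, G, T, gap, other. Column-column score is the mean over residue
// pairs of match/mismatch, with pairs involving an existing gap scoring 0 and
// 'other' scoring mismatch against everything. New gap columns cost
// gap_open per column opened/extended (unscaled).
// Returns two 0/1 vectors: for each merged column, whether profile A (resp. B)
// contributes a column (1) or receives an all-gap column (0).
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix pa, NumericMatrix pb,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const int n = pa.ncol(), m = pb.ncol();
  double na = 0.0, nb = 0.0;
  for (int r = 0; r < 6; ++r) { na += pa(r, 0); nb += pb(r, 0); }
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
      tY((n + 1) * W, -1);

  // precompute column scores
  std::vector<double> cs(n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int r = 0; r < 4; ++r) {
        for (int q = 0; q < 4; ++q) {
          acc += pa(r, i) * pb(q, j) * (r == q ? match : mismatch);
        }
      }
      // 'other' (row 5) scores mismatch vs bases and vs itself; gaps score 0
      double oa = pa(5, i), ob = pb(5, j);
      double basesA = pa(0, i) + pa(1, i) + pa(2, i) + pa(3, i);
      double basesB = pb(0, j) + pb(1, j) + pb(2, j) + pb(3, j);
      acc += mismatch * (oa * (basesB + ob) + ob * basesA);
      cs[i * m + j] = acc / (na * nb);
    }
  }

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_ext;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_ext;
    tY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = cs[(i - 1) * m + (j - 1)];
      double best = M[d]; signed char bt = 0;
      if (X[d] > best) { best = X[d]; bt = 1; }
      if (Y[d] > best) { best = Y[d]; bt = 2; }
      M[c] = best + s; tM[c] = bt;

      double open_x = M[u] + gap_open;
      double ext_x = X[u] + gap_ext;
      double from_y = Y[u] + gap_open;
      best = open_x; bt = 0;
      if (ext_x > best) { best = ext_x; bt = 1; }
      if (from_y > best) { best = from_y; bt = 2; }
      X[c] = best; tX[c] = bt;

      double open_y = M[l] + gap_open;
      double from_x = X[l] + gap_open;
      double ext_y = Y[l] + gap_ext;
      best = open_y; bt = 0;
      if (from_x > best) { best = from_x; bt = 1; }
      if (ext_y > best) { best = ext_y; bt = 2; }
      Y[c] = best; tY[c] = bt;
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::vector<int> ua, ub; // reversed path
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) { ua.push_back(1); ub.push_back(1); state = tM[c]; --i; --j; }
    else if (state == 1) { ua.push_back(1); ub.push_back(0); state = tX[c]; --i; }
    else { ua.push_back(0); ub.push_back(1); state = tY[c]; --j; }
  }
  std::reverse(ua.begin(), ua.end());
  std::reverse(ub.begin(), ub.end());
  return List::create(_["use_a"] = wrap(ua), _["use_b"] = wrap(ub),
                      _["score"] = score);
}
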