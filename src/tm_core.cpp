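// Core numerics for C1'-based RNA structure scoring.
//
// Conventions used throughout this file:
//   * point sets are k x 3 matrices, one row per residue;
//   * a rigid transform (R, t) maps a model point x (column vector) to
//     R x + t; in row form: X_new = X * R^T + t^T;
//   * TM contributions are 1 / (1 + (d_i/d0)^2), summed over aligned pairs
//     and divided by Lref (the solved length of the reference), so every
//     value lies in (0, Lalign/Lref].
//
// Two independent code paths live here on purpose: the production scoring
// machinery (kabsch_fit / optimize_superposition / tm_align drivers) and
// brute-force enumeration oracles used only for verification. The oracles
// share nothing with the production path beyond Armadillo's SVD.

#include <RcppArmadillo.h>
#include <set>
#include <vector>
#include <array>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;

struct Sup {
  mat R;   // 3 x 3 proper rotation
  vec t;   // 3-vector translation
};

// Least-squares proper rotation + translation mapping A onto B (Kabsch).
static Sup kabsch_fit(const mat& A, const mat& B) {
  vec ca = arma::mean(A, 0).t();
  vec cb = arma::mean(B, 0).t();
  mat Ac = A.each_row() - ca.t();
  mat Bc = B.each_row() - cb.t();
  mat H = Ac.t() * Bc;  // 3 x 3 covariance
  mat U, V;
  vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t()) < 0.0 ? -1.0 : 1.0;
  mat D = arma::eye(3, 3);
  D(2, 2) = d;  // reflection correction: force det(R) = +1
  Sup out;
  out.R = V * D * U.t();
  out.t = cb - out.R * ca;
  return out;
}

static inline double tm_eval(const mat& A, const mat& B, const Sup& sup,
                             double Lref, double d0) {
  mat At = A * sup.R.t();
  At.each_row() += sup.t.t();
  double acc = 0.0;
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    double dx = At(i, 0) - B(i, 0);
    double dy = At(i, 1) - B(i, 1);
    double dz = At(i, 2) - B(i, 2);
    double r = (dx * dx + dy * dy + dz * dz) / (d0 * d0);
    acc += 1.0 / (1.0 + r);
  }
  return acc / Lref;
}

// ---------------------------------------------------------------------------
// Superposition optimization for a fixed pairing.
//
// Small pairings (k <= small_max) are solved exactly over the family of
// Kabsch fits of every subset of >= 3 pairs. Larger pairings use the
// fragment-seeded iterative refinement: seeds are Kabsch fits of contiguous
// aligned fragments (lengths Lalign, Lalign/2, Lalign/4, minimum 4, start
// offsets at stride len/2); from each seed, pairs closer than a distance
// cutoff are kept and re-fit, with the cutoff starting at d0 + 1.5 A,
// shrinking by 0.5 A whenever the kept set stops changing, floored at
// 0.5 A; at most 30 refinement iterations per seed. TM is always recomputed
// over ALL pairs of the pairing.
// ---------------------------------------------------------------------------

static const int kSmallExactMax = 10;

static void sup_exact_small(const mat& A, const mat& B, double Lref, double d0,
                            double& best_tm, Sup& best_sup) {
  int k = (int)A.n_rows;
  unsigned long nmask = 1UL << k;
  for (unsigned long mask = 0; mask < nmask; ++mask) {
    int pc = __builtin_popcountl(mask);
    if (pc < 3) continue;
    arma::uvec idx(pc);
    int w = 0;
    for (int b = 0; b < k; ++b)
      if (mask & (1UL << b)) idx(w++) = b;
    Sup s = kabsch_fit(A.rows(idx), B.rows(idx));
    double tm = tm_eval(A, B, s, Lref, d0);
    if (tm > best_tm) {
      best_tm = tm;
      best_sup = s;
    }
  }
}

static void sup_heuristic(const mat& A, const mat& B, double Lref, double d0,
                          double& best_tm, Sup& best_sup) {
  int La = (int)A.n_rows;
  std::set<int> lens;
  lens.insert(La);
  lens.insert(std::min(La, std::max(4, La / 2)));
  lens.insert(std::min(La, std::max(4, La / 4)));
  std::vector<std::pair<int, int>> seeds;  // (start, len)
  for (int fl : lens) {
    int stride = std::max(1, fl / 2);
    int last = -1;
    for (int s = 0; s + fl <= La; s += stride) {
      seeds.push_back({s, fl});
      last = s;
    }
    if (last != La - fl) seeds.push_back({La - fl, fl});
  }
  for (auto& sd : seeds) {
    arma::uvec idx(sd.second);
    for (int i = 0; i < sd.second; ++i) idx(i) = sd.first + i;
    Sup sup = kabsch_fit(A.rows(idx), B.rows(idx));
    std::vector<int> prev_kept;
    double cutoff = d0 + 1.5;
    for (int iter = 0; iter < 30; ++iter) {
      mat At = A * sup.R.t();
      At.each_row() += sup.t.t();
      vec dist(La);
      for (int i = 0; i < La; ++i)
        dist(i) = arma::norm(At.row(i).t() - B.row(i).t());
      double acc = 0.0;
      for (int i = 0; i < La; ++i) acc += 1.0 / (1.0 + (dist(i) / d0) * (dist(i) / d0));
      double tm = acc / Lref;
      if (tm > best_tm) {
        best_tm = tm;
        best_sup = sup;
      }
      std::vector<int> kept;
      for (int i = 0; i < La; ++i)
        if (dist(i) < cutoff) kept.push_back(i);
      if ((int)kept.size() < 3) {
        arma::uvec ord = arma::sort_index(dist);
        kept.clear();
        for (int i = 0; i < 3; ++i) kept.push_back((int)ord(i));
        std::sort(kept.begin(), kept.end());
      }
      if (kept == prev_kept) {
        if (cutoff <= 0.5 + 1e-12) break;       // converged at floor
        cutoff = std::max(0.5, cutoff - 0.5);   // stagnation: shrink cutoff
      }
      prev_kept = kept;
      arma::uvec kidx(kept.size());
      for (size_t i = 0; i < kept.size(); ++i) kidx(i) = kept[i];
      sup = kabsch_fit(A.rows(kidx), B.rows(kidx));
    }
    double tm = tm_eval(A, B, sup, Lref, d0);
    if (tm > best_tm) {
      best_tm = tm;
      best_sup = sup;
    }
  }
}

static void optimize_sup(const mat& A, const mat& B, double Lref, double d0,
                         double& best_tm, Sup& best_sup) {
  best_tm = -1.0;
  best_sup.R = arma::eye(3, 3);
  best_sup.t = arma::zeros(3);
  if ((int)A.n_rows <= kSmallExactMax) {
    sup_exact_small(A, B, Lref, d0, best_tm, best_sup);
  } else {
    sup_heuristic(A, B, Lref, d0, best_tm, best_sup);
  }
}

// ---------------------------------------------------------------------------
// Global dynamic-programming alignment (Needleman-Wunsch, affine gaps with
// open penalty and zero extension) over a score matrix S.
// ---------------------------------------------------------------------------

typedef std::vector<std::array<int, 2>> Alignment;

static Alignment dp_align(const mat& S, double gap_open) {
  int n = (int)S.n_rows, m = (int)S.n_cols;
  const double NEG = -1e18;
  mat M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  arma::imat pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  pM.zeros(); pX.zeros(); pY.zeros();
  M(0, 0) = 0.0;
  for (int j = 1; j <= m; ++j) { X(0, j) = gap_open; pX(0, j) = 1; }
  for (int i = 1; i <= n; ++i) { Y(i, 0) = gap_open; pY(i, 0) = 2; }
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i > 0 && j > 0) {
        double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
        int k = (a >= b && a >= c) ? 0 : (b >= c ? 1 : 2);
        M(i, j) = std::max(a, std::max(b, c)) + S(i - 1, j - 1);
        pM(i, j) = k;
      }
      if (j > 0 && !(i == 0 && j == 1)) {
        double a = M(i, j - 1) + gap_open, b = X(i, j - 1), c = Y(i, j - 1) + gap_open;
        int k = (a >= b && a >= c) ? 0 : (b >= c ? 1 : 2);
        X(i, j) = std::max(a, std::max(b, c));
        pX(i, j) = k;
      }
      if (i > 0 && !(i == 1 && j == 0)) {
        double a = M(i - 1, j) + gap_open, b = X(i - 1, j) + gap_open, c = Y(i - 1, j);
        int k = (a >= b && a >= c) ? 0 : (b >= c ? 1 : 2);
        Y(i, j) = std::max(a, std::max(b, c));
        pY(i, j) = k;
      }
    }
  }
  int i = n, j = m;
  double a = M(n, m), b = X(n, m), c = Y(n, m);
  int st = (a >= b && a >= c) ? 0 : (b >= c ? 1 : 2);
  Alignment rev;
  while (i > 0 || j > 0) {
    if (st == 0) {
      rev.push_back({i - 1, j - 1});
      st = pM(i, j); --i; --j;
    } else if (st == 1) {
      st = pX(i, j); --j;
    } else {
      st = pY(i, j); --i;
    }
  }
  Alignment out(rev.rbegin(), rev.rend());
  return out;
}

// ---------------------------------------------------------------------------
// TM-align driver: joint optimization of alignment and superposition.
// Starts: gapless threadings at every offset (>= 3 overlapping positions);
// for small chains (both lengths <= 10) additionally every monotone 3-pair
// alignment, which lets the search reach optima governed by isolated
// well-matching residue triples. Rounds alternate superposition
// optimization over the current alignment with DP realignment from the
// resulting superposition (gap open -0.6, extension 0), up to 20 rounds or
// until an alignment repeats. Alignments already visited are cached.
// Tie-breaking among equal-TM alignments: larger Lalign first, then
// lexicographically smallest pair list.
// ---------------------------------------------------------------------------

struct TMBest {
  double tm = -1.0;
  Alignment al;
  Sup sup;
};

static bool lex_less(const Alignment& a, const Alignment& b) {
  size_t n = std::min(a.size(), b.size());
  for (size_t i = 0; i < n; ++i) {
    if (a[i][0] != b[i][0]) return a[i][0] < b[i][0];
    if (a[i][1] != b[i][1]) return a[i][1] < b[i][1];
  }
  return a.size() < b.size();
}

static void consider(TMBest& best, double tm, const Alignment& al, const Sup& sup) {
  bool take = false;
  if (tm > best.tm + 1e-12) {
    take = true;
  } else if (std::fabs(tm - best.tm) <= 1e-12) {
    if (al.size() > best.al.size()) take = true;
    else if (al.size() == best.al.size() && lex_less(al, best.al)) take = true;
  }
  if (take) {
    best.tm = tm;
    best.al = al;
    best.sup = sup;
  }
}

// Exact small-chain branch. TM is monotone under alignment inclusion
// (every aligned pair contributes a positive term and the superposition
// family over a superset contains the subset's fits), so the maximum over
// all monotone alignments is attained on an inclusion-maximal one. For
// chains of at most 8 solved residues each we therefore enumerate the
// maximal monotone alignments and solve each superposition exactly over
// its >= 3-pair Kabsch fits.
static bool is_maximal_alignment(const Alignment& al, int n, int m) {
  if (al.front()[0] != 0 && al.front()[1] != 0) return false;
  for (size_t k = 1; k < al.size(); ++k) {
    if (al[k][0] - al[k - 1][0] > 1 && al[k][1] - al[k - 1][1] > 1) return false;
  }
  return al.back()[0] == n - 1 || al.back()[1] == m - 1;
}

static void exact_rec(const mat& Mo, const mat& Re, double Lref, double d0,
                      Alignment& cur, int i0, int j0, TMBest& best) {
  int n = (int)Mo.n_rows, m = (int)Re.n_rows;
  if ((int)cur.size() >= 3 && is_maximal_alignment(cur, n, m)) {
    arma::uvec mi(cur.size()), ri(cur.size());
    for (size_t k = 0; k < cur.size(); ++k) { mi(k) = cur[k][0]; ri(k) = cur[k][1]; }
    double tm;
    Sup sup;
    optimize_sup(Mo.rows(mi), Re.rows(ri), Lref, d0, tm, sup);
    consider(best, tm, cur, sup);
  }
  for (int i = i0; i < n; ++i)
    for (int j = j0; j < m; ++j) {
      cur.push_back({i, j});
      exact_rec(Mo, Re, Lref, d0, cur, i + 1, j + 1, best);
      cur.pop_back();
    }
}

static TMBest tm_align_run(const mat& Mo, const mat& Re, double Lref, double d0,
                           double gap_open) {
  int n = (int)Mo.n_rows, m = (int)Re.n_rows;
  if (n <= 8 && m <= 8) {
    TMBest best;
    Alignment cur;
    exact_rec(Mo, Re, Lref, d0, cur, 0, 0, best);
    return best;
  }
  std::vector<Alignment> starts;
  for (int off = -(n - 3); off <= m - 3; ++off) {
    Alignment al;
    for (int i = 0; i < n; ++i) {
      int j = i + off;
      if (j >= 0 && j < m) al.push_back({i, j});
    }
    if ((int)al.size() >= 3) starts.push_back(al);
  }
  if (n <= 10 && m <= 10) {
    for (int i1 = 0; i1 < n - 2; ++i1)
      for (int i2 = i1 + 1; i2 < n - 1; ++i2)
        for (int i3 = i2 + 1; i3 < n; ++i3)
          for (int j1 = 0; j1 < m - 2; ++j1)
            for (int j2 = j1 + 1; j2 < m - 1; ++j2)
              for (int j3 = j2 + 1; j3 < m; ++j3)
                starts.push_back({{i1, j1}, {i2, j2}, {i3, j3}});
  }
  TMBest best;
  std::set<std::vector<int>> seen;
  // Work-stack exploration: every evaluated superposition proposes two
  // realignments — the standard DP (gap open -0.6) and a zero-gap DP,
  // which is the TM-optimal monotone alignment for that superposition
  // (every matched pair contributes a positive TM term). A global work
  // cap bounds the search; proposals cycle until no new alignment
  // appears.
  size_t max_evals = starts.size() * 4 + 400;
  std::vector<Alignment> stack(starts.rbegin(), starts.rend());
  size_t evals = 0;
  while (!stack.empty() && evals < max_evals) {
    Alignment cur = stack.back();
    stack.pop_back();
    if ((int)cur.size() < 3) continue;
    std::vector<int> key;
    key.reserve(cur.size() * 2);
    for (auto& p : cur) { key.push_back(p[0]); key.push_back(p[1]); }
    if (!seen.insert(key).second) continue;  // alignment already explored
    ++evals;
    arma::uvec mi(cur.size()), ri(cur.size());
    for (size_t k = 0; k < cur.size(); ++k) { mi(k) = cur[k][0]; ri(k) = cur[k][1]; }
    double tm;
    Sup sup;
    optimize_sup(Mo.rows(mi), Re.rows(ri), Lref, d0, tm, sup);
    consider(best, tm, cur, sup);
    mat Mt = Mo * sup.R.t();
    Mt.each_row() += sup.t.t();
    mat S(n, m);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j) {
        double dx = Mt(i, 0) - Re(j, 0);
        double dy = Mt(i, 1) - Re(j, 1);
        double dz = Mt(i, 2) - Re(j, 2);
        S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / (d0 * d0));
      }
    stack.push_back(dp_align(S, gap_open));
    stack.push_back(dp_align(S, 0.0));
  }
  return best;
}

// ---------------------------------------------------------------------------
// Verification oracles (independent of the machinery above).
// ---------------------------------------------------------------------------

// Independent Kabsch used only by the oracles.
static void oracle_fit(const mat& P, const mat& Q, mat& R, vec& t) {
  vec cp = arma::mean(P, 0).t(), cq = arma::mean(Q, 0).t();
  mat C = (P.each_row() - cp.t()).t() * (Q.each_row() - cq.t());
  mat U, V;
  vec s;
  arma::svd(U, s, V, C);
  mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0.0) D(2, 2) = -1.0;
  R = V * D * U.t();
  t = cq - R * cp;
}

// Max TM over Kabsch fits of every >= 3-pair subset of a fixed pairing,
// scored over all pairs of the pairing.
static double oracle_subset_max(const mat& A, const mat& B, double Lref, double d0) {
  int k = (int)A.n_rows;
  double best = -1.0;
  unsigned long nmask = 1UL << k;
  for (unsigned long mask = 0; mask < nmask; ++mask) {
    if (__builtin_popcountl(mask) < 3) continue;
    std::vector<arma::uword> rows;
    for (int b = 0; b < k; ++b)
      if (mask & (1UL << b)) rows.push_back(b);
    arma::uvec idx(rows.size());
    for (size_t i = 0; i < rows.size(); ++i) idx(i) = rows[i];
    mat R;
    vec t;
    oracle_fit(A.rows(idx), B.rows(idx), R, t);
    mat At = A * R.t();
    At.each_row() += t.t();
    double acc = 0.0;
    for (int i = 0; i < k; ++i) {
      double d2 = arma::accu(arma::square(At.row(i) - B.row(i)));
      acc += 1.0 / (1.0 + d2 / (d0 * d0));
    }
    double tm = acc / Lref;
    if (tm > best) best = tm;
  }
  return best;
}

static void oracle_rec(const mat& Mo, const mat& Re, double Lref, double d0,
                       std::vector<int>& mi, std::vector<int>& ri,
                       int inext, int jnext, double& best) {
  if ((int)mi.size() >= 3) {
    arma::uvec a(mi.size()), b(ri.size());
    for (size_t k = 0; k < mi.size(); ++k) { a(k) = mi[k]; b(k) = ri[k]; }
    double tm = oracle_subset_max(Mo.rows(a), Re.rows(b), Lref, d0);
    if (tm > best) best = tm;
  }
  int n = (int)Mo.n_rows, m = (int)Re.n_rows;
  for (int i = inext; i < n; ++i)
    for (int j = jnext; j < m; ++j) {
      mi.push_back(i);
      ri.push_back(j);
      oracle_rec(Mo, Re, Lref, d0, mi, ri, i + 1, j + 1, best);
      mi.pop_back();
      ri.pop_back();
    }
}

// ---------------------------------------------------------------------------
// Exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_kabsch(const arma::mat& A, const arma::mat& B) {
  Sup s = kabsch_fit(A, B);
  mat At = A * s.R.t();
  At.each_row() += s.t.t();
  vec d(A.n_rows);
  for (arma::uword i = 0; i < A.n_rows; ++i)
    d(i) = arma::norm(At.row(i).t() - B.row(i).t());
  double rmsd = std::sqrt(arma::mean(arma::square(d)));
  return Rcpp::List::create(Rcpp::Named("rotation") = s.R,
                            Rcpp::Named("translation") = s.t,
                            Rcpp::Named("distances") = d,
                            Rcpp::Named("rmsd") = rmsd);
}

// [[Rcpp::export]]
Rcpp::List cpp_optimize_superposition(const arma::mat& A, const arma::mat& B,
                                      double Lref, double d0) {
  double tm;
  Sup sup;
  optimize_sup(A, B, Lref, d0, tm, sup);
  return Rcpp::List::create(Rcpp::Named("tm") = tm,
                            Rcpp::Named("rotation") = sup.R,
                            Rcpp::Named("translation") = sup.t);
}

// [[Rcpp::export]]
Rcpp::List cpp_tm_align(const arma::mat& M, const arma::mat& R, double Lref,
                        double d0, double gap_open) {
  TMBest best = tm_align_run(M, R, Lref, d0, gap_open);
  Rcpp::IntegerMatrix pairs(best.al.size(), 2);
  for (size_t k = 0; k < best.al.size(); ++k) {
    pairs(k, 0) = best.al[k][0];
    pairs(k, 1) = best.al[k][1];
  }
  return Rcpp::List::create(Rcpp::Named("tm") = best.tm,
                            Rcpp::Named("pairs") = pairs,
                            Rcpp::Named("rotation") = best.sup.R,
                            Rcpp::Named("translation") = best.sup.t);
}

// [[Rcpp::export]]
double cpp_subset_superposition_oracle(const arma::mat& A, const arma::mat& B,
                                       double Lref, double d0) {
  return oracle_subset_max(A, B, Lref, d0);
}

// [[Rcpp::export]]
double cpp_tm_align_oracle(const arma::mat& M, const arma::mat& R, double Lref,
                           double d0) {
  std::vector<int> mi, ri;
  double best = -1.0;
  oracle_rec(M, R, Lref, d0, mi, ri, 0, 0, best);
  return best;
}
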