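// Core numerics for the soft approximate-string-matching (ASM) layer:
// forward scoring recursions, span backtracking, and analytic gradients.
// All matrices follow the (M+1) x (L+1) dynamic-programming layout with
// row 0 / column 0 holding the boundary conditions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Smoothed max of three values.  The largest argument contributes exp(0)=1,
// so only the two others need exponentials; terms below exp(-37) are at
// machine precision relative to 1 and are skipped.
static inline double lse3(double a, double b, double c, double gamma) {
  double mx, x, y;
  if (a >= b) {
    if (a >= c) { mx = a; x = b; y = c; } else { mx = c; x = a; y = b; }
  } else {
    if (b >= c) { mx = b; x = a; y = c; } else { mx = c; x = a; y = b; }
  }
  const double cut = -37.0 * gamma;
  double s = 1.0;
  if (x > cut + mx) s += std::exp((x - mx) / gamma);
  if (y > cut + mx) s += std::exp((y - mx) / gamma);
  if (s == 1.0) return mx;
  return mx + gamma * std::log(s);
}

// Soft ASM scoring matrix for one pattern against a one-hot sequence.
// R = P %*% t(S) must be the M x L per-position reward matrix.
static arma::mat soft_asm_fill(const arma::mat& R, double g, double gamma) {
  const arma::uword M = R.n_rows, L = R.n_cols;
  arma::mat F(M + 1, L + 1);
  F.row(0).zeros();
  for (arma::uword m = 1; m <= M; ++m) F(m, 0) = -static_cast<double>(m) * g;
  for (arma::uword l = 1; l <= L; ++l) {
    for (arma::uword m = 1; m <= M; ++m) {
      F(m, l) = lse3(F(m - 1, l - 1) + R(m - 1, l - 1),
                     F(m - 1, l) - g,
                     F(m, l - 1) - g, gamma);
    }
  }
  return F;
}

// Hard max over the last row; ties resolved toward the smallest column.
// Returns the 0-based column index (= number of sequence positions consumed).
static arma::uword last_row_argmax(const arma::mat& F) {
  const arma::uword M = F.n_rows - 1, L = F.n_cols - 1;
  arma::uword best = 0;
  for (arma::uword l = 1; l <= L; ++l)
    if (F(M, l) > F(M, best)) best = l;
  return best;
}

// Backtrack from (M, lstar) picking at each cell the branch with the largest
// argument (ties: diagonal > up > left) until row 0 is reached.  Returns the
// first consumed column (0-based exclusive), i.e. the span is
// [lprime + 1, lstar] in 1-based sequence coordinates.
static arma::uword backtrack_start(const arma::mat& F, const arma::mat& R,
                                   double g, arma::uword lstar) {
  arma::uword m = F.n_rows - 1, l = lstar;
  while (m > 0) {
    if (l == 0) { --m; continue; }
    double diag = F(m - 1, l - 1) + R(m - 1, l - 1);
    double up = F(m - 1, l) - g;
    double left = F(m, l - 1) - g;
    if (diag >= up && diag >= left) { --m; --l; }
    else if (up >= left) { --m; }
    else { --l; }
  }
  return l;
}

// [[Rcpp::export]]
List soft_asm_cpp(const arma::mat& P, const arma::mat& S, double g,
                  double gamma) {
  arma::mat R = P * S.t();
  arma::mat F = soft_asm_fill(R, g, gamma);
  arma::uword lstar = last_row_argmax(F);
  return List::create(_["F"] = F,
                      _["v"] = F(F.n_rows - 1, lstar),
                      _["argmax_col"] = static_cast<int>(lstar));
}

// [[Rcpp::export]]
IntegerVector asm_span_cpp(const arma::mat& P, const arma::mat& S, double g,
                           double gamma) {
  arma::mat R = P * S.t();
  arma::mat F = soft_asm_fill(R, g, gamma);
  arma::uword lstar = last_row_argmax(F);
  arma::uword lprime = backtrack_start(F, R, g, lstar);
  return IntegerVector::create(static_cast<int>(lprime) + 1,
                               static_cast<int>(lstar));
}

// Differentiable NW matrix on a (sub)sequence: global boundary conditions,
// both leading gaps penalized.
static arma::mat diff_nw_fill(const arma::mat& R, double g, double gamma) {
  const arma::uword M = R.n_rows, L = R.n_cols;
  arma::mat F(M + 1, L + 1);
  for (arma::uword l = 0; l <= L; ++l) F(0, l) = -static_cast<double>(l) * g;
  for (arma::uword m = 1; m <= M; ++m) F(m, 0) = -static_cast<double>(m) * g;
  for (arma::uword l = 1; l <= L; ++l)
    for (arma::uword m = 1; m <= M; ++m)
      F(m, l) = lse3(F(m - 1, l - 1) + R(m - 1, l - 1),
                     F(m - 1, l) - g,
                     F(m, l - 1) - g, gamma);
  return F;
}

// [[Rcpp::export]]
arma::mat diff_nw_cpp(const arma::mat& P, const arma::mat& St, double g,
                      double gamma) {
  arma::mat R = P * St.t();
  return diff_nw_fill(R, g, gamma);
}

// Analytic gradient of F~(M, L) w.r.t. the pattern rows and the gap penalty.
// One forward fill, one backward sweep for E(m,l) = dF~(M,L)/dF~(m,l), and a
// forward accumulation for dF~(m,l)/dg.
static void grad_span_core(const arma::mat& P, const arma::mat& St, double g,
                           double gamma, arma::mat& dP, double& dg) {
  const arma::uword M = P.n_rows, L = St.n_rows;
  dP.zeros(M, 4);
  if (L == 0) {            // empty span: pattern fully deleted, score -M*g
    dg = -static_cast<double>(M);
    return;
  }
  arma::mat R = P * St.t();
  arma::mat F = diff_nw_fill(R, g, gamma);

  // Local softmax branch weights for every interior cell.
  arma::mat wd(M + 1, L + 1, arma::fill::zeros);
  arma::mat wu(M + 1, L + 1, arma::fill::zeros);
  arma::mat wl(M + 1, L + 1, arma::fill::zeros);
  for (arma::uword l = 1; l <= L; ++l) {
    for (arma::uword m = 1; m <= M; ++m) {
      wd(m, l) = std::exp((F(m - 1, l - 1) + R(m - 1, l - 1) - F(m, l)) / gamma);
      wu(m, l) = std::exp((F(m - 1, l) - g - F(m, l)) / gamma);
      wl(m, l) = std::exp((F(m, l - 1) - g - F(m, l)) / gamma);
    }
  }

  // Backward sweep: E(m,l) accumulates through the existing downstream
  // neighbours only; E(M,L) seeds the recursion with 1.
  arma::mat E(M + 1, L + 1, arma::fill::zeros);
  E(M, L) = 1.0;
  for (arma::uword mi = M + 1; mi-- > 0;) {
    for (arma::uword li = L + 1; li-- > 0;) {
      if (mi == M && li == L) continue;
      double e = 0.0;
      if (mi < M) e += E(mi + 1, li) * wu(mi + 1, li);
      if (li < L) e += E(mi, li + 1) * wl(mi, li + 1);
      if (mi < M && li < L) e += E(mi + 1, li + 1) * wd(mi + 1, li + 1);
      E(mi, li) = e;
    }
  }

  // dF~(m,l)/dp_m = wd(m,l) * s~_l ; chain through E.
  for (arma::uword m = 1; m <= M; ++m)
    for (arma::uword l = 1; l <= L; ++l)
      dP.row(m - 1) += E(m, l) * wd(m, l) * St.row(l - 1);

  // Forward accumulation of dF~(m,l)/dg with boundary seeds -m and -l.
  arma::mat D(M + 1, L + 1);
  for (arma::uword l = 0; l <= L; ++l) D(0, l) = -static_cast<double>(l);
  for (arma::uword m = 1; m <= M; ++m) D(m, 0) = -static_cast<double>(m);
  for (arma::uword l = 1; l <= L; ++l)
    for (arma::uword m = 1; m <= M; ++m)
      D(m, l) = wd(m, l) * D(m - 1, l - 1) +
                wu(m, l) * (D(m - 1, l) - 1.0) +
                wl(m, l) * (D(m, l - 1) - 1.0);
  dg = D(M, L);
}

// [[Rcpp::export]]
List grad_span_cpp(const arma::mat& P, const arma::mat& St, double g,
                   double gamma) {
  arma::mat dP;
  double dg = 0.0;
  grad_span_core(P, St, g, gamma, dP, dg);
  return List::create(_["dP"] = dP, _["dg"] = dg);
}

// ---- fast exp-domain forward pass -----------------------------------------
// The soft recursion is linear after the substitution E = exp(F / gamma):
//   E(m,l) = E(m-1,l-1) * W(m-1,l-1) + G * (E(m-1,l) + E(m,l-1)),
// with W = exp(R / gamma) and G = exp(-g / gamma).  The inner loop is then
// pure multiply-add; the only exponentials are exp(P / gamma) (gathered
// through one-hot sequence columns).  Valid only while exp(F / gamma) stays
// inside double range; callers must check fast_path_ok() and fall back to
// the log-domain recursion otherwise.  Both paths compute the same
// quantity, differing only in rounding.

static bool fast_path_ok(const arma::mat& P, double g, double gamma) {
  // |F| <= M * (max |reward| + g); rewards are convex combinations of
  // pattern entries, so max |reward| <= max |P|
  double amax = std::max(arma::abs(P).max(), g);
  return static_cast<double>(P.n_rows) * (amax + g) / gamma < 600.0;
}

// per-column base index for gather: 0..3 for a unit one-hot row, -1 otherwise
static arma::ivec onehot_index(const arma::mat& S) {
  arma::ivec idx(S.n_rows);
  for (arma::uword l = 0; l < S.n_rows; ++l) {
    idx(l) = -1;
    for (int j = 0; j < 4; ++j) {
      if (S(l, j) == 1.0) { idx(l) = j; break; }
    }
  }
  return idx;
}

static void exp_rewards(const arma::mat& P, const arma::mat& S,
                        const arma::ivec& idx, double gamma, arma::mat& W) {
  const arma::uword M = P.n_rows, L = S.n_rows;
  arma::mat eP = arma::exp(P / gamma);
  W.set_size(M, L);
  for (arma::uword l = 0; l < L; ++l) {
    if (idx(l) >= 0) {
      W.col(l) = eP.col(idx(l));
    } else {
      W.col(l) = arma::exp(P * S.row(l).t() / gamma);
    }
  }
}

static void soft_asm_fill_exp(const arma::mat& W, double G, arma::mat& E) {
  const arma::uword M = W.n_rows, L = W.n_cols;
  E.set_size(M + 1, L + 1);
  E.row(0).ones();
  double e0 = 1.0;
  for (arma::uword m = 1; m <= M; ++m) { e0 *= G; E(m, 0) = e0; }
  for (arma::uword l = 1; l <= L; ++l) {
    const double* Wc = W.colptr(l - 1);
    const double* Ep = E.colptr(l - 1);
    double* Ec = E.colptr(l);
    for (arma::uword m = 1; m <= M; ++m)
      Ec[m] = Ep[m - 1] * Wc[m - 1] + G * (Ec[m - 1] + Ep[m]);
  }
}

// backtrack in the exp domain (the domain map is strictly monotone, so the
// branch comparisons and tie order are the same as in the log domain)
static arma::uword backtrack_start_exp(const arma::mat& E, const arma::mat& W,
                                       double G, arma::uword lstar) {
  arma::uword m = E.n_rows - 1, l = lstar;
  while (m > 0) {
    if (l == 0) { --m; continue; }
    double diag = E(m - 1, l - 1) * W(m - 1, l - 1);
    double up = G * E(m - 1, l);
    double left = G * E(m, l - 1);
    if (diag >= up && diag >= left) { --m; --l; }
    else if (up >= left) { --m; }
    else { --l; }
  }
  return l;
}

// Embedding of one one-hot sequence under all N patterns.
// P is an M x 4 x N cube.  Returns v, u = ReLU(v + b), and (optionally) the
// best-match span per pattern.
static void embed_core(const arma::cube& P, const arma::mat& S, double g,
                       const arma::vec& b, double gamma, bool want_spans,
                       arma::vec& v, arma::vec& u, arma::imat& spans) {
  const arma::uword N = P.n_slices, M = P.n_rows, L = S.n_rows;
  v.set_size(N);
  u.set_size(N);
  if (want_spans) spans.set_size(N, 2);
  arma::ivec idx = onehot_index(S);
  arma::mat W, E;
  for (arma::uword n = 0; n < N; ++n) {
    const arma::mat& Pn = P.slice(n);
    if (fast_path_ok(Pn, g, gamma)) {
      exp_rewards(Pn, S, idx, gamma, W);
      double G = std::exp(-g / gamma);
      soft_asm_fill_exp(W, G, E);
      arma::uword lstar = 0;
      for (arma::uword l = 1; l <= L; ++l)
        if (E(M, l) > E(M, lstar)) lstar = l;
      v(n) = gamma * std::log(E(M, lstar));
      if (want_spans) {
        arma::uword lprime = backtrack_start_exp(E, W, G, lstar);
        spans(n, 0) = static_cast<arma::sword>(lprime) + 1;
        spans(n, 1) = static_cast<arma::sword>(lstar);
      }
    } else {
      arma::mat R = Pn * S.t();
      arma::mat F = soft_asm_fill(R, g, gamma);
      arma::uword lstar = last_row_argmax(F);
      v(n) = F(M, lstar);
      if (want_spans) {
        arma::uword lprime = backtrack_start(F, R, g, lstar);
        spans(n, 0) = static_cast<arma::sword>(lprime) + 1;
        spans(n, 1) = static_cast<arma::sword>(lstar);
      }
    }
  }
  u = v + b;
  u.transform([](double x) { return x > 0.0 ? x : 0.0; });
}

// [[Rcpp::export]]
List embed_cpp(const arma::cube& P, const arma::mat& S, double g,
               const arma::vec& b, double gamma, bool want_spans) {
  arma::vec v, u;
  arma::imat spans;
  embed_core(P, S, g, b, gamma, want_spans, v, u, spans);
  List out = List::create(_["v"] = v, _["u"] = u);
  if (want_spans) out["spans"] = spans;
  return out;
}

// [[Rcpp::export]]
arma::mat embed_batch_cpp(const List& Slist, const arma::cube& P, double g,
                          const arma::vec& b, double gamma) {
  const arma::uword n = Slist.size();
  arma::mat out(n, P.n_slices);
  arma::vec v, u;
  arma::imat spans;
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat S = as<arma::mat>(Slist[i]);
    embed_core(P, S, g, b, gamma, false, v, u, spans);
    out.row(i) = u.t();
  }
  return out;
}

// Cosine embedding distance with epsilon-guarded norms; gradient w.r.t. u1
// written into g1 (zero-norm vectors get the zero subgradient).
static double cos_dist_grad(const arma::vec& u1, const arma::vec& u2,
                            arma::vec& g1, arma::vec& g2) {
  const double eps = 1e-8;
  double n1 = arma::norm(u1), n2 = arma::norm(u2);
  double denom = (n1 + eps) * (n2 + eps);
  double dt = arma::dot(u1, u2);
  double de = 1.0 - dt / denom;
  g1 = -u2 / denom;
  g2 = -u1 / denom;
  if (n1 > 0) g1 += dt / (n1 * (n1 + eps) * denom) * u1;
  if (n2 > 0) g2 += dt / (n2 * (n2 + eps) * denom) * u2;
  return de;
}

// [[Rcpp::export]]
double cosine_distance_cpp(const arma::vec& u1, const arma::vec& u2) {
  arma::vec g1, g2;
  return cos_dist_grad(u1, u2, g1, g2);
}

// Full per-pair backward pass: squared error of the cosine embedding
// distance against the target alignment distance, chained through the ReLU
// and the span-restricted differentiable NW into pattern/gap/bias gradients.
// Both Siamese branches share parameters, so contributions are summed.
// [[Rcpp::export]]
List pair_backward_cpp(const arma::cube& P, const arma::mat& S1,
                       const arma::mat& S2, double g, const arma::vec& b,
                       double gamma, double d_a) {
  const arma::uword N = P.n_slices, M = P.n_rows;
  arma::vec v1, u1, v2, u2;
  arma::imat sp1, sp2;
  embed_core(P, S1, g, b, gamma, true, v1, u1, sp1);
  embed_core(P, S2, g, b, gamma, true, v2, u2, sp2);

  arma::vec gu1, gu2;
  double de = cos_dist_grad(u1, u2, gu1, gu2);
  double loss = (de - d_a) * (de - d_a);
  double dde = 2.0 * (de - d_a);
  gu1 *= dde;
  gu2 *= dde;

  arma::cube dP(M, 4, N, arma::fill::zeros);
  arma::vec db(N, arma::fill::zeros);
  double dg = 0.0;
  arma::mat dPn;
  double dgn;

  for (arma::uword n = 0; n < N; ++n) {
    for (int side = 0; side < 2; ++side) {
      const arma::mat& S = side == 0 ? S1 : S2;
      const arma::vec& v = side == 0 ? v1 : v2;
      const arma::vec& gu = side == 0 ? gu1 : gu2;
      const arma::imat& sp = side == 0 ? sp1 : sp2;
      if (v(n) + b(n) <= 0.0) continue;  // ReLU mask
      double dv = gu(n);
      db(n) += dv;
      if (dv == 0.0) continue;
      arma::sword a = sp(n, 0), z = sp(n, 1);
      if (a > z) {                        // empty span: all-gap limit
        dg += dv * (-static_cast<double>(M));
        continue;
      }
      arma::mat St = S.rows(a - 1, z - 1);
      grad_span_core(P.slice(n), St, g, gamma, dPn, dgn);
      dP.slice(n) += dv * dPn;
      dg += dv * dgn;
    }
  }
  return List::create(_["loss"] = loss, _["de"] = de, _["dP"] = dP,
                      _["dg"] = dg, _["db"] = db);
}

// Hard ASM (integer edit-distance form): F(0,l) = 0, F(m,0) = -m,
// interior max of {diag - c, up - 1, left - 1} with c = 0 on a base match.
// [[Rcpp::export]]
List hard_asm_cpp(const std::string& pattern, const std::string& seq) {
  const int M = pattern.size(), L = seq.size();
  arma::imat F(M + 1, L + 1);
  for (int l = 0; l <= L; ++l) F(0, l) = 0;
  for (int m = 1; m <= M; ++m) F(m, 0) = -m;
  for (int l = 1; l <= L; ++l) {
    for (int m = 1; m <= M; ++m) {
      int c = pattern[m - 1] == seq[l - 1] ? 0 : 1;
      int best = F(m - 1, l - 1) - c;
      if (F(m - 1, l) - 1 > best) best = F(m - 1, l) - 1;
      if (F(m, l - 1) - 1 > best) best = F(m, l - 1) - 1;
      F(m, l) = best;
    }
  }
  int lstar = 0;
  for (int l = 1; l <= L; ++l)
    if (F(M, l) > F(M, lstar)) lstar = l;
  // backtrack, ties diagonal > up > left
  int m = M, l = lstar;
  while (m > 0) {
    if (l == 0) { --m; continue; }
    int c = pattern[m - 1] == seq[l - 1] ? 0 : 1;
    int diag = F(m - 1, l - 1) - c;
    int up = F(m - 1, l) - 1;
    int left = F(m, l - 1) - 1;
    if (diag >= up && diag >= left) { --m; --l; }
    else if (up >= left) { --m; }
    else { --l; }
  }
  return List::create(_["min_edit_distance"] = -F(M, lstar),
                      _["span"] = IntegerVector::create(l + 1, lstar));
}
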