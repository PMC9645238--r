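// Affine-gap (Gotoh three-state) global alignment.  Convention: a gap run of
// length k costs gap_open + (k - 1) * gap_extend, i.e. the opening score
// covers the first gapped column.  Traceback is deterministic with state
// preference M (diagonal) > Ix (up, gap in b) > Iy (left, gap in a).
#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static const double NEG_INF = -1e30;

static inline bool plain_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct NWOut {
  std::string aligned_a, aligned_b;
  double score;
  double distance;
};

// pick among three candidate scores with preference M > Ix > Iy at ties
static inline int argmax3(double m, double x, double y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

static NWOut nw_core(const std::string& a, const std::string& b, double match,
                     double mismatch, double gap_open, double gap_extend,
                     bool traceback) {
  const int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  // traceback: predecessor state (0=M, 1=Ix, 2=Iy) per state matrix
  std::vector<signed char> tM, tIx, tIy;
  if (traceback) {
    tM.assign((n + 1) * (m + 1), -1);
    tIx.assign((n + 1) * (m + 1), -1);
    tIy.assign((n + 1) * (m + 1), -1);
  }
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    if (traceback) tIx[at(i, 0)] = i == 1 ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[at(0, j)] = gap_open + (j - 1) * gap_extend;
    if (traceback) tIy[at(0, j)] = j == 1 ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = a[i - 1] == b[j - 1] ? match : mismatch;
      // M: diagonal move from any state
      {
        double cm = M[at(i - 1, j - 1)], cx = Ix[at(i - 1, j - 1)],
               cy = Iy[at(i - 1, j - 1)];
        int k = argmax3(cm, cx, cy);
        double best = k == 0 ? cm : (k == 1 ? cx : cy);
        M[at(i, j)] = best + s;
        if (traceback) tM[at(i, j)] = (signed char)k;
      }
      // Ix: consume a[i-1] against a gap
      {
        double cm = M[at(i - 1, j)] + gap_open;
        double cx = Ix[at(i - 1, j)] + gap_extend;
        double cy = Iy[at(i - 1, j)] + gap_open;
        int k = argmax3(cm, cx, cy);
        Ix[at(i, j)] = k == 0 ? cm : (k == 1 ? cx : cy);
        if (traceback) tIx[at(i, j)] = (signed char)k;
      }
      // Iy: consume b[j-1] against a gap
      {
        double cm = M[at(i, j - 1)] + gap_open;
        double cx = Ix[at(i, j - 1)] + gap_open;
        double cy = Iy[at(i, j - 1)] + gap_extend;
        int k = argmax3(cm, cx, cy);
        Iy[at(i, j)] = k == 0 ? cm : (k == 1 ? cx : cy);
        if (traceback) tIy[at(i, j)] = (signed char)k;
      }
    }
  }

  NWOut out;
  int state = argmax3(M[at(n, m)], Ix[at(n, m)], Iy[at(n, m)]);
  out.score = state == 0 ? M[at(n, m)] : (state == 1 ? Ix[at(n, m)] : Iy[at(n, m)]);
  out.distance = NA_REAL;
  if (!traceback) return out;

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = tM[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tIx[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      prev = tIy[at(i, j)];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int ident = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] == rb[k] && plain_base(ra[k])) ++ident;
  out.aligned_a = ra;
  out.aligned_b = rb;
  out.distance = 1.0 - (double)ident / (double)ra.size();
  return out;
}

// [[Rcpp::export]]
List nw_align_cpp(const std::string& a, const std::string& b, double match,
                  double mismatch, double gap_open, double gap_extend) {
  NWOut r = nw_core(a, b, match, mismatch, gap_open, gap_extend, true);
  return List::create(_["aligned_a"] = r.aligned_a, _["aligned_b"] = r.aligned_b,
                      _["score"] = r.score, _["distance"] = r.distance);
}

// Batch alignment distances for index pairs (1-based) into seqs.
// [[Rcpp::export]]
List nw_pairs_cpp(const std::vector<std::string>& seqs,
                  const IntegerVector& ia, const IntegerVector& ib,
                  double match, double mismatch, double gap_open,
                  double gap_extend) {
  const int np = ia.size();
  NumericVector score(np), dist(np);
  for (int k = 0; k < np; ++k) {
    NWOut r = nw_core(seqs[ia[k] - 1], seqs[ib[k] - 1], match, mismatch,
                      gap_open, gap_extend, true);
    score[k] = r.score;
    dist[k] = r.distance;
  }
  return List::create(_["score"] = score, _["distance"] = dist);
}

// Score-only query x reference matrix (rolling rows, no traceback).
// [[Rcpp::export]]
NumericMatrix nw_score_matrix_cpp(const std::vector<std::string>& queries,
                                  const std::vector<std::string>& refs,
                                  double match, double mismatch,
                                  double gap_open, double gap_extend) {
  NumericMatrix out(queries.size(), refs.size());
  for (size_t qi = 0; qi < queries.size(); ++qi) {
    const std::string& a = queries[qi];
    for (size_t ri = 0; ri < refs.size(); ++ri) {
      const std::string& b = refs[ri];
      const int n = a.size(), m = b.size();
      std::vector<double> Mp(m + 1, NEG_INF), Xp(m + 1, NEG_INF),
          Yp(m + 1, NEG_INF);
      std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
      Mp[0] = 0.0;
      for (int j = 1; j <= m; ++j) Yp[j] = gap_open + (j - 1) * gap_extend;
      for (int i = 1; i <= n; ++i) {
        Mc[0] = NEG_INF;
        Yc[0] = NEG_INF;
        Xc[0] = gap_open + (i - 1) * gap_extend;
        for (int j = 1; j <= m; ++j) {
          double s = a[i - 1] == b[j - 1] ? match : mismatch;
          Mc[j] = s + std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
          Xc[j] = std::max(Mp[j] + gap_open,
                           std::max(Xp[j] + gap_extend, Yp[j] + gap_open));
          Yc[j] = std::max(Mc[j - 1] + gap_open,
                           std::max(Xc[j - 1] + gap_open, Yc[j - 1] + gap_extend));
        }
        std::swap(Mp, Mc);
        std::swap(Xp, Xc);
        std::swap(Yp, Yc);
      }
      out(qi, ri) = std::max(Mp[m], std::max(Xp[m], Yp[m]));
    }
  }
  return out;
}
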