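// Brute-force oracles: literal enumeration of every substring pair and
// every legal gapped alignment between them, each scored directly from
// the score definition (delta for query pairs with both endpoints
// aligned, gamma for other matched columns, h + s*L per maximal gap
// run).  Deliberately shares no logic with the DP engine: this is the
// ground truth the engine is certified against on small inputs.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Problem {
  std::vector<int> S, T;       // 0-based codes
  std::vector<int> partner;    // 1-based partner or 0
  double gamma[4][4];
  double delta[256];
  double h, s;
};

// score an explicit alignment; columns are (query pos or 0, target pos
// or 0), 1-based; the query substring is [xs..ys]
static double score_alignment(const Problem& P, const std::vector<int>& qc,
                              const std::vector<int>& tc, int xs, int ys) {
  int r = (int)qc.size();
  double sc = 0.0;
  // column of each query position
  std::vector<int> colof(P.S.size() + 2, -1);
  for (int c = 0; c < r; ++c)
    if (qc[c] > 0) colof[qc[c]] = c;
  std::vector<bool> asPair(r, false);
  for (int i = xs; i <= ys; ++i) {
    int j = (i >= 1 && i <= (int)P.partner.size()) ? P.partner[i - 1] : 0;
    if (j > i && j <= ys) {  // pair fully inside the substring
      int ci = colof[i], cj = colof[j];
      if (tc[ci] > 0 && tc[cj] > 0) {
        sc += P.delta[((P.S[i - 1] * 4 + P.S[j - 1]) * 4 +
                       P.T[tc[ci] - 1]) * 4 + P.T[tc[cj] - 1]];
        asPair[ci] = asPair[cj] = true;
      }
    }
  }
  for (int c = 0; c < r; ++c)
    if (qc[c] > 0 && tc[c] > 0 && !asPair[c])
      sc += P.gamma[P.S[qc[c] - 1]][P.T[tc[c] - 1]];
  // affine gap penalty: h per maximal run (in either string), s per space
  int k = 0, l = 0;
  for (int c = 0; c < r; ++c) {
    if (qc[c] == 0) { ++l; if (c == 0 || qc[c - 1] != 0) ++k; }
    if (tc[c] == 0) { ++l; if (c == 0 || tc[c - 1] != 0) ++k; }
  }
  return sc - k * P.h - l * P.s;
}

struct Best {
  double score;
  std::vector<int> qc, tc;
  Best() : score(-1e30) {}
  void offer(double v, const std::vector<int>& q, const std::vector<int>& t) {
    if (v > score) { score = v; qc = q; tc = t; }
  }
};

// enumerate all global alignments of S[xs..ys] vs T[xt..yt]
template <class F>
static void enum_alignments(const Problem& P, int xs, int ys, int xt, int yt,
                            std::vector<int>& qc, std::vector<int>& tc,
                            int i, int j, F&& visit) {
  if (i > ys && j > yt) { visit(qc, tc); return; }
  if (i <= ys && j <= yt) {
    qc.push_back(i); tc.push_back(j);
    enum_alignments(P, xs, ys, xt, yt, qc, tc, i + 1, j + 1, visit);
    qc.pop_back(); tc.pop_back();
  }
  if (i <= ys) {
    qc.push_back(i); tc.push_back(0);
    enum_alignments(P, xs, ys, xt, yt, qc, tc, i + 1, j, visit);
    qc.pop_back(); tc.pop_back();
  }
  if (j <= yt) {
    qc.push_back(0); tc.push_back(j);
    enum_alignments(P, xs, ys, xt, yt, qc, tc, i, j + 1, visit);
    qc.pop_back(); tc.pop_back();
  }
}

static Problem make_problem(const IntegerVector& q, const IntegerMatrix& pairs,
                            const IntegerVector& t, const NumericVector& gamma,
                            const NumericVector& delta, double h, double s) {
  Problem P;
  P.S.assign(q.begin(), q.end());
  P.T.assign(t.begin(), t.end());
  P.partner.assign(std::max((int)q.size(), 1), 0);
  for (int r = 0; r < pairs.nrow(); ++r) {
    P.partner[pairs(r, 0) - 1] = pairs(r, 1);
    P.partner[pairs(r, 1) - 1] = pairs(r, 0);
  }
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      P.gamma[i][j] = gamma[i + 4 * j];
  for (int i = 0; i < 256; ++i) {
    int u1 = i % 4, u2 = (i / 4) % 4, v1 = (i / 16) % 4, v2 = i / 64;
    P.delta[((u1 * 4 + u2) * 4 + v1) * 4 + v2] = delta[i];
  }
  P.h = h; P.s = s;
  return P;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_brute")]]
List cpp_brute(IntegerVector q, IntegerMatrix pairs, IntegerVector t,
               NumericVector gamma, NumericVector delta,
               double h, double s, std::string mode) {
  Problem P = make_problem(q, pairs, t, gamma, delta, h, s);
  int m = (int)P.S.size(), n = (int)P.T.size();
  Best best;
  std::vector<int> qc, tc;
  auto run = [&](int xs, int ys, int xt, int yt) {
    enum_alignments(P, xs, ys, xt, yt, qc, tc, xs, xt,
      [&](const std::vector<int>& a, const std::vector<int>& b) {
        best.offer(score_alignment(P, a, b, xs, ys), a, b);
      });
  };
  if (mode == "global") {
    run(1, m, 1, n);
  } else if (mode == "semiglobal") {
    for (int xs = 1; xs <= m + 1; ++xs)
      for (int ys = xs - 1; ys <= m; ++ys) {
        if (xs > ys && xs != 1) continue;  // one canonical empty substring
        run(xs, ys, 1, n);
      }
  } else {  // local
    for (int xs = 1; xs <= m + 1; ++xs)
      for (int ys = xs - 1; ys <= m; ++ys) {
        if (xs > ys && xs != 1) continue;
        for (int xt = 1; xt <= n + 1; ++xt)
          for (int yt = xt - 1; yt <= n; ++yt) {
            if (xt > yt && xt != 1) continue;
            run(xs, ys, xt, yt);
          }
      }
  }
  return List::create(_["score"] = best.score,
                      _["qcols"] = IntegerVector(best.qc.begin(), best.qc.end()),
                      _["tcols"] = IntegerVector(best.tc.begin(), best.tc.end()));
}

// Component tables at the top interval, by enumeration, for auditing the
// engine's A1 (nine boundary cases), A2/A3 (boundary-state buckets),
// A4 and A tables.  Boundary states: 1 = char/char, 2 = query char vs
// space, 3 = space vs target char (paper's case numbering is the 3x3
// product of these for A1).
// [[Rcpp::export(name = ".cpp_brute_tables")]]
List cpp_brute_tables(IntegerVector q, IntegerMatrix pairs, IntegerVector t,
                      NumericVector gamma, NumericVector delta,
                      double h, double s) {
  Problem P = make_problem(q, pairs, t, gamma, delta, h, s);
  int m = (int)P.S.size(), n = (int)P.T.size();
  int nr = n + 1;
  auto newmat = [&]() {
    NumericMatrix M(nr, nr);
    std::fill(M.begin(), M.end(), NA_REAL);
    return M;
  };
  List A1(9), A2(4), A3(4);
  std::vector<NumericMatrix> a1m, a2m, a3m;
  for (int c = 0; c < 9; ++c) { a1m.push_back(newmat()); A1[c] = a1m[c]; }
  for (int c = 0; c < 4; ++c) { a2m.push_back(newmat()); A2[c] = a2m[c]; }
  for (int c = 0; c < 4; ++c) { a3m.push_back(newmat()); A3[c] = a3m[c]; }
  NumericMatrix A4 = newmat(), Am = newmat();
  auto upd = [](NumericMatrix& M, int e, int f, double v) {
    double cur = M(e - 1, f);
    if (NumericVector::is_na(cur) || ISNAN(cur) || v > cur) M(e - 1, f) = v;
  };
  std::vector<int> qc, tc;
  for (int e = 1; e <= n + 1; ++e)
    for (int f = e - 1; f <= n; ++f) {
      // initialize feasible cells to -Inf
      for (int c = 0; c < 9; ++c) a1m[c](e - 1, f) = R_NegInf;
      for (int c = 0; c < 4; ++c) {
        a2m[c](e - 1, f) = R_NegInf;
        a3m[c](e - 1, f) = R_NegInf;
      }
      A4(e - 1, f) = R_NegInf;
      Am(e - 1, f) = R_NegInf;
      // closed form buckets (empty prefix/suffix against the whole slice)
      double cf = f >= e ? -(h + s * (f - e + 1)) : 0.0;
      a2m[3](e - 1, f) = cf;
      a3m[3](e - 1, f) = cf;
      for (int xs = 1; xs <= m + 1; ++xs)
        for (int ys = xs - 1; ys <= m; ++ys) {
          if (xs > ys && xs != 1) continue;
          enum_alignments(P, xs, ys, e, f, qc, tc, xs, e,
            [&](const std::vector<int>& a, const std::vector<int>& b) {
              double v = score_alignment(P, a, b, xs, ys);
              int r = (int)a.size();
              // boundary states of first/last column (0-based M/T/Q)
              int Ls = -1, Rs = -1;
              if (r > 0) {
                Ls = a[0] > 0 ? (b[0] > 0 ? 0 : 1) : 2;
                Rs = a[r - 1] > 0 ? (b[r - 1] > 0 ? 0 : 1) : 2;
              }
              bool emptyq = (xs > ys);
              if (!emptyq && xs == 1 && ys == m && m >= 1)
                upd(a1m[Ls * 3 + Rs], e, f, v);
              if (xs == 1 && ys <= m - 1) {   // prefix bucket (A2)
                if (r > 0) upd(a2m[Ls], e, f, v);
              }
              if (ys == m && xs >= 2) {       // suffix bucket (A3)
                if (r > 0) upd(a3m[Rs], e, f, v);
              }
              bool inner = (xs >= 2 && ys <= m - 1) || emptyq;
              if (inner) upd(A4, e, f, v);
              upd(Am, e, f, v);
            });
          if (xs > ys) {
            // the empty substring is canonicalized as (1, 0); it also
            // feeds the suffix (A3) state-Q bucket
            enum_alignments(P, xs, ys, e, f, qc, tc, xs, e,
              [&](const std::vector<int>& a, const std::vector<int>& b) {
                double v = score_alignment(P, a, b, xs, ys);
                if (!a.empty()) upd(a3m[2], e, f, v);
              });
          }
        }
    }
  return List::create(_["A1"] = A1, _["A2"] = A2, _["A3"] = A3,
                      _["A4"] = A4, _["A"] = Am, _["m"] = m, _["n"] = n);
}
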