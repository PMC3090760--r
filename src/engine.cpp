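// Dynamic programming engine for local/global/semi-global structural
// alignment of a query RNA (known regular secondary structure) against a
// target of unknown structure, under the affine gap model h + s*L.
//
// The query is decomposed into O(m) intervals (PAIRED / SPLIT / UNPAIRED
// cases driven by the structure).  Per interval and per target slice
// (e,f) we keep boundary-state-resolved tables; the boundary state of a
// column is one of
//   M : query char aligned to target char
//   T : query char aligned to a space        ("S[x] with space")
//   Q : space aligned to a target char       ("T[x] with space")
//   N : the zero-column (empty) alignment
// Tables per interval (p,q):
//   G[L][R]  global  S[p..q]   vs all of T[e..f], first/last column states
//   P[ls]    prefix-global  (prefix of S[p..q-1], possibly empty) vs T[e..f],
//            keyed by first-column state; P[Q] includes the all-gap
//            empty-prefix closed form -h - s*(f-e+1)
//   R[rs]    suffix-global  (suffix of S[p+1..q]) vs T[e..f], keyed by
//            last-column state (mirror of P)
//   Sg       semi-global on the inner interval S[p+1..q-1] (scalar)
//   A        = max over all of the above (computed on demand)
// Affine bookkeeping: extending a gap run costs s, opening costs h+s;
// when two partial alignments are joined at a split point and the
// touching boundary columns are the same gap type, the two runs are one
// maximal run, so the doubly-charged h is added back.
//
// Traceback re-derives the achieving candidate at every cell with the
// exact arithmetic of the fill, so no backpointers are stored.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <functional>
#include <algorithm>
using namespace Rcpp;

static const int SM = 0, ST = 1, SQ = 2, SN = 3;
static const double NEG = -1e30;
static const double NEG_GUARD = -1e25;

struct Node {
  int p, q;           // 1-based inclusive; EMPTY node has p > q
  int type;           // 0 = UNPAIRED, 1 = PAIRED, 2 = SPLIT, 3 = EMPTY
  int c1, c2;         // child node indices (-1 when absent)
  int qp;             // split point q' for SPLIT
  int refcount;
  bool filled, freed;
  std::vector<double> G;   // 16 * SZ2  (L*4+R)
  std::vector<double> P;   // 4 * SZ2
  std::vector<double> Rr;  // 4 * SZ2
  std::vector<double> Sg;  // SZ2
};

struct Workspace {
  int m, n;
  std::vector<int> S, T;        // 0-based codes 0..3
  double gamma[4][4];
  double delta[256];
  double h, s, open, ext;
  bool retain;
  std::vector<Node> nodes;
  int top;
  int SZ2;

  inline int sid(int e, int f) const { return (e - 1) * (n + 1) + f; }
  inline double gam(int qi, int tj) const { return gamma[S[qi - 1]][T[tj - 1]]; }
  inline double del(int qi, int qj, int ti, int tj) const {
    return delta[((S[qi - 1] * 4 + S[qj - 1]) * 4 + T[ti - 1]) * 4 + T[tj - 1]];
  }
  inline double chT(int st) const { return st == ST ? ext : open; }
  inline double chQ(int st) const { return st == SQ ? ext : open; }
  // gap-run merge bonus at a join between boundary states a (left's last
  // column) and b (right's first column)
  inline bool mergeable(int a, int b) const {
    return a == b && (a == ST || a == SQ);
  }
};

// ---------------------------------------------------------------------
// decomposition (mirrors the R-level decompose())

static int build_nodes(Workspace& W, int p, int q,
                       std::map<std::pair<int, int>, int>& memo,
                       const std::vector<int>& partner) {
  if (p > q) { p = 1; q = 0; }  // canonical EMPTY node
  auto key = std::make_pair(p, q);
  auto it = memo.find(key);
  if (it != memo.end()) { W.nodes[it->second].refcount++; return it->second; }
  Node nd;
  nd.p = p; nd.q = q; nd.c1 = nd.c2 = -1; nd.qp = 0;
  nd.refcount = 1; nd.filled = false; nd.freed = false;
  if (p > q) {
    nd.type = 3;
  } else {
    int j = partner[p - 1];
    if (j > q || j < p) j = 0;
    if (j == q) {
      nd.type = 1;
    } else if (j > p) {
      nd.type = 2; nd.qp = j;
    } else {
      nd.type = 0;
    }
  }
  W.nodes.push_back(nd);
  int idx = (int)W.nodes.size() - 1;
  memo[key] = idx;
  if (W.nodes[idx].type == 1) {
    int c = build_nodes(W, p + 1, q - 1, memo, partner);
    W.nodes[idx].c1 = c;
  } else if (W.nodes[idx].type == 2) {
    int qp = W.nodes[idx].qp;
    int a = build_nodes(W, p, qp, memo, partner);
    int b = build_nodes(W, qp + 1, q, memo, partner);
    W.nodes[idx].c1 = a; W.nodes[idx].c2 = b;
  } else if (W.nodes[idx].type == 0) {
    int c = build_nodes(W, p + 1, q, memo, partner);
    W.nodes[idx].c1 = c;
  }
  return idx;
}

// ---------------------------------------------------------------------
// table fill

static void alloc_node(Workspace& W, Node& nd) {
  nd.G.assign(16 * W.SZ2, NEG);
  nd.P.assign(4 * W.SZ2, NEG);
  nd.Rr.assign(4 * W.SZ2, NEG);
  nd.Sg.assign(W.SZ2, NEG);
}

static void free_node(Node& nd) {
  std::vector<double>().swap(nd.G);
  std::vector<double>().swap(nd.P);
  std::vector<double>().swap(nd.Rr);
  std::vector<double>().swap(nd.Sg);
  nd.freed = true;
}

static void fill_empty(Workspace& W, Node& nd) {
  // empty query interval: only the all-gap (Q-run) and zero-column
  // alignments exist.  Closed form accumulated incrementally so that the
  // arithmetic matches the generic Q-peel chains elsewhere.
  const int n = W.n;
  for (int e = 1; e <= n + 1; ++e) {
    int id0 = W.sid(e, e - 1);
    nd.G[(SN * 4 + SN) * W.SZ2 + id0] = 0.0;
    nd.P[SN * W.SZ2 + id0] = 0.0;
    nd.Rr[SN * W.SZ2 + id0] = 0.0;
    nd.Sg[id0] = 0.0;
    double cf = 0.0;
    for (int f = e; f <= n; ++f) {
      cf = (f == e) ? -W.open : cf - W.ext;
      int id = W.sid(e, f);
      nd.G[(SQ * 4 + SQ) * W.SZ2 + id] = cf;
      nd.P[SQ * W.SZ2 + id] = cf;
      nd.Rr[SQ * W.SZ2 + id] = cf;
      nd.Sg[id] = cf;
    }
  }
}

static void fill_node(Workspace& W, int ni);

// best over all stored tables: the semi-global score A(p,q,e,f)
static double nodeA(const Workspace& W, const Node& nd, int e, int f) {
  int id = W.sid(e, f);
  double best = NEG;
  for (int st = 0; st < 16; ++st) best = std::max(best, nd.G[st * W.SZ2 + id]);
  for (int st = 0; st < 4; ++st) {
    best = std::max(best, nd.P[st * W.SZ2 + id]);
    best = std::max(best, nd.Rr[st * W.SZ2 + id]);
  }
  best = std::max(best, nd.Sg[id]);
  return best;
}

static void fill_unpaired(Workspace& W, Node& nd) {
  const int n = W.n, SZ2 = W.SZ2;
  const Node& C = W.nodes[nd.c1];
  const double* cG = C.G.data();
  const double* cP = C.P.data();
  const double* cR = C.Rr.data();
  const double* cSg = C.Sg.data();
  double* G = nd.G.data();
  double* P = nd.P.data();
  double* R = nd.Rr.data();
  double* Sg = nd.Sg.data();
  const bool single = (nd.p == nd.q);   // prefix range S[p..q-1] empty
  for (int len = 0; len <= n; ++len) {
    for (int e = 1; e + len - 1 <= n; ++e) {
      int f = e + len - 1;
      int id = W.sid(e, f);
      // ---- G ----
      if (len >= 1) {
        double gpe = W.gam(nd.p, e);
        int idr = W.sid(e + 1, f);  // target rest after consuming T[e]
        for (int Rs = 0; Rs < 3; ++Rs) {
          double best = NEG;
          for (int L = 0; L < 3; ++L)
            best = std::max(best, cG[(L * 4 + Rs) * SZ2 + idr]);
          if (Rs == SM)
            best = std::max(best, cG[(SN * 4 + SN) * SZ2 + idr]);
          G[(SM * 4 + Rs) * SZ2 + id] = gpe + best;
        }
      }
      for (int Rs = 0; Rs < 3; ++Rs) {
        double best = NEG;
        for (int L = 0; L < 3; ++L)
          best = std::max(best, cG[(L * 4 + Rs) * SZ2 + id] - W.chT(L));
        if (Rs == ST)
          best = std::max(best, cG[(SN * 4 + SN) * SZ2 + id] - W.open);
        G[(ST * 4 + Rs) * SZ2 + id] = best;
      }
      if (len >= 1) {
        int idr = W.sid(e + 1, f);
        for (int Rs = 0; Rs < 3; ++Rs) {
          double best = NEG;
          for (int L = 0; L < 3; ++L)
            best = std::max(best, G[(L * 4 + Rs) * SZ2 + idr] - W.chQ(L));
          G[(SQ * 4 + Rs) * SZ2 + id] = best;
        }
      }
      // ---- P ----
      if (!single) {
        int idr = (len >= 1) ? W.sid(e + 1, f) : -1;
        if (len >= 1) {
          double gpe = W.gam(nd.p, e);
          double best = NEG;
          for (int ls = 0; ls < 4; ++ls)
            best = std::max(best, cP[ls * SZ2 + idr]);
          P[SM * SZ2 + id] = gpe + best;
        }
        {
          double best = NEG;
          for (int ls = 0; ls < 4; ++ls)
            best = std::max(best, cP[ls * SZ2 + id] - W.chT(ls));
          P[ST * SZ2 + id] = best;
        }
      }
      if (len >= 1) {
        int idr = W.sid(e + 1, f);
        double best = NEG;
        for (int ls = 0; ls < 4; ++ls)
          best = std::max(best, P[ls * SZ2 + idr] - W.chQ(ls));
        P[SQ * SZ2 + id] = best;
      }
      if (len == 0) P[SN * SZ2 + id] = 0.0;
      // ---- R : suffix-global over the full child range ----
      for (int rs = 0; rs < 3; ++rs) {
        double best = cR[rs * SZ2 + id];
        for (int L = 0; L < 3; ++L)
          best = std::max(best, cG[(L * 4 + rs) * SZ2 + id]);
        R[rs * SZ2 + id] = best;
      }
      if (len == 0) R[SN * SZ2 + id] = 0.0;
      // ---- Sg : best substring of the child range not ending at q ----
      {
        double best = cSg[id];
        for (int ls = 0; ls < 4; ++ls)
          best = std::max(best, cP[ls * SZ2 + id]);
        Sg[id] = best;
      }
    }
  }
}

static void fill_paired(Workspace& W, Node& nd) {
  const int n = W.n, SZ2 = W.SZ2;
  const Node& C = W.nodes[nd.c1];
  const double* cG = C.G.data();
  const double* cP = C.P.data();
  const double* cR = C.Rr.data();
  const double* cSg = C.Sg.data();
  double* G = nd.G.data();
  double* P = nd.P.data();
  double* R = nd.Rr.data();
  double* Sg = nd.Sg.data();
  const int NN = SN * 4 + SN;
  for (int len = 0; len <= n; ++len) {
    for (int e = 1; e + len - 1 <= n; ++e) {
      int f = e + len - 1;
      int id = W.sid(e, f);
      // ---- G structural: both boundary columns peeled ----
      {  // (T,T): S[p] and S[q] both with space
        double best = NEG;
        for (int L = 0; L < 3; ++L)
          for (int Rs = 0; Rs < 3; ++Rs)
            best = std::max(best,
              cG[(L * 4 + Rs) * SZ2 + id] - W.chT(L) - W.chT(Rs));
        // empty inner: the two spaces form one run of length 2
        best = std::max(best, cG[NN * SZ2 + id] - W.open - W.ext);
        G[(ST * 4 + ST) * SZ2 + id] = best;
      }
      if (len >= 1) {
        {  // (M,T)
          int idr = W.sid(e + 1, f);
          double gpe = W.gam(nd.p, e);
          double best = NEG;
          for (int L = 0; L < 3; ++L)
            for (int Rs = 0; Rs < 3; ++Rs)
              best = std::max(best,
                cG[(L * 4 + Rs) * SZ2 + idr] - W.chT(Rs));
          best = std::max(best, cG[NN * SZ2 + idr] - W.open);
          G[(SM * 4 + ST) * SZ2 + id] = gpe + best;
        }
        {  // (T,M)
          int idr = W.sid(e, f - 1);
          double gqf = W.gam(nd.q, f);
          double best = NEG;
          for (int L = 0; L < 3; ++L)
            for (int Rs = 0; Rs < 3; ++Rs)
              best = std::max(best,
                cG[(L * 4 + Rs) * SZ2 + idr] - W.chT(L));
          best = std::max(best, cG[NN * SZ2 + idr] - W.open);
          G[(ST * 4 + SM) * SZ2 + id] = gqf + best;
        }
      }
      if (len >= 2) {  // (M,M): the base pair aligned to T[e], T[f]
        int idr = W.sid(e + 1, f - 1);
        double dv = W.del(nd.p, nd.q, e, f);
        double best = NEG;
        for (int L = 0; L < 3; ++L)
          for (int Rs = 0; Rs < 3; ++Rs)
            best = std::max(best, cG[(L * 4 + Rs) * SZ2 + idr]);
        best = std::max(best, cG[NN * SZ2 + idr]);
        G[(SM * 4 + SM) * SZ2 + id] = dv + best;
      }
      if (len >= 1) {
        // generic right peel for (M,Q), (T,Q)
        int idl = W.sid(e, f - 1);
        for (int L = 0; L < 2; ++L) {
          double best = NEG;
          for (int Rs = 0; Rs < 3; ++Rs)
            best = std::max(best, G[(L * 4 + Rs) * SZ2 + idl] - W.chQ(Rs));
          G[(L * 4 + SQ) * SZ2 + id] = best;
        }
        // generic left peel for (Q,*)
        int idr = W.sid(e + 1, f);
        for (int Rs = 0; Rs < 3; ++Rs) {
          double best = NEG;
          for (int L = 0; L < 3; ++L)
            best = std::max(best, G[(L * 4 + Rs) * SZ2 + idr] - W.chQ(L));
          G[(SQ * 4 + Rs) * SZ2 + id] = best;
        }
      }
      // ---- P : prefix of S[p..q-1]; rest is a proper prefix of the
      //          inner interval (child P) or the whole inner (child G)
      if (len >= 1) {
        int idr = W.sid(e + 1, f);
        double gpe = W.gam(nd.p, e);
        double best = NEG;
        for (int ls = 0; ls < 4; ++ls)
          best = std::max(best, cP[ls * SZ2 + idr]);
        for (int st = 0; st < 16; ++st)
          best = std::max(best, cG[st * SZ2 + idr]);
        P[SM * SZ2 + id] = gpe + best;
      }
      {
        double best = NEG;
        for (int ls = 0; ls < 4; ++ls)
          best = std::max(best, cP[ls * SZ2 + id] - W.chT(ls));
        for (int L = 0; L < 4; ++L)
          for (int Rs = 0; Rs < 4; ++Rs)
            best = std::max(best, cG[(L * 4 + Rs) * SZ2 + id] - W.chT(L));
        P[ST * SZ2 + id] = best;
      }
      if (len >= 1) {
        int idr = W.sid(e + 1, f);
        double best = NEG;
        for (int ls = 0; ls < 4; ++ls)
          best = std::max(best, P[ls * SZ2 + idr] - W.chQ(ls));
        P[SQ * SZ2 + id] = best;
      }
      if (len == 0) P[SN * SZ2 + id] = 0.0;
      // ---- R : suffix of S[p+1..q]; mirror of P ----
      if (len >= 1) {
        int idl = W.sid(e, f - 1);
        double gqf = W.gam(nd.q, f);
        double best = NEG;
        for (int rs = 0; rs < 4; ++rs)
          best = std::max(best, cR[rs * SZ2 + idl]);
        for (int st = 0; st < 16; ++st)
          best = std::max(best, cG[st * SZ2 + idl]);
        R[SM * SZ2 + id] = gqf + best;
      }
      {
        double best = NEG;
        for (int rs = 0; rs < 4; ++rs)
          best = std::max(best, cR[rs * SZ2 + id] - W.chT(rs));
        for (int L = 0; L < 4; ++L)
          for (int Rs = 0; Rs < 4; ++Rs)
            best = std::max(best, cG[(L * 4 + Rs) * SZ2 + id] - W.chT(Rs));
        R[ST * SZ2 + id] = best;
      }
      if (len >= 1) {
        int idl = W.sid(e, f - 1);
        double best = NEG;
        for (int rs = 0; rs < 4; ++rs)
          best = std::max(best, R[rs * SZ2 + idl] - W.chQ(rs));
        R[SQ * SZ2 + id] = best;
      }
      if (len == 0) R[SN * SZ2 + id] = 0.0;
      // ---- Sg = semi-global on the inner interval = child's A ----
      {
        double best = cSg[id];
        for (int st = 0; st < 16; ++st) best = std::max(best, cG[st * SZ2 + id]);
        for (int st = 0; st < 4; ++st) {
          best = std::max(best, cP[st * SZ2 + id]);
          best = std::max(best, cR[st * SZ2 + id]);
        }
        Sg[id] = best;
      }
    }
  }
}

static void fill_split(Workspace& W, Node& nd) {
  const int n = W.n, SZ2 = W.SZ2;
  const Node& A = W.nodes[nd.c1];   // (p, q') -- PAIRED
  const Node& B = W.nodes[nd.c2];   // (q'+1, q)
  const double* aG = A.G.data();
  const double* aP = A.P.data();
  const double* aR = A.Rr.data();
  const double* aSg = A.Sg.data();
  const double* bG = B.G.data();
  const double* bP = B.P.data();
  const double* bR = B.Rr.data();
  const double* bSg = B.Sg.data();
  double* G = nd.G.data();
  double* P = nd.P.data();
  double* R = nd.Rr.data();
  double* Sg = nd.Sg.data();
  const double h = W.h;
  for (int len = 0; len <= n; ++len) {
    for (int e = 1; e + len - 1 <= n; ++e) {
      int f = e + len - 1;
      int id = W.sid(e, f);
      double bestG[9];
      double bestPM = NEG, bestPT = NEG;
      double bestRM = NEG, bestRT = NEG;
      double bestSg = NEG;
      for (int x = 0; x < 9; ++x) bestG[x] = NEG;
      for (int k = e - 1; k <= f; ++k) {
        int idl = W.sid(e, k);
        int idr = W.sid(k + 1, f);
        // G join: all of T split at k, gap runs merged across the join
        double la[3], laT[3], laQ[3], rb[3], rbT[3], rbQ[3];
        for (int L = 0; L < 3; ++L) {
          double b0 = aG[(L * 4 + SM) * SZ2 + idl];
          double b1 = aG[(L * 4 + ST) * SZ2 + idl];
          double b2 = aG[(L * 4 + SQ) * SZ2 + idl];
          la[L] = std::max(b0, std::max(b1, b2));
          laT[L] = b1; laQ[L] = b2;
        }
        for (int Rs = 0; Rs < 3; ++Rs) {
          double b0 = bG[(SM * 4 + Rs) * SZ2 + idr];
          double b1 = bG[(ST * 4 + Rs) * SZ2 + idr];
          double b2 = bG[(SQ * 4 + Rs) * SZ2 + idr];
          rb[Rs] = std::max(b0, std::max(b1, b2));
          rbT[Rs] = b1; rbQ[Rs] = b2;
        }
        for (int L = 0; L < 3; ++L)
          for (int Rs = 0; Rs < 3; ++Rs) {
            double v = la[L] + rb[Rs];
            v = std::max(v, laT[L] + rbT[Rs] + h);
            v = std::max(v, laQ[L] + rbQ[Rs] + h);
            bestG[L * 3 + Rs] = std::max(bestG[L * 3 + Rs], v);
          }
        // P join: whole left child + prefix of the right child
        {
          double pb = NEG, pbT, pbQ;
          for (int lr = 0; lr < 4; ++lr)
            pb = std::max(pb, bP[lr * SZ2 + idr]);
          pbT = bP[ST * SZ2 + idr];
          pbQ = bP[SQ * SZ2 + idr];
          for (int L = 0; L < 2; ++L) {   // outer ls in {M, T}
            double v = la[L] + pb;
            v = std::max(v, laT[L] + pbT + h);
            v = std::max(v, laQ[L] + pbQ + h);
            if (L == SM) bestPM = std::max(bestPM, v);
            else bestPT = std::max(bestPT, v);
          }
        }
        // R join: suffix of the left child + whole right child
        {
          double ra = NEG, raT, raQ;
          for (int rl = 0; rl < 4; ++rl)
            ra = std::max(ra, aR[rl * SZ2 + idl]);
          raT = aR[ST * SZ2 + idl];
          raQ = aR[SQ * SZ2 + idl];
          for (int Rs = 0; Rs < 2; ++Rs) {  // outer rs in {M, T}
            double v = ra + rb[Rs];
            v = std::max(v, raT + rbT[Rs] + h);
            v = std::max(v, raQ + rbQ[Rs] + h);
            if (Rs == SM) bestRM = std::max(bestRM, v);
            else bestRT = std::max(bestRT, v);
          }
          // Sg join: suffix of left + prefix of right (substring
          // spanning the split, not touching p or q)
          double pb = NEG, pbT, pbQ;
          for (int lr = 0; lr < 4; ++lr)
            pb = std::max(pb, bP[lr * SZ2 + idr]);
          pbT = bP[ST * SZ2 + idr];
          pbQ = bP[SQ * SZ2 + idr];
          double v = ra + pb;
          v = std::max(v, raT + pbT + h);
          v = std::max(v, raQ + pbQ + h);
          bestSg = std::max(bestSg, v);
        }
      }
      for (int L = 0; L < 3; ++L)
        for (int Rs = 0; Rs < 3; ++Rs)
          G[(L * 4 + Rs) * SZ2 + id] = bestG[L * 3 + Rs];
      // P: prefix entirely inside the left child
      bestPM = std::max(bestPM, aP[SM * SZ2 + id]);
      bestPT = std::max(bestPT, aP[ST * SZ2 + id]);
      P[SM * SZ2 + id] = bestPM;
      P[ST * SZ2 + id] = bestPT;
      if (len >= 1) {
        int idr2 = W.sid(e + 1, f);
        double best = NEG;
        for (int ls = 0; ls < 4; ++ls)
          best = std::max(best, P[ls * SZ2 + idr2] - W.chQ(ls));
        P[SQ * SZ2 + id] = best;
      }
      if (len == 0) P[SN * SZ2 + id] = 0.0;
      // R: suffix entirely inside the right child
      {
        double bm = bestRM, bt = bestRT;
        bm = std::max(bm, bR[SM * SZ2 + id]);
        bt = std::max(bt, bR[ST * SZ2 + id]);
        for (int L = 0; L < 3; ++L) {
          bm = std::max(bm, bG[(L * 4 + SM) * SZ2 + id]);
          bt = std::max(bt, bG[(L * 4 + ST) * SZ2 + id]);
        }
        R[SM * SZ2 + id] = bm;
        R[ST * SZ2 + id] = bt;
      }
      if (len >= 1) {
        int idl2 = W.sid(e, f - 1);
        double best = NEG;
        for (int rs = 0; rs < 4; ++rs)
          best = std::max(best, R[rs * SZ2 + idl2] - W.chQ(rs));
        R[SQ * SZ2 + id] = best;
      }
      if (len == 0) R[SN * SZ2 + id] = 0.0;
      // Sg: substring inside the left child / inside the right child /
      // spanning the split
      {
        double best = bestSg;
        best = std::max(best, aSg[id]);
        best = std::max(best, bSg[id]);
        for (int rl = 0; rl < 4; ++rl)
          best = std::max(best, aR[rl * SZ2 + id]);
        for (int lr = 0; lr < 4; ++lr)
          best = std::max(best, bP[lr * SZ2 + id]);
        Sg[id] = best;
      }
    }
  }
}

static void fill_node(Workspace& W, int ni) {
  Node& nd = W.nodes[ni];
  if (nd.filled) return;
  // children first
  if (nd.c1 >= 0) fill_node(W, nd.c1);
  if (nd.c2 >= 0) fill_node(W, nd.c2);
  alloc_node(W, nd);
  switch (nd.type) {
    case 3: fill_empty(W, nd); break;
    case 0: fill_unpaired(W, nd); break;
    case 1: fill_paired(W, nd); break;
    case 2: fill_split(W, nd); break;
  }
  nd.filled = true;
  // release children that no parent still needs
  if (!W.retain) {
    int kids[2] = { nd.c1, nd.c2 };
    for (int t = 0; t < 2; ++t) {
      if (kids[t] < 0) continue;
      Node& c = W.nodes[kids[t]];
      if (--c.refcount <= 0 && kids[t] != W.top) free_node(c);
    }
  }
}

// ---------------------------------------------------------------------
// traceback by re-derivation.  Columns are appended as (query position
// or 0, target position or 0).

struct TraceOut {
  std::vector<int> qc, tc;
  void col(int qi, int ti) { qc.push_back(qi); tc.push_back(ti); }
};

static void trace_cell(Workspace& W, int ni, int tab, int a, int b,
                       int e, int f, TraceOut& out);
// tab: 0 = G (a = L, b = R), 1 = P (a = ls), 2 = R (a = rs), 3 = Sg, 4 = A

static void trace_fail(const char* where) {
  Rcpp::stop(std::string("straln internal traceback inconsistency in ") + where);
}

static inline bool eq(double x, double y) { return x == y; }

static void trace_empty(Workspace& W, const Node& nd, int tab, int a,
                        int e, int f, TraceOut& out) {
  (void)W; (void)tab; (void)a; (void)nd;
  for (int t = e; t <= f; ++t) out.col(0, t);
}

static void trace_A(Workspace& W, int ni, int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  int id = W.sid(e, f);
  double v = nodeA(W, nd, e, f);
  // tie-break: A1 (paper's nine cases in order), then A2, A3, A4
  static const int ord[9][2] = { {SM,SM},{SM,ST},{SM,SQ},{ST,SM},{ST,ST},
                                 {ST,SQ},{SQ,SM},{SQ,ST},{SQ,SQ} };
  for (int c = 0; c < 9; ++c)
    if (eq(nd.G[(ord[c][0] * 4 + ord[c][1]) * W.SZ2 + id], v)) {
      trace_cell(W, ni, 0, ord[c][0], ord[c][1], e, f, out); return;
    }
  if (eq(nd.G[(SN * 4 + SN) * W.SZ2 + id], v)) return;  // zero columns
  static const int sord[4] = { SM, ST, SQ, SN };
  for (int c = 0; c < 4; ++c)
    if (eq(nd.P[sord[c] * W.SZ2 + id], v)) {
      trace_cell(W, ni, 1, sord[c], 0, e, f, out); return;
    }
  for (int c = 0; c < 4; ++c)
    if (eq(nd.Rr[sord[c] * W.SZ2 + id], v)) {
      trace_cell(W, ni, 2, sord[c], 0, e, f, out); return;
    }
  if (eq(nd.Sg[id], v)) { trace_cell(W, ni, 3, 0, 0, e, f, out); return; }
  trace_fail("A");
}

static void trace_G_unpaired(Workspace& W, int ni, int L, int R,
                             int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  const Node& C = W.nodes[nd.c1];
  int SZ2 = W.SZ2;
  int id = W.sid(e, f);
  double v = nd.G[(L * 4 + R) * SZ2 + id];
  if (L == SM) {
    int idr = W.sid(e + 1, f);
    double gpe = W.gam(nd.p, e);
    for (int Lc = 0; Lc < 3; ++Lc)
      if (eq(v, gpe + C.G[(Lc * 4 + R) * SZ2 + idr])) {
        out.col(nd.p, e);
        trace_cell(W, nd.c1, 0, Lc, R, e + 1, f, out);
        return;
      }
    if (R == SM && eq(v, gpe + C.G[(SN * 4 + SN) * SZ2 + idr])) {
      out.col(nd.p, e); return;
    }
  } else if (L == ST) {
    for (int Lc = 0; Lc < 3; ++Lc)
      if (eq(v, C.G[(Lc * 4 + R) * SZ2 + id] - W.chT(Lc))) {
        out.col(nd.p, 0);
        trace_cell(W, nd.c1, 0, Lc, R, e, f, out);
        return;
      }
    if (R == ST && eq(v, C.G[(SN * 4 + SN) * SZ2 + id] - W.open)) {
      out.col(nd.p, 0); return;
    }
  } else {  // L == SQ: generic left peel within this node
    int idr = W.sid(e + 1, f);
    for (int Lc = 0; Lc < 3; ++Lc)
      if (eq(v, nd.G[(Lc * 4 + R) * SZ2 + idr] - W.chQ(Lc))) {
        out.col(0, e);
        trace_cell(W, ni, 0, Lc, R, e + 1, f, out);
        return;
      }
  }
  trace_fail("G/unpaired");
}

static void trace_G_paired(Workspace& W, int ni, int L, int R,
                           int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  const Node& C = W.nodes[nd.c1];
  int SZ2 = W.SZ2;
  int id = W.sid(e, f);
  const int NN = SN * 4 + SN;
  double v = nd.G[(L * 4 + R) * SZ2 + id];
  if (L == SM && R == SM) {
    int idr = W.sid(e + 1, f - 1);
    double dv = W.del(nd.p, nd.q, e, f);
    for (int Lc = 0; Lc < 3; ++Lc)
      for (int Rc = 0; Rc < 3; ++Rc)
        if (eq(v, dv + C.G[(Lc * 4 + Rc) * SZ2 + idr])) {
          out.col(nd.p, e);
          trace_cell(W, nd.c1, 0, Lc, Rc, e + 1, f - 1, out);
          out.col(nd.q, f);
          return;
        }
    if (eq(v, dv + C.G[NN * SZ2 + idr])) {
      out.col(nd.p, e); out.col(nd.q, f); return;
    }
  } else if (L == SM && R == ST) {
    int idr = W.sid(e + 1, f);
    double gpe = W.gam(nd.p, e);
    for (int Lc = 0; Lc < 3; ++Lc)
      for (int Rc = 0; Rc < 3; ++Rc)
        if (eq(v, gpe + (C.G[(Lc * 4 + Rc) * SZ2 + idr] - W.chT(Rc)))) {
          out.col(nd.p, e);
          trace_cell(W, nd.c1, 0, Lc, Rc, e + 1, f, out);
          out.col(nd.q, 0);
          return;
        }
    if (eq(v, gpe + (C.G[NN * SZ2 + idr] - W.open))) {
      out.col(nd.p, e); out.col(nd.q, 0); return;
    }
  } else if (L == ST && R == SM) {
    int idr = W.sid(e, f - 1);
    double gqf = W.gam(nd.q, f);
    for (int Lc = 0; Lc < 3; ++Lc)
      for (int Rc = 0; Rc < 3; ++Rc)
        if (eq(v, gqf + (C.G[(Lc * 4 + Rc) * SZ2 + idr] - W.chT(Lc)))) {
          out.col(nd.p, 0);
          trace_cell(W, nd.c1, 0, Lc, Rc, e, f - 1, out);
          out.col(nd.q, f);
          return;
        }
    if (eq(v, gqf + (C.G[NN * SZ2 + idr] - W.open))) {
      out.col(nd.p, 0); out.col(nd.q, f); return;
    }
  } else if (L == ST && R == ST) {
    for (int Lc = 0; Lc < 3; ++Lc)
      for (int Rc = 0; Rc < 3; ++Rc)
        if (eq(v, C.G[(Lc * 4 + Rc) * SZ2 + id] - W.chT(Lc) - W.chT(Rc))) {
          out.col(nd.p, 0);
          trace_cell(W, nd.c1, 0, Lc, Rc, e, f, out);
          out.col(nd.q, 0);
          return;
        }
    if (eq(v, C.G[NN * SZ2 + id] - W.open - W.ext)) {
      out.col(nd.p, 0); out.col(nd.q, 0); return;
    }
  } else if (L != SQ && R == SQ) {
    int idl = W.sid(e, f - 1);
    for (int Rc = 0; Rc < 3; ++Rc)
      if (eq(v, nd.G[(L * 4 + Rc) * SZ2 + idl] - W.chQ(Rc))) {
        trace_cell(W, ni, 0, L, Rc, e, f - 1, out);
        out.col(0, f);
        return;
      }
  } else {  // L == SQ
    int idr = W.sid(e + 1, f);
    for (int Lc = 0; Lc < 3; ++Lc)
      if (eq(v, nd.G[(Lc * 4 + R) * SZ2 + idr] - W.chQ(Lc))) {
        out.col(0, e);
        trace_cell(W, ni, 0, Lc, R, e + 1, f, out);
        return;
      }
  }
  trace_fail("G/paired");
}

static void trace_G_split(Workspace& W, int ni, int L, int R,
                          int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  const Node& A = W.nodes[nd.c1];
  const Node& B = W.nodes[nd.c2];
  int SZ2 = W.SZ2;
  double v = nd.G[(L * 4 + R) * SZ2 + W.sid(e, f)];
  for (int k = e - 1; k <= f; ++k) {
    int idl = W.sid(e, k);
    int idr = W.sid(k + 1, f);
    for (int Rl = 0; Rl < 3; ++Rl)
      for (int Lr = 0; Lr < 3; ++Lr) {
        double lv = A.G[(L * 4 + Rl) * SZ2 + idl];
        double rv = B.G[(Lr * 4 + R) * SZ2 + idr];
        double cand = lv + rv;
        if (W.mergeable(Rl, Lr)) cand = cand + W.h;
        if (eq(v, cand)) {
          trace_cell(W, nd.c1, 0, L, Rl, e, k, out);
          trace_cell(W, nd.c2, 0, Lr, R, k + 1, f, out);
          return;
        }
        // also accept the non-merged pairing when states match but the
        // fill kept the plain sum (cannot happen: merged is larger);
      }
  }
  trace_fail("G/split");
}

static void trace_P(Workspace& W, int ni, int ls, int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  int SZ2 = W.SZ2;
  int id = W.sid(e, f);
  double v = nd.P[ls * SZ2 + id];
  if (ls == SN) return;  // empty prefix, empty target
  if (ls == SQ) {        // generic: leading space against T[e]
    int idr = W.sid(e + 1, f);
    if (nd.type == 3) { trace_empty(W, nd, 1, ls, e, f, out); return; }
    for (int lc = 0; lc < 4; ++lc)
      if (eq(v, nd.P[lc * SZ2 + idr] - W.chQ(lc))) {
        out.col(0, e);
        trace_cell(W, ni, 1, lc, 0, e + 1, f, out);
        return;
      }
    trace_fail("P/Q");
  }
  if (nd.type == 3) { trace_empty(W, nd, 1, ls, e, f, out); return; }
  const Node& C = W.nodes[nd.c1 >= 0 ? nd.c1 : ni];
  if (nd.type == 0) {  // UNPAIRED
    if (ls == SM) {
      int idr = W.sid(e + 1, f);
      double gpe = W.gam(nd.p, e);
      for (int lc = 0; lc < 4; ++lc)
        if (eq(v, gpe + C.P[lc * SZ2 + idr])) {
          out.col(nd.p, e);
          trace_cell(W, nd.c1, 1, lc, 0, e + 1, f, out);
          return;
        }
    } else {  // ST
      for (int lc = 0; lc < 4; ++lc)
        if (eq(v, C.P[lc * SZ2 + id] - W.chT(lc))) {
          out.col(nd.p, 0);
          trace_cell(W, nd.c1, 1, lc, 0, e, f, out);
          return;
        }
    }
    trace_fail("P/unpaired");
  } else if (nd.type == 1) {  // PAIRED
    if (ls == SM) {
      int idr = W.sid(e + 1, f);
      double gpe = W.gam(nd.p, e);
      for (int lc = 0; lc < 4; ++lc)
        if (eq(v, gpe + C.P[lc * SZ2 + idr])) {
          out.col(nd.p, e);
          trace_cell(W, nd.c1, 1, lc, 0, e + 1, f, out);
          return;
        }
      for (int Lc = 0; Lc < 4; ++Lc)
        for (int Rc = 0; Rc < 4; ++Rc)
          if (eq(v, gpe + C.G[(Lc * 4 + Rc) * SZ2 + idr])) {
            out.col(nd.p, e);
            trace_cell(W, nd.c1, 0, Lc, Rc, e + 1, f, out);
            return;
          }
    } else {  // ST
      for (int lc = 0; lc < 4; ++lc)
        if (eq(v, C.P[lc * SZ2 + id] - W.chT(lc))) {
          out.col(nd.p, 0);
          trace_cell(W, nd.c1, 1, lc, 0, e, f, out);
          return;
        }
      for (int Lc = 0; Lc < 4; ++Lc)
        for (int Rc = 0; Rc < 4; ++Rc)
          if (eq(v, C.G[(Lc * 4 + Rc) * SZ2 + id] - W.chT(Lc))) {
            out.col(nd.p, 0);
            trace_cell(W, nd.c1, 0, Lc, Rc, e, f, out);
            return;
          }
    }
    trace_fail("P/paired");
  } else {  // SPLIT
    const Node& A = W.nodes[nd.c1];
    const Node& B = W.nodes[nd.c2];
    if (eq(v, A.P[ls * SZ2 + id])) {
      trace_cell(W, nd.c1, 1, ls, 0, e, f, out);
      return;
    }
    for (int k = e - 1; k <= f; ++k) {
      int idl = W.sid(e, k);
      int idr = W.sid(k + 1, f);
      for (int Rl = 0; Rl < 3; ++Rl)
        for (int lr = 0; lr < 4; ++lr) {
          double cand = A.G[(ls * 4 + Rl) * SZ2 + idl] + B.P[lr * SZ2 + idr];
          if (W.mergeable(Rl, lr)) cand = cand + W.h;
          if (eq(v, cand)) {
            trace_cell(W, nd.c1, 0, ls, Rl, e, k, out);
            trace_cell(W, nd.c2, 1, lr, 0, k + 1, f, out);
            return;
          }
        }
    }
    trace_fail("P/split");
  }
}

static void trace_R(Workspace& W, int ni, int rs, int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  int SZ2 = W.SZ2;
  int id = W.sid(e, f);
  double v = nd.Rr[rs * SZ2 + id];
  if (rs == SN) return;
  if (rs == SQ && nd.type != 0) {
    // generic trailing space against T[f] (PAIRED/SPLIT fill R[Q] this
    // way; UNPAIRED aliases the child's tables instead, handled below)
    if (nd.type == 3) { trace_empty(W, nd, 2, rs, e, f, out); return; }
    int idl = W.sid(e, f - 1);
    for (int rc = 0; rc < 4; ++rc)
      if (eq(v, nd.Rr[rc * SZ2 + idl] - W.chQ(rc))) {
        trace_cell(W, ni, 2, rc, 0, e, f - 1, out);
        out.col(0, f);
        return;
      }
    trace_fail("R/Q");
  }
  if (nd.type == 3) { trace_empty(W, nd, 2, rs, e, f, out); return; }
  const Node& C = W.nodes[nd.c1 >= 0 ? nd.c1 : ni];
  if (nd.type == 0) {  // UNPAIRED: alias of the child's full suffix-global
    for (int Lc = 0; Lc < 3; ++Lc)
      if (eq(v, C.G[(Lc * 4 + rs) * SZ2 + id])) {
        trace_cell(W, nd.c1, 0, Lc, rs, e, f, out);
        return;
      }
    if (eq(v, C.Rr[rs * SZ2 + id])) {
      trace_cell(W, nd.c1, 2, rs, 0, e, f, out);
      return;
    }
    trace_fail("R/unpaired");
  } else if (nd.type == 1) {  // PAIRED
    if (rs == SM) {
      int idl = W.sid(e, f - 1);
      double gqf = W.gam(nd.q, f);
      for (int rc = 0; rc < 4; ++rc)
        if (eq(v, gqf + C.Rr[rc * SZ2 + idl])) {
          trace_cell(W, nd.c1, 2, rc, 0, e, f - 1, out);
          out.col(nd.q, f);
          return;
        }
      for (int Lc = 0; Lc < 4; ++Lc)
        for (int Rc = 0; Rc < 4; ++Rc)
          if (eq(v, gqf + C.G[(Lc * 4 + Rc) * SZ2 + idl])) {
            trace_cell(W, nd.c1, 0, Lc, Rc, e, f - 1, out);
            out.col(nd.q, f);
            return;
          }
    } else {  // ST
      for (int rc = 0; rc < 4; ++rc)
        if (eq(v, C.Rr[rc * SZ2 + id] - W.chT(rc))) {
          trace_cell(W, nd.c1, 2, rc, 0, e, f, out);
          out.col(nd.q, 0);
          return;
        }
      for (int Lc = 0; Lc < 4; ++Lc)
        for (int Rc = 0; Rc < 4; ++Rc)
          if (eq(v, C.G[(Lc * 4 + Rc) * SZ2 + id] - W.chT(Rc))) {
            trace_cell(W, nd.c1, 0, Lc, Rc, e, f, out);
            out.col(nd.q, 0);
            return;
          }
    }
    trace_fail("R/paired");
  } else {  // SPLIT
    const Node& A = W.nodes[nd.c1];
    const Node& B = W.nodes[nd.c2];
    if (eq(v, B.Rr[rs * SZ2 + id])) {
      trace_cell(W, nd.c2, 2, rs, 0, e, f, out);
      return;
    }
    for (int Lc = 0; Lc < 3; ++Lc)
      if (eq(v, B.G[(Lc * 4 + rs) * SZ2 + id])) {
        trace_cell(W, nd.c2, 0, Lc, rs, e, f, out);
        return;
      }
    for (int k = e - 1; k <= f; ++k) {
      int idl = W.sid(e, k);
      int idr = W.sid(k + 1, f);
      for (int rl = 0; rl < 4; ++rl)
        for (int Lr = 0; Lr < 3; ++Lr) {
          double cand = A.Rr[rl * SZ2 + idl] + B.G[(Lr * 4 + rs) * SZ2 + idr];
          if (W.mergeable(rl, Lr)) cand = cand + W.h;
          if (eq(v, cand)) {
            trace_cell(W, nd.c1, 2, rl, 0, e, k, out);
            trace_cell(W, nd.c2, 0, Lr, rs, k + 1, f, out);
            return;
          }
        }
    }
    trace_fail("R/split");
  }
}

static void trace_Sg(Workspace& W, int ni, int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  int SZ2 = W.SZ2;
  int id = W.sid(e, f);
  double v = nd.Sg[id];
  if (nd.type == 3) { trace_empty(W, nd, 3, 0, e, f, out); return; }
  if (nd.type == 0) {  // best child substring not ending at child's q
    const Node& C = W.nodes[nd.c1];
    for (int lc = 0; lc < 4; ++lc)
      if (eq(v, C.P[lc * SZ2 + id])) {
        trace_cell(W, nd.c1, 1, lc, 0, e, f, out);
        return;
      }
    if (eq(v, C.Sg[id])) { trace_cell(W, nd.c1, 3, 0, 0, e, f, out); return; }
    trace_fail("Sg/unpaired");
  } else if (nd.type == 1) {  // child's A
    const Node& C = W.nodes[nd.c1];
    static const int ord[9][2] = { {SM,SM},{SM,ST},{SM,SQ},{ST,SM},{ST,ST},
                                   {ST,SQ},{SQ,SM},{SQ,ST},{SQ,SQ} };
    for (int c = 0; c < 9; ++c)
      if (eq(v, C.G[(ord[c][0] * 4 + ord[c][1]) * SZ2 + id])) {
        trace_cell(W, nd.c1, 0, ord[c][0], ord[c][1], e, f, out);
        return;
      }
    if (eq(v, C.G[(SN * 4 + SN) * SZ2 + id])) return;
    for (int st = 0; st < 4; ++st)
      if (eq(v, C.P[st * SZ2 + id])) {
        trace_cell(W, nd.c1, 1, st, 0, e, f, out);
        return;
      }
    for (int st = 0; st < 4; ++st)
      if (eq(v, C.Rr[st * SZ2 + id])) {
        trace_cell(W, nd.c1, 2, st, 0, e, f, out);
        return;
      }
    if (eq(v, C.Sg[id])) { trace_cell(W, nd.c1, 3, 0, 0, e, f, out); return; }
    trace_fail("Sg/paired");
  } else {  // SPLIT
    const Node& A = W.nodes[nd.c1];
    const Node& B = W.nodes[nd.c2];
    for (int rl = 0; rl < 4; ++rl)
      if (eq(v, A.Rr[rl * SZ2 + id])) {
        trace_cell(W, nd.c1, 2, rl, 0, e, f, out);
        return;
      }
    if (eq(v, A.Sg[id])) { trace_cell(W, nd.c1, 3, 0, 0, e, f, out); return; }
    for (int lr = 0; lr < 4; ++lr)
      if (eq(v, B.P[lr * SZ2 + id])) {
        trace_cell(W, nd.c2, 1, lr, 0, e, f, out);
        return;
      }
    if (eq(v, B.Sg[id])) { trace_cell(W, nd.c2, 3, 0, 0, e, f, out); return; }
    for (int k = e - 1; k <= f; ++k) {
      int idl = W.sid(e, k);
      int idr = W.sid(k + 1, f);
      for (int rl = 0; rl < 4; ++rl)
        for (int lr = 0; lr < 4; ++lr) {
          double cand = A.Rr[rl * SZ2 + idl] + B.P[lr * SZ2 + idr];
          if (W.mergeable(rl, lr)) cand = cand + W.h;
          if (eq(v, cand)) {
            trace_cell(W, nd.c1, 2, rl, 0, e, k, out);
            trace_cell(W, nd.c2, 1, lr, 0, k + 1, f, out);
            return;
          }
        }
    }
    trace_fail("Sg/split");
  }
}

static void trace_cell(Workspace& W, int ni, int tab, int a, int b,
                       int e, int f, TraceOut& out) {
  const Node& nd = W.nodes[ni];
  if (nd.freed) Rcpp::stop("straln: traceback requires retained tables");
  switch (tab) {
    case 0:
      if (nd.type == 3) { trace_empty(W, nd, 0, a, e, f, out); return; }
      if (a == SN) return;  // zero-column cell
      if (nd.type == 0) trace_G_unpaired(W, ni, a, b, e, f, out);
      else if (nd.type == 1) trace_G_paired(W, ni, a, b, e, f, out);
      else trace_G_split(W, ni, a, b, e, f, out);
      return;
    case 1: trace_P(W, ni, a, e, f, out); return;
    case 2: trace_R(W, ni, a, e, f, out); return;
    case 3: trace_Sg(W, ni, e, f, out); return;
    case 4: trace_A(W, ni, e, f, out); return;
  }
}

// ---------------------------------------------------------------------
// workspace construction from R inputs

static Workspace* make_workspace(const IntegerVector& q,
                                 const IntegerMatrix& pairs,
                                 const IntegerVector& t,
                                 const NumericVector& gamma,
                                 const NumericVector& delta,
                                 double h, double s, bool retain) {
  Workspace* W = new Workspace();
  W->m = q.size();
  W->n = t.size();
  W->S.assign(q.begin(), q.end());
  W->T.assign(t.begin(), t.end());
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      W->gamma[i][j] = gamma[i + 4 * j];      // R column-major 4x4
  for (int i = 0; i < 256; ++i) {
    // R array delta[u1,u2,v1,v2] column-major: index u1 fastest
    int u1 = i % 4, u2 = (i / 4) % 4, v1 = (i / 16) % 4, v2 = i / 64;
    W->delta[((u1 * 4 + u2) * 4 + v1) * 4 + v2] = delta[i];
  }
  W->h = h; W->s = s; W->open = h + s; W->ext = s;
  W->retain = retain;
  W->SZ2 = (W->n + 1) * (W->n + 1);
  std::vector<int> partner(std::max(W->m, 1), 0);
  for (int r = 0; r < pairs.nrow(); ++r) {
    partner[pairs(r, 0) - 1] = pairs(r, 1);
    partner[pairs(r, 1) - 1] = pairs(r, 0);
  }
  std::map<std::pair<int, int>, int> memo;
  W->top = build_nodes(*W, 1, W->m, memo, partner);
  W->nodes[W->top].refcount++;  // never freed
  fill_node(*W, W->top);
  return W;
}

static List alignment_from_trace(Workspace& W, TraceOut& out, double score) {
  return List::create(_["score"] = score,
                      _["qcols"] = IntegerVector(out.qc.begin(), out.qc.end()),
                      _["tcols"] = IntegerVector(out.tc.begin(), out.tc.end()));
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(IntegerVector q, IntegerMatrix pairs, IntegerVector t,
               NumericVector gamma, NumericVector delta,
               double h, double s, std::string mode, bool traceback) {
  Workspace* W = make_workspace(q, pairs, t, gamma, delta, h, s, traceback);
  const Node& top = W->nodes[W->top];
  double score = NEG;
  int be = 1, bf = 0;
  TraceOut out;
  if (mode == "local") {
    for (int e = 1; e <= W->n + 1; ++e)
      for (int f = e - 1; f <= W->n; ++f) {
        double v = nodeA(*W, top, e, f);
        if (v > score) { score = v; be = e; bf = f; }
      }
    if (traceback) trace_A(*W, W->top, be, bf, out);
  } else if (mode == "semiglobal") {
    be = 1; bf = W->n;
    score = nodeA(*W, top, be, bf);
    if (traceback) trace_A(*W, W->top, be, bf, out);
  } else {  // global
    be = 1; bf = W->n;
    int id = W->sid(be, bf);
    int bst = -1;
    static const int ord[10][2] = { {SM,SM},{SM,ST},{SM,SQ},{ST,SM},{ST,ST},
                                    {ST,SQ},{SQ,SM},{SQ,ST},{SQ,SQ},{SN,SN} };
    for (int c = 0; c < 10; ++c) {
      double v = top.G[(ord[c][0] * 4 + ord[c][1]) * W->SZ2 + id];
      if (v > score) { score = v; bst = c; }
    }
    if (traceback && bst >= 0 && ord[bst][0] != SN)
      trace_cell(*W, W->top, 0, ord[bst][0], ord[bst][1], be, bf, out);
  }
  List res = alignment_from_trace(*W, out, score < NEG_GUARD ? R_NegInf : score);
  res["e"] = be; res["f"] = bf;
  delete W;
  return res;
}

// exposes the top-interval tables for auditing, plus a retained
// workspace pointer for cell-level traceback
// [[Rcpp::export(name = ".cpp_workspace")]]
List cpp_workspace(IntegerVector q, IntegerMatrix pairs, IntegerVector t,
                   NumericVector gamma, NumericVector delta,
                   double h, double s) {
  Workspace* W = make_workspace(q, pairs, t, gamma, delta, h, s, true);
  const Node& top = W->nodes[W->top];
  int n = W->n;
  int nr = n + 1;  // rows: e = 1..n+1; cols: f = 0..n
  auto mat = [&](std::function<double(int, int)> getter) {
    NumericMatrix M(nr, nr);
    std::fill(M.begin(), M.end(), NA_REAL);
    for (int e = 1; e <= n + 1; ++e)
      for (int f = e - 1; f <= n; ++f) {
        double v = getter(e, f);
        M(e - 1, f) = v < NEG_GUARD ? R_NegInf : v;
      }
    return M;
  };
  List A1(9);
  static const int ord[9][2] = { {SM,SM},{SM,ST},{SM,SQ},{ST,SM},{ST,ST},
                                 {ST,SQ},{SQ,SM},{SQ,ST},{SQ,SQ} };
  for (int c = 0; c < 9; ++c) {
    int st = ord[c][0] * 4 + ord[c][1];
    A1[c] = mat([&, st](int e, int f) { return top.G[st * W->SZ2 + W->sid(e, f)]; });
  }
  List A2(4), A3(4);
  static const int sord[3] = { SM, ST, SQ };
  for (int c = 0; c < 3; ++c) {
    int st = sord[c];
    A2[c] = mat([&, st](int e, int f) { return top.P[st * W->SZ2 + W->sid(e, f)]; });
    A3[c] = mat([&, st](int e, int f) { return top.Rr[st * W->SZ2 + W->sid(e, f)]; });
  }
  // closed-form empty prefix/suffix -h - s(f-e+1) (0 for the empty slice)
  auto cfm = mat([&](int e, int f) {
    return f >= e ? -(W->h + W->s * (f - e + 1)) : 0.0; });
  A2[3] = cfm; A3[3] = cfm;
  NumericMatrix A4 = mat([&](int e, int f) { return top.Sg[W->sid(e, f)]; });
  NumericMatrix Am = mat([&](int e, int f) { return nodeA(*W, top, e, f); });
  XPtr<Workspace> ptr(W, true);
  return List::create(_["A1"] = A1, _["A2"] = A2, _["A3"] = A3,
                      _["A4"] = A4, _["A"] = Am,
                      _["m"] = W->m, _["n"] = n, _["ptr"] = ptr);
}

// [[Rcpp::export(name = ".cpp_trace")]]
List cpp_trace(SEXP wsptr, std::string table, int cas, int e, int f) {
  XPtr<Workspace> W(wsptr);
  TraceOut out;
  double score;
  const Node& top = W->nodes[W->top];
  int id = W->sid(e, f);
  static const int ord[9][2] = { {SM,SM},{SM,ST},{SM,SQ},{ST,SM},{ST,ST},
                                 {ST,SQ},{SQ,SM},{SQ,ST},{SQ,SQ} };
  static const int sord[3] = { SM, ST, SQ };
  if (table == "A1") {
    int L = ord[cas - 1][0], R = ord[cas - 1][1];
    score = top.G[(L * 4 + R) * W->SZ2 + id];
    if (score < NEG_GUARD) Rcpp::stop("cell is infeasible (-Inf)");
    trace_cell(*W, W->top, 0, L, R, e, f, out);
  } else if (table == "A2" || table == "A3") {
    int tb = table == "A2" ? 1 : 2;
    if (cas == 4) {  // closed-form all-gap cell
      score = f >= e ? -(W->h + W->s * (f - e + 1)) : 0.0;
      for (int tt = e; tt <= f; ++tt) out.col(0, tt);
    } else {
      int st = sord[cas - 1];
      score = (tb == 1 ? top.P : top.Rr)[st * W->SZ2 + id];
      if (score < NEG_GUARD) Rcpp::stop("cell is infeasible (-Inf)");
      trace_cell(*W, W->top, tb, st, 0, e, f, out);
    }
  } else if (table == "A4") {
    score = top.Sg[id];
    if (score < NEG_GUARD) Rcpp::stop("cell is infeasible (-Inf)");
    trace_cell(*W, W->top, 3, 0, 0, e, f, out);
  } else {  // "A"
    score = nodeA(*W, top, e, f);
    if (score < NEG_GUARD) Rcpp::stop("cell is infeasible (-Inf)");
    trace_A(*W, W->top, e, f, out);
  }
  return alignment_from_trace(*W, out, score);
}

// node count and timing helper for the complexity-trend check: fills all
// tables (score-only) and returns the local optimum
// [[Rcpp::export(name = ".cpp_fill_time")]]
double cpp_fill_time(IntegerVector q, IntegerMatrix pairs, IntegerVector t,
                     NumericVector gamma, NumericVector delta,
                     double h, double s) {
  Workspace* W = make_workspace(q, pairs, t, gamma, delta, h, s, false);
  const Node& top = W->nodes[W->top];
  double score = NEG;
  for (int e = 1; e <= W->n + 1; ++e)
    for (int f = e - 1; f <= W->n; ++f)
      score = std::max(score, nodeA(*W, top, e, f));
  delete W;
  return score;
}

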