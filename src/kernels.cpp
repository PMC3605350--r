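#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <vector>
using namespace Rcpp;

typedef long long ll;
static const ll INF = (1LL << 60);

static inline ll addc(ll x, ll y) { return (x >= INF || y >= INF) ? INF : x + y; }

// ---------------------------------------------------------------------------
// Powerset lookup tables.
//
// Residue sets are bitmasks over the alphabet order (indel = highest bit,
// always last). Masks run 1..(2^nsym - 1); tables are indexed mask-1.
//   dp     : d_P(X,Y) = min over member pairs of d
//   wx, wy : witness pair realizing d_P, ties by alphabet order (x, then y);
//            1-based symbol indices
//   med    : non-affine median set m(X,Y) = all members of X and Y that
//            participate in a pair realizing d_P
//   medaff : the affine rule-4 set for a diagonal (g) step:
//            { x in X : some y in Y has d(x,y) = subst(X,Y) } union
//            { y in Y : some x in X has d(x,y) = subst(X,Y) },
//            where subst(X,Y) = d_P(X \ indel, Y \ indel); 0 when undefined
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_build_tables(IntegerMatrix dcost) {
  int nsym = dcost.nrow();
  int nset = (1 << nsym) - 1;
  IntegerMatrix dp(nset, nset), wx(nset, nset), wy(nset, nset);
  IntegerMatrix med(nset, nset), medaff(nset, nset);
  int ib = 1 << (nsym - 1);  // indel bit

  std::vector<std::vector<int> > mem(nset + 1);
  for (int m = 1; m <= nset; m++)
    for (int s = 0; s < nsym; s++)
      if (m & (1 << s)) mem[m].push_back(s);

  for (int x = 1; x <= nset; x++) {
    for (int y = 1; y <= nset; y++) {
      int best = INT_MAX, bx = -1, by = -1;
      for (size_t i = 0; i < mem[x].size(); i++)
        for (size_t j = 0; j < mem[y].size(); j++) {
          int c = dcost(mem[x][i], mem[y][j]);
          if (c < best) { best = c; bx = mem[x][i]; by = mem[y][j]; }
        }
      dp(x - 1, y - 1) = best;
      wx(x - 1, y - 1) = bx + 1;
      wy(x - 1, y - 1) = by + 1;
      int mm = 0;
      for (size_t i = 0; i < mem[x].size(); i++)
        for (size_t j = 0; j < mem[y].size(); j++)
          if (dcost(mem[x][i], mem[y][j]) == best)
            mm |= (1 << mem[x][i]) | (1 << mem[y][j]);
      med(x - 1, y - 1) = mm;
    }
  }
  for (int x = 1; x <= nset; x++) {
    for (int y = 1; y <= nset; y++) {
      int sx = x & ~ib, sy = y & ~ib;
      if (sx == 0 || sy == 0) { medaff(x - 1, y - 1) = 0; continue; }
      int t = dp(sx - 1, sy - 1);
      int mm = 0;
      // participants are the non-indel members mutually realizing subst
      for (size_t i = 0; i < mem[sx].size(); i++)
        for (size_t j = 0; j < mem[sy].size(); j++)
          if (dcost(mem[sx][i], mem[sy][j]) == t)
            mm |= (1 << mem[sx][i]) | (1 << mem[sy][j]);
      medaff(x - 1, y - 1) = mm;
    }
  }
  return List::create(_["dp"] = dp, _["wx"] = wx, _["wy"] = wy,
                      _["med"] = med, _["medaff"] = medaff);
}

// ---------------------------------------------------------------------------
// Non-affine RAG alignment: Needleman-Wunsch over the powerset alphabet with
// substitution cost d_P(A_i, B_j) and indel cost d_P(., {indel}).
// Backtrack tie order: diagonal > delete (consume A) > insert (consume B).
// Returns the optimal cost and one backtrack as per-column operation codes
// (1 = diagonal, 2 = delete, 3 = insert) plus consumed positions (0 = gap).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_align_rag(IntegerVector am, IntegerVector bm, IntegerMatrix dp,
                   int indel_mask) {
  int n = am.size(), m = bm.size();
  std::vector<ll> C((n + 1) * (m + 1), INF);
#define IDX(i, j) ((i) * (m + 1) + (j))
  C[IDX(0, 0)] = 0;
  for (int i = 1; i <= n; i++)
    C[IDX(i, 0)] = C[IDX(i - 1, 0)] + dp(am[i - 1] - 1, indel_mask - 1);
  for (int j = 1; j <= m; j++)
    C[IDX(0, j)] = C[IDX(0, j - 1)] + dp(bm[j - 1] - 1, indel_mask - 1);
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      ll s = C[IDX(i - 1, j - 1)] + dp(am[i - 1] - 1, bm[j - 1] - 1);
      ll del = C[IDX(i - 1, j)] + dp(am[i - 1] - 1, indel_mask - 1);
      ll ins = C[IDX(i, j - 1)] + dp(bm[j - 1] - 1, indel_mask - 1);
      ll v = s < del ? s : del;
      if (ins < v) v = ins;
      C[IDX(i, j)] = v;
    }
  }
  std::vector<int> ops, ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    ll cur = C[IDX(i, j)];
    if (i > 0 && j > 0 &&
        cur == C[IDX(i - 1, j - 1)] + dp(am[i - 1] - 1, bm[j - 1] - 1)) {
      ops.push_back(1); ai.push_back(i); bj.push_back(j); i--; j--;
    } else if (i > 0 &&
               cur == C[IDX(i - 1, j)] + dp(am[i - 1] - 1, indel_mask - 1)) {
      ops.push_back(2); ai.push_back(i); bj.push_back(0); i--;
    } else {
      ops.push_back(3); ai.push_back(0); bj.push_back(j); j--;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
#undef IDX
  return List::create(_["cost"] = (double)C[(n + 1) * (m + 1) - 1],
                      _["ops"] = wrap(ops), _["ai"] = wrap(ai),
                      _["bj"] = wrap(bj));
}

// ---------------------------------------------------------------------------
// Affine RAG alignment over the powerset alphabet, with atomic optional gap
// blocks.  Four matrices:
//   g[i,j] : last visible column is a match (non-indel members of A_i, B_j)
//   d[i,j] : diagonal indel run (both columns select indels)
//   v[i,j] : open gap on the B side (A_i consumed against an indel)
//   h[i,j] : open gap on the A side (B_j consumed against an indel)
// Accessory costs on the *effective* column sets:
//   subst(X,Y) = d_P(X \ indel, Y \ indel)  (INF when a side is pure indel)
//   diag(X,Y)  = 0 if indel in both, else INF
//   ge(X)      = 0 if indel in X, else b
//   inv(X)     = 0 if indel in X, else INF  (invisible consumption)
//   go(A,i)    = printed gap-opening accessory, used on the d paths
// ga/gb give per-column block-group ids (0 = ordinary).  The columns of a
// nonzero group are consumed under one shared decision: take (the column
// acts as its residue set, no indel) or skip (the column acts as {indel}).
// The DP carries the decision of the group of the last consumed column per
// side, so contained-sequence selections can keep or drop a whole gap
// block but never split one.  The value is the exact minimum affine cost
// over (group-consistent) contained pairs; on singleton RAGs it is the
// Gotoh distance.
// Gap runs open from g/d/v/h at cost a + ge and extend at ge; invisible
// moves cost 0 and preserve the matrix.  Backtrack tie order across
// matrices g > d > v > h, within a matrix diagonal/printed cases before
// completion moves, take before skip.  Column codes: 1=g (diagonal), 2=d,
// 3=v, 4=h, 5=invisible-A, 6=invisible-B; ea/eb return the effective
// consumed masks (0 = side not consumed).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_align_rag_affine(IntegerVector am, IntegerVector bm,
                          IntegerVector ga, IntegerVector gb,
                          IntegerMatrix dp, int nsym, int a, int b,
                          bool keep) {
  int n = am.size(), m = bm.size();
  int ib = 1 << (nsym - 1);

  // raw printed go arrays (used on d paths; sound there, see module docs)
  std::vector<int> goA(n + 2, a), goB(m + 2, a);
  for (int i = 1; i <= n; i++) {
    bool cur = (am[i - 1] & ib) != 0;
    bool prev = (i > 1) && ((am[i - 2] & ib) != 0);
    if ((i == 1 && cur) || (i > 1 && !prev && cur)) goA[i] = 0;
  }
  for (int j = 1; j <= m; j++) {
    bool cur = (bm[j - 1] & ib) != 0;
    bool prev = (j > 1) && ((bm[j - 2] & ib) != 0);
    if ((j == 1 && cur) || (j > 1 && !prev && cur)) goB[j] = 0;
  }

  // effective per-column properties under decision d (0 = plain/skip,
  // 1 = take); index [i][d], i 1-based
  auto effProps = [&](IntegerVector &masks, IntegerVector &grp, int i, int d,
                      int &eS, ll &eInv, ll &eGe, bool &eInd,
                      int &eMask) -> bool {
    int raw = masks[i - 1];
    if (grp[i - 1] == 0) {
      if (d != 0) return false;
      eS = raw & ~ib;
      eInv = (raw & ib) ? 0 : INF;
      eGe = (raw & ib) ? 0 : b;
      eInd = (raw & ib) != 0;
      eMask = raw;
    } else if (d == 1) {  // take
      eS = raw & ~ib;
      eInv = INF;
      eGe = b;
      eInd = false;
      eMask = raw & ~ib;
    } else {              // skip
      eS = 0;
      eInv = 0;
      eGe = 0;
      eInd = true;
      eMask = ib;
    }
    return true;
  };

  // admissible source-side decisions when consuming column i under d
  auto predDecisions = [&](IntegerVector &grp, int i, int d, int out[2]) -> int {
    if (grp[i - 1] != 0 && i > 1 && grp[i - 2] == grp[i - 1]) {
      out[0] = d;  // continuing the group: same decision
      return 1;
    }
    if (i == 1 || grp[i - 2] == 0) { out[0] = 0; return 1; }
    out[0] = 0; out[1] = 1;  // previous column closed some other group
    return 2;
  };

  size_t sz = (size_t)(n + 1) * (m + 1);
  // V[mat][da][db], mat 0..3 = g,d,v,h
  std::vector<ll> V(16 * sz, INF);
#define ID(mat, da, db, i, j) \
  ((size_t)(((mat) * 2 + (da)) * 2 + (db)) * sz + (size_t)(i) * (m + 1) + (j))
  V[ID(0, 0, 0, 0, 0)] = 0;

  int eSA, eSB, eMA, eMB;
  ll eInvA, eInvB, eGeA, eGeB;
  bool eIndA, eIndB;
  int pa[2], pb[2];

  for (int i = 0; i <= n; i++) {
    for (int j = 0; j <= m; j++) {
      if (i == 0 && j == 0) continue;
      for (int da = 0; da < 2; da++) {
        if (i == 0 && da != 0) continue;
        if (i > 0 && !effProps(am, ga, i, da, eSA, eInvA, eGeA, eIndA, eMA))
          continue;
        for (int db = 0; db < 2; db++) {
          if (j == 0 && db != 0) continue;
          if (j > 0 && !effProps(bm, gb, j, db, eSB, eInvB, eGeB, eIndB, eMB))
            continue;
          int npa = (i > 0) ? predDecisions(ga, i, da, pa) : 0;
          int npb = (j > 0) ? predDecisions(gb, j, db, pb) : 0;
          ll gb_ = INF, db_ = INF, vb_ = INF, hb_ = INF;

          if (i > 0 && j > 0) {
            ll sb = (eSA && eSB) ? (ll)dp(eSA - 1, eSB - 1) : INF;
            ll dg = (eIndA && eIndB) ? 0 : INF;
            for (int x = 0; x < npa; x++)
              for (int y = 0; y < npb; y++) {
                size_t base = ID(0, pa[x], pb[y], i - 1, j - 1);
                // g: diagonal match from g/v/h at subst, from d with go's
                ll c = addc(V[base], sb);                       // from g
                if (c < gb_) gb_ = c;
                c = addc(V[base + 1 * 4 * sz],
                         addc(sb, goA[i] + goB[j]));            // from d
                if (c < gb_) gb_ = c;
                c = addc(V[base + 2 * 4 * sz], sb);             // from v
                if (c < gb_) gb_ = c;
                c = addc(V[base + 3 * 4 * sz], sb);             // from h
                if (c < gb_) gb_ = c;
                // d: diagonal indels from d, or from g with go's
                c = addc(dg, V[base + 1 * 4 * sz]);
                if (c < db_) db_ = c;
                c = addc(dg, addc(V[base], goA[i] + goB[j]));
                if (c < db_) db_ = c;
              }
          }
          if (i > 0) {
            for (int x = 0; x < npa; x++) {
              size_t base = ID(0, pa[x], db, i - 1, j);
              // v: extend / open (d, g, h)
              ll c = addc(V[base + 2 * 4 * sz], eGeA);
              if (c < vb_) vb_ = c;
              c = addc(V[base + 1 * 4 * sz], addc(eGeA, a));
              if (c < vb_) vb_ = c;
              c = addc(V[base], addc(eGeA, a));
              if (c < vb_) vb_ = c;
              c = addc(V[base + 3 * 4 * sz], addc(eGeA, a));
              if (c < vb_) vb_ = c;
              // invisible A: inside g and inside h
              c = addc(V[base], eInvA);
              if (c < gb_) gb_ = c;
              c = addc(V[base + 3 * 4 * sz], eInvA);
              if (c < hb_) hb_ = c;
            }
          }
          if (j > 0) {
            for (int y = 0; y < npb; y++) {
              size_t base = ID(0, da, pb[y], i, j - 1);
              // h: extend / open (d, g, v)
              ll c = addc(V[base + 3 * 4 * sz], eGeB);
              if (c < hb_) hb_ = c;
              c = addc(V[base + 1 * 4 * sz], addc(eGeB, a));
              if (c < hb_) hb_ = c;
              c = addc(V[base], addc(eGeB, a));
              if (c < hb_) hb_ = c;
              c = addc(V[base + 2 * 4 * sz], addc(eGeB, a));
              if (c < hb_) hb_ = c;
              // invisible B: inside g and inside v
              c = addc(V[base], eInvB);
              if (c < gb_) gb_ = c;
              c = addc(V[base + 2 * 4 * sz], eInvB);
              if (c < vb_) vb_ = c;
            }
          }
          V[ID(0, da, db, i, j)] = gb_;
          V[ID(1, da, db, i, j)] = db_;
          V[ID(2, da, db, i, j)] = vb_;
          V[ID(3, da, db, i, j)] = hb_;
        }
      }
    }
  }

  ll cost = INF;
  int fmat = 0, fda = 0, fdb = 0;
  for (int mat = 0; mat < 4; mat++)
    for (int da = 0; da < 2; da++)
      for (int db = 0; db < 2; db++) {
        ll c = V[ID(mat, da, db, n, m)];
        if (c < cost) { cost = c; fmat = mat; fda = da; fdb = db; }
      }

  std::vector<int> mats, ea, eb;
  {
    int i = n, j = m, mat = fmat, da = fda, db = fdb;
    while (i > 0 || j > 0) {
      ll cur = V[ID(mat, da, db, i, j)];
      bool iok = i > 0 && effProps(am, ga, i, da, eSA, eInvA, eGeA, eIndA, eMA);
      bool jok = j > 0 && effProps(bm, gb, j, db, eSB, eInvB, eGeB, eIndB, eMB);
      int npa = iok ? predDecisions(ga, i, da, pa) : 0;
      int npb = jok ? predDecisions(gb, j, db, pb) : 0;
      bool moved = false;
      if (mat == 0) {  // g
        if (iok && jok) {
          ll sb = (eSA && eSB) ? (ll)dp(eSA - 1, eSB - 1) : INF;
          for (int x = 0; x < npa && !moved; x++)
            for (int y = 0; y < npb && !moved; y++) {
              size_t base = ID(0, pa[x], pb[y], i - 1, j - 1);
              int src[4] = {0, 1, 2, 3};
              for (int s = 0; s < 4 && !moved; s++) {
                ll add = (src[s] == 1) ? addc(sb, goA[i] + goB[j]) : sb;
                if (cur == addc(V[base + (size_t)src[s] * 4 * sz], add)) {
                  mats.push_back(1); ea.push_back(eMA); eb.push_back(eMB);
                  mat = src[s]; da = pa[x]; db = pb[y]; i--; j--;
                  moved = true;
                }
              }
            }
        }
        if (!moved && iok)
          for (int x = 0; x < npa && !moved; x++)
            if (cur == addc(V[ID(0, pa[x], db, i - 1, j)], eInvA)) {
              mats.push_back(5); ea.push_back(eMA); eb.push_back(0);
              da = pa[x]; i--; moved = true;
            }
        if (!moved && jok)
          for (int y = 0; y < npb && !moved; y++)
            if (cur == addc(V[ID(0, da, pb[y], i, j - 1)], eInvB)) {
              mats.push_back(6); ea.push_back(0); eb.push_back(eMB);
              db = pb[y]; j--; moved = true;
            }
      } else if (mat == 1) {  // d
        ll dg = (iok && jok && eIndA && eIndB) ? 0 : INF;
        for (int x = 0; x < npa && !moved; x++)
          for (int y = 0; y < npb && !moved; y++) {
            size_t base = ID(0, pa[x], pb[y], i - 1, j - 1);
            if (cur == addc(dg, V[base + 1 * 4 * sz])) {
              mats.push_back(2); ea.push_back(eMA); eb.push_back(eMB);
              mat = 1; da = pa[x]; db = pb[y]; i--; j--; moved = true;
            } else if (cur == addc(dg, addc(V[base], goA[i] + goB[j]))) {
              mats.push_back(2); ea.push_back(eMA); eb.push_back(eMB);
              mat = 0; da = pa[x]; db = pb[y]; i--; j--; moved = true;
            }
          }
      } else if (mat == 2) {  // v
        for (int x = 0; x < npa && !moved; x++) {
          size_t base = ID(0, pa[x], db, i - 1, j);
          int srcs[4] = {2, 1, 0, 3};
          for (int s = 0; s < 4 && !moved; s++) {
            ll add = (srcs[s] == 2) ? eGeA : addc(eGeA, a);
            if (cur == addc(V[base + (size_t)srcs[s] * 4 * sz], add)) {
              mats.push_back(3); ea.push_back(eMA); eb.push_back(0);
              mat = srcs[s]; da = pa[x]; i--; moved = true;
            }
          }
        }
        if (!moved && jok)
          for (int y = 0; y < npb && !moved; y++)
            if (cur == addc(V[ID(2, da, pb[y], i, j - 1)], eInvB)) {
              mats.push_back(6); ea.push_back(0); eb.push_back(eMB);
              db = pb[y]; j--; moved = true;
            }
      } else {  // h
        for (int y = 0; y < npb && !moved; y++) {
          size_t base = ID(0, da, pb[y], i, j - 1);
          int srcs[4] = {3, 1, 0, 2};
          for (int s = 0; s < 4 && !moved; s++) {
            ll add = (srcs[s] == 3) ? eGeB : addc(eGeB, a);
            if (cur == addc(V[base + (size_t)srcs[s] * 4 * sz], add)) {
              mats.push_back(4); ea.push_back(0); eb.push_back(eMB);
              mat = srcs[s]; db = pb[y]; j--; moved = true;
            }
          }
        }
        if (!moved && iok)
          for (int x = 0; x < npa && !moved; x++)
            if (cur == addc(V[ID(3, pa[x], db, i - 1, j)], eInvA)) {
              mats.push_back(5); ea.push_back(eMA); eb.push_back(0);
              da = pa[x]; i--; moved = true;
            }
      }
      if (!moved) stop("internal error: affine backtrack lost its path");
    }
  }
  std::reverse(mats.begin(), mats.end());
  std::reverse(ea.begin(), ea.end());
  std::reverse(eb.begin(), eb.end());

  List out = List::create(_["cost"] = (cost >= INF ? R_PosInf : (double)cost),
                          _["mats"] = wrap(mats), _["ea"] = wrap(ea),
                          _["eb"] = wrap(eb), _["final"] = fmat + 1);
  if (keep) {
    NumericMatrix G(n + 1, m + 1), D(n + 1, m + 1), Vm(n + 1, m + 1),
        H(n + 1, m + 1);
    for (int ii = 0; ii <= n; ii++)
      for (int jj = 0; jj <= m; jj++) {
        ll bg = INF, bd = INF, bv = INF, bh = INF;
        for (int da = 0; da < 2; da++)
          for (int db = 0; db < 2; db++) {
            if (V[ID(0, da, db, ii, jj)] < bg) bg = V[ID(0, da, db, ii, jj)];
            if (V[ID(1, da, db, ii, jj)] < bd) bd = V[ID(1, da, db, ii, jj)];
            if (V[ID(2, da, db, ii, jj)] < bv) bv = V[ID(2, da, db, ii, jj)];
            if (V[ID(3, da, db, ii, jj)] < bh) bh = V[ID(3, da, db, ii, jj)];
          }
        G(ii, jj) = bg >= INF ? R_PosInf : (double)bg;
        D(ii, jj) = bd >= INF ? R_PosInf : (double)bd;
        Vm(ii, jj) = bv >= INF ? R_PosInf : (double)bv;
        H(ii, jj) = bh >= INF ? R_PosInf : (double)bh;
      }
    out["g"] = G; out["d"] = D; out["v"] = Vm; out["h"] = H;
  }
#undef ID
  return out;
}

// ---------------------------------------------------------------------------
// Plain-sequence kernels (independent of the RAG path). Sequences are 1-based
// symbol indices into the cost matrix; indel_idx is the indel's index.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_nw(IntegerVector s1, IntegerVector s2, IntegerMatrix dcost,
              int indel_idx) {
  int n = s1.size(), m = s2.size();
  std::vector<ll> prev(m + 1), cur(m + 1);
  prev[0] = 0;
  for (int j = 1; j <= m; j++)
    prev[j] = prev[j - 1] + dcost(s2[j - 1] - 1, indel_idx - 1);
  for (int i = 1; i <= n; i++) {
    cur[0] = prev[0] + dcost(s1[i - 1] - 1, indel_idx - 1);
    for (int j = 1; j <= m; j++) {
      ll s = prev[j - 1] + dcost(s1[i - 1] - 1, s2[j - 1] - 1);
      ll del = prev[j] + dcost(s1[i - 1] - 1, indel_idx - 1);
      ll ins = cur[j - 1] + dcost(s2[j - 1] - 1, indel_idx - 1);
      ll v = s < del ? s : del;
      cur[j] = ins < v ? ins : v;
    }
    std::swap(prev, cur);
  }
  return (double)prev[m];
}

// Textbook Gotoh with gap cost G(k) = a + b*k, three matrices M/Ix/Iy.
// [[Rcpp::export]]
double cpp_gotoh(IntegerVector s1, IntegerVector s2, IntegerMatrix dcost,
                 int a, int b) {
  int n = s1.size(), m = s2.size();
  if (n == 0 && m == 0) return 0.0;
  std::vector<ll> Mp(m + 1), Xp(m + 1), Yp(m + 1), Mc(m + 1), Xc(m + 1),
      Yc(m + 1);
  Mp[0] = 0; Xp[0] = INF; Yp[0] = INF;
  for (int j = 1; j <= m; j++) {
    Mp[j] = INF; Xp[j] = INF;
    Yp[j] = (ll)a + (ll)b * j;
  }
  for (int i = 1; i <= n; i++) {
    Mc[0] = INF; Yc[0] = INF;
    Xc[0] = (ll)a + (ll)b * i;
    for (int j = 1; j <= m; j++) {
      ll dm = Mp[j - 1], dx = Xp[j - 1], dy = Yp[j - 1];
      ll best = dm < dx ? dm : dx;
      if (dy < best) best = dy;
      Mc[j] = addc(best, dcost(s1[i - 1] - 1, s2[j - 1] - 1));
      ll x1 = addc(Mp[j], a + b), x2 = addc(Xp[j], b), x3 = addc(Yp[j], a + b);
      ll xb = x1 < x2 ? x1 : x2;
      Xc[j] = x3 < xb ? x3 : xb;
      ll y1 = addc(Mc[j - 1], a + b), y2 = addc(Yc[j - 1], b),
         y3 = addc(Xc[j - 1], a + b);
      ll yb = y1 < y2 ? y1 : y2;
      Yc[j] = y3 < yb ? y3 : yb;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  ll r = Mp[m] < Xp[m] ? Mp[m] : Xp[m];
  if (Yp[m] < r) r = Yp[m];
  return (double)r;
}

// ---------------------------------------------------------------------------
// Exact 3-sequence (star) alignment, non-affine: 3D DP over a center sequence.
// Each column advances a nonempty subset S of the three sequences against a
// center residue c (cost sum d(c, x_t) for t in S plus b per t not in S) or
// against a center gap (cost b per advancing sequence). Minimizing over all
// paths yields min over centers m of sum_t e(m, s_t).
// Sequences are 0-based residue indices (0..nres-1).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_exact3(IntegerVector s1, IntegerVector s2, IntegerVector s3,
                IntegerMatrix dcost, int nres, int indel_idx, bool want_median) {
  int n1 = s1.size(), n2 = s2.size(), n3 = s3.size();
  size_t sz = (size_t)(n1 + 1) * (n2 + 1) * (n3 + 1);
  std::vector<ll> V(sz, INF);
  std::vector<uint8_t> bp(sz, 0);
  ll b = dcost(0, indel_idx - 1);
#define IDX3(i, j, k) (((size_t)(i) * (n2 + 1) + (j)) * (n3 + 1) + (k))
  V[0] = 0;
  for (int i = 0; i <= n1; i++)
    for (int j = 0; j <= n2; j++)
      for (int k = 0; k <= n3; k++) {
        ll val = V[IDX3(i, j, k)];
        if (val >= INF) continue;
        int ch[3] = {i < n1 ? s1[i] : -1, j < n2 ? s2[j] : -1,
                     k < n3 ? s3[k] : -1};
        for (int S = 1; S <= 7; S++) {
          int d1 = S & 1, d2 = (S >> 1) & 1, d3 = (S >> 2) & 1;
          if ((d1 && ch[0] < 0) || (d2 && ch[1] < 0) || (d3 && ch[2] < 0))
            continue;
          size_t tid = IDX3(i + d1, j + d2, k + d3);
          // center residue: min over c of sum d(c, char) + b per gap side
          ll mc = INF;
          for (int c = 0; c < nres; c++) {
            ll s = 0;
            if (d1) s += dcost(c, ch[0]);
            if (d2) s += dcost(c, ch[1]);
            if (d3) s += dcost(c, ch[2]);
            if (s < mc) mc = s;
          }
          ll nv = val + mc + b * (3 - d1 - d2 - d3);
          if (nv < V[tid]) { V[tid] = nv; bp[tid] = (uint8_t)S; }
          // center gap
          nv = val + b * (d1 + d2 + d3);
          if (nv < V[tid]) { V[tid] = nv; bp[tid] = (uint8_t)(S + 8); }
        }
      }
  ll cost = V[IDX3(n1, n2, n3)];
  List out = List::create(_["cost"] = (double)cost);
  if (want_median) {
    std::vector<int> med;
    int i = n1, j = n2, k = n3;
    while (i > 0 || j > 0 || k > 0) {
      int mv = bp[IDX3(i, j, k)];
      int S = mv & 7;
      int d1 = S & 1, d2 = (S >> 1) & 1, d3 = (S >> 2) & 1;
      i -= d1; j -= d2; k -= d3;
      if (mv < 8) {  // center residue: recompute argmin c (lowest index wins)
        int ch[3] = {d1 ? s1[i] : -1, d2 ? s2[j] : -1, d3 ? s3[k] : -1};
        ll mc = INF; int bc = -1;
        for (int c = 0; c < nres; c++) {
          ll s = 0;
          for (int t = 0; t < 3; t++)
            if (ch[t] >= 0) s += dcost(c, ch[t]);
          if (s < mc) { mc = s; bc = c; }
        }
        med.push_back(bc + 1);
      }
    }
    std::reverse(med.begin(), med.end());
    out["median"] = wrap(med);
  }
#undef IDX3
  return out;
}

// ---------------------------------------------------------------------------
// Exact 3-sequence star alignment under affine gap cost G(k) = a + b*k, with
// each center-to-leaf edge priced as an independent pairwise affine alignment.
// 3D DP augmented with a per-edge gap state:
//   0 = last visible column on the edge was residue-residue
//   1 = open gap in the sequence (center residue vs sequence gap)
//   2 = open gap in the center (center gap vs sequence residue)
// Columns where both the center and a sequence have gaps are invisible to
// that edge and leave its state unchanged.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_exact3_affine(IntegerVector s1, IntegerVector s2, IntegerVector s3,
                       IntegerMatrix dcost, int nres, int a, int b,
                       bool want_median) {
  int n1 = s1.size(), n2 = s2.size(), n3 = s3.size();
  const int NS = 27;
  size_t plane = (size_t)(n2 + 1) * (n3 + 1) * NS;
  std::vector<ll> cur(plane, INF), nxt(plane, INF);
  std::vector<uint16_t> bp;
  if (want_median) bp.assign((size_t)(n1 + 1) * plane, 0);

  // per-state per-subset extra gap costs and target states
  int e1[NS], e2[NS], e3[NS];
  for (int st = 0; st < NS; st++) {
    e1[st] = st % 3; e2[st] = (st / 3) % 3; e3[st] = st / 9;
  }
  ll resExtra[NS][8], gapExtra[NS][8];
  int resTgt[NS][8], gapTgt[NS][8];
  for (int st = 0; st < NS; st++) {
    int e[3] = {e1[st], e2[st], e3[st]};
    for (int S = 1; S <= 7; S++) {
      ll re = 0, ge = 0;
      int rt[3], gt[3];
      for (int t = 0; t < 3; t++) {
        bool adv = (S >> t) & 1;
        if (adv) { rt[t] = 0; gt[t] = 2; ge += b + (e[t] == 2 ? 0 : a); }
        else     { rt[t] = 1; gt[t] = e[t]; re += b + (e[t] == 1 ? 0 : a); }
      }
      resExtra[st][S] = re; gapExtra[st][S] = ge;
      resTgt[st][S] = rt[0] + 3 * rt[1] + 9 * rt[2];
      gapTgt[st][S] = gt[0] + 3 * gt[1] + 9 * gt[2];
    }
  }

#define PIDX(j, k, st) ((((size_t)(j) * (n3 + 1)) + (k)) * NS + (st))
  cur[PIDX(0, 0, 0)] = 0;
  for (int i = 0; i <= n1; i++) {
    for (int j = 0; j <= n2; j++)
      for (int k = 0; k <= n3; k++) {
        int ch[3] = {i < n1 ? s1[i] : -1, j < n2 ? s2[j] : -1,
                     k < n3 ? s3[k] : -1};
        // min over center residue c of substitution sums, per subset
        ll minc[8];
        {
          for (int S = 1; S <= 7; S++) minc[S] = INF;
          for (int c = 0; c < nres; c++) {
            ll dc[3];
            for (int t = 0; t < 3; t++) dc[t] = (ch[t] >= 0) ? dcost(c, ch[t]) : 0;
            for (int S = 1; S <= 7; S++) {
              ll s = 0;
              if (S & 1) s += dc[0];
              if (S & 2) s += dc[1];
              if (S & 4) s += dc[2];
              if (s < minc[S]) minc[S] = s;
            }
          }
        }
        for (int st = 0; st < NS; st++) {
          ll val = cur[PIDX(j, k, st)];
          if (val >= INF) continue;
          for (int S = 1; S <= 7; S++) {
            int d1 = S & 1, d2 = (S >> 1) & 1, d3 = (S >> 2) & 1;
            if ((d1 && ch[0] < 0) || (d2 && ch[1] < 0) || (d3 && ch[2] < 0))
              continue;
            std::vector<ll> &tp = d1 ? nxt : cur;
            size_t tid = PIDX(j + d2, k + d3, 0);
            // center residue move
            {
              int ts = resTgt[st][S];
              ll nv = val + minc[S] + resExtra[st][S];
              if (nv < tp[tid + ts]) {
                tp[tid + ts] = nv;
                if (want_median)
                  bp[(size_t)(i + d1) * plane + tid + ts] =
                      (uint16_t)(S | (st << 5));
              }
            }
            // center gap move
            {
              int ts = gapTgt[st][S];
              ll nv = val + gapExtra[st][S];
              if (nv < tp[tid + ts]) {
                tp[tid + ts] = nv;
                if (want_median)
                  bp[(size_t)(i + d1) * plane + tid + ts] =
                      (uint16_t)(S | 8 | (st << 5));
              }
            }
          }
        }
      }
    if (i < n1) {
      std::swap(cur, nxt);
      std::fill(nxt.begin(), nxt.end(), INF);
    }
  }
  ll cost = INF;
  int bestst = 0;
  for (int st = 0; st < NS; st++) {
    ll v = cur[PIDX(n2, n3, st)];
    if (v < cost) { cost = v; bestst = st; }
  }
  List out = List::create(_["cost"] = (double)cost);
  if (want_median) {
    std::vector<int> med;
    int i = n1, j = n2, k = n3, st = bestst;
    while (i > 0 || j > 0 || k > 0) {
      uint16_t mv = bp[(size_t)i * plane + PIDX(j, k, st)];
      int S = mv & 7;
      bool cgap = (mv & 8) != 0;
      int src = mv >> 5;
      int d1 = S & 1, d2 = (S >> 1) & 1, d3 = (S >> 2) & 1;
      i -= d1; j -= d2; k -= d3;
      if (!cgap) {
        int ch[3] = {d1 ? s1[i] : -1, d2 ? s2[j] : -1, d3 ? s3[k] : -1};
        ll mc = INF; int bc = -1;
        for (int c = 0; c < nres; c++) {
          ll s = 0;
          for (int t = 0; t < 3; t++)
            if (ch[t] >= 0) s += dcost(c, ch[t]);
          if (s < mc) { mc = s; bc = c; }
        }
        med.push_back(bc + 1);
      }
      st = src;
    }
    std::reverse(med.begin(), med.end());
    out["median"] = wrap(med);
  }
#undef PIDX
  return out;
}
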