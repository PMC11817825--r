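// Nearest-neighbor thermodynamic model for single-stranded DNA and a
// Zuker-style minimum-free-energy dynamic program over pseudoknot-free
// secondary structures.
//
// Conventions (must stay in sync with the R layer):
//   * bases are coded A=1, C=2, G=3, T=4; 0 stands for "no base" (N / out
//     of range);
//   * pair types follow the parameter-file row order CG=1, GC=2, GT=3,
//     TG=4, AT=5, TA=6; 0 = pair not allowed;
//   * all energies are integers in hundredths of kcal/mol (dekacal);
//   * dangle model is "d2": both-side terminal mismatches on every helix
//     end in exterior and multi loops, regardless of whether the
//     neighboring base is itself paired;
//   * minimum hairpin loop size is 3 unpaired bases; interior loops are
//     restricted to <= 30 unpaired bases total in the DP (evaluation of a
//     given structure has no such limit, using logarithmic extrapolation).

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static const int E_INF = 10000000;  // "forbidden", matches ViennaRNA's INF
static const int MAXLOOP = 30;      // interior-loop size cap in the DP

// saturating add so E_INF never overflows into a valid energy
static inline int iadd(int a, int b) {
  if (a >= E_INF || b >= E_INF) return E_INF;
  return a + b;
}

// pair type lookup: pt_tab[a][b], a,b in 0..4
static const int PT_TAB[5][5] = {
  // -  A  C  G  T
  {0, 0, 0, 0, 0},   // -
  {0, 0, 0, 0, 5},   // A:  A-T = 5
  {0, 0, 0, 1, 0},   // C:  C-G = 1
  {0, 0, 2, 0, 3},   // G:  G-C = 2, G-T = 3
  {0, 6, 0, 4, 0}    // T:  T-A = 6, T-G = 4
};

static inline int pair_type(int a, int b) { return PT_TAB[a][b]; }

struct NNParams {
  const int *stack;     // [6][6] stored 7x7 (row NN unused)
  const int *mm_h;      // [7][5][5] mismatch hairpin
  const int *mm_i;      // mismatch interior
  const int *mm_i1n;    // mismatch interior 1xn
  const int *mm_i23;    // mismatch interior 2x3
  const int *mm_m;      // mismatch multiloop
  const int *mm_e;      // mismatch exterior
  const int *d5;        // [7][5]
  const int *d3;        // [7][5]
  const int *i11;       // [7][7][5][5]
  const int *i21;       // [7][7][5][5][5]
  const int *i22;       // [6][6][4][4][4][4]
  const int *hp;        // [31]
  const int *bulge;     // [31]
  const int *intl;      // [31]
  int ml_base, ml_closing, ml_intern;
  int ninio, max_ninio;
  int term_au;
  double lxc;
  std::map<std::string, int> tetra, tri, hexa;

  int st(int t1, int t2) const { return stack[(t1 - 1) * 7 + (t2 - 1)]; }
  int mm(const int *tab, int t, int x, int y) const {
    return tab[((t - 1) * 5 + x) * 5 + y];
  }
  int dang5(int t, int x) const { return d5[(t - 1) * 5 + x]; }
  int dang3(int t, int x) const { return d3[(t - 1) * 5 + x]; }
  int int11(int t1, int t2, int x, int y) const {
    return i11[(((t1 - 1) * 7 + (t2 - 1)) * 5 + x) * 5 + y];
  }
  int int21(int t1, int t2, int x, int y, int z) const {
    return i21[((((t1 - 1) * 7 + (t2 - 1)) * 5 + x) * 5 + y) * 5 + z];
  }
  int int22(int t1, int t2, int a, int b, int c, int d) const {
    if (t1 > 6 || t2 > 6 || a < 1 || b < 1 || c < 1 || d < 1) return E_INF;
    return i22[(((((t1 - 1) * 6 + (t2 - 1)) * 4 + (a - 1)) * 4 + (b - 1)) * 4 +
                (c - 1)) * 4 + (d - 1)];
  }
};

static void fill_special(std::map<std::string, int> &m, SEXP names_, SEXP e_) {
  CharacterVector nm(names_);
  IntegerVector e(e_);
  for (int k = 0; k < nm.size(); ++k) m[as<std::string>(nm[k])] = e[k];
}

static NNParams unpack(const List &par) {
  NNParams p;
  p.stack = INTEGER(par["stack"]);
  p.mm_h = INTEGER(par["mm_hairpin"]);
  p.mm_i = INTEGER(par["mm_interior"]);
  p.mm_i1n = INTEGER(par["mm_interior_1n"]);
  p.mm_i23 = INTEGER(par["mm_interior_23"]);
  p.mm_m = INTEGER(par["mm_multi"]);
  p.mm_e = INTEGER(par["mm_exterior"]);
  p.d5 = INTEGER(par["dangle5"]);
  p.d3 = INTEGER(par["dangle3"]);
  p.i11 = INTEGER(par["int11"]);
  p.i21 = INTEGER(par["int21"]);
  p.i22 = INTEGER(par["int22"]);
  p.hp = INTEGER(par["hairpin"]);
  p.bulge = INTEGER(par["bulge"]);
  p.intl = INTEGER(par["interior"]);
  IntegerVector ml = par["ml"];
  p.ml_base = ml[0]; p.ml_closing = ml[1]; p.ml_intern = ml[2];
  IntegerVector nin = par["ninio"];
  p.ninio = nin[0]; p.max_ninio = nin[1];
  p.term_au = as<int>(par["terminal_au"]);
  p.lxc = as<double>(par["lxc"]);
  List sp = par["special_hairpins"];
  fill_special(p.tetra, List(sp["tetra"])["seq"], List(sp["tetra"])["e"]);
  fill_special(p.tri,   List(sp["tri"])["seq"],   List(sp["tri"])["e"]);
  fill_special(p.hexa,  List(sp["hexa"])["seq"],  List(sp["hexa"])["e"]);
  return p;
}

// ---- loop-face energies -------------------------------------------------

static int e_hairpin(const NNParams &p, int size, int type, int si1, int sj1,
                     const std::string &ctx) {
  if (size < 3) return E_INF;
  int e = (size <= MAXLOOP)
              ? p.hp[size]
              : p.hp[MAXLOOP] + (int)(p.lxc * std::log((double)size / MAXLOOP));
  // special tabulated loops (closing pair + loop sequence); empty for the
  // bundled DNA set but honored for any parameter file that carries them
  if (!ctx.empty()) {
    if (size == 4) {
      std::map<std::string, int>::const_iterator it = p.tetra.find(ctx);
      if (it != p.tetra.end()) return it->second;
    } else if (size == 6) {
      std::map<std::string, int>::const_iterator it = p.hexa.find(ctx);
      if (it != p.hexa.end()) return it->second;
    } else if (size == 3) {
      std::map<std::string, int>::const_iterator it = p.tri.find(ctx);
      if (it != p.tri.end()) return it->second;
    }
  }
  if (size == 3) return e + (type > 2 ? p.term_au : 0);
  return e + p.mm(p.mm_h, type, si1, sj1);
}

// interior loop between closing pair (type, si1/sj1 inner neighbors) and
// enclosed pair (type2 = reversed inner pair, sp1/sq1 outer neighbors)
static int e_intloop(const NNParams &p, int n1, int n2, int type, int type2,
                     int si1, int sj1, int sp1, int sq1) {
  int nl = n1 > n2 ? n1 : n2;
  int ns = n1 > n2 ? n2 : n1;
  if (nl == 0) return p.st(type, type2);  // stack
  if (ns == 0) {                          // bulge
    int e = (nl <= MAXLOOP)
                ? p.bulge[nl]
                : p.bulge[MAXLOOP] +
                      (int)(p.lxc * std::log((double)nl / MAXLOOP));
    if (nl == 1) {
      e += p.st(type, type2);
    } else {
      if (type > 2) e += p.term_au;
      if (type2 > 2) e += p.term_au;
    }
    return e;
  }
  if (ns == 1) {
    if (nl == 1) return p.int11(type, type2, si1, sj1);
    if (nl == 2) {
      if (n1 == 1) return p.int21(type, type2, si1, sq1, sj1);
      return p.int21(type2, type, sq1, si1, sp1);
    }
    // 1 x n, n > 2
    int u = nl + 1;
    int e = (u <= MAXLOOP)
                ? p.intl[u]
                : p.intl[MAXLOOP] + (int)(p.lxc * std::log((double)u / MAXLOOP));
    int asym = (nl - ns) * p.ninio;
    e += (asym < p.max_ninio) ? asym : p.max_ninio;
    e += p.mm(p.mm_i1n, type, si1, sj1) + p.mm(p.mm_i1n, type2, sq1, sp1);
    return e;
  }
  if (ns == 2) {
    if (nl == 2) return p.int22(type, type2, si1, sp1, sq1, sj1);
    if (nl == 3) {
      int e = p.intl[5] + p.ninio;
      e += p.mm(p.mm_i23, type, si1, sj1) + p.mm(p.mm_i23, type2, sq1, sp1);
      return e;
    }
  }
  // generic interior loop
  int u = nl + ns;
  int e = (u <= MAXLOOP)
              ? p.intl[u]
              : p.intl[MAXLOOP] + (int)(p.lxc * std::log((double)u / MAXLOOP));
  int asym = (nl - ns) * p.ninio;
  e += (asym < p.max_ninio) ? asym : p.max_ninio;
  e += p.mm(p.mm_i, type, si1, sj1) + p.mm(p.mm_i, type2, sq1, sp1);
  return e;
}

// contribution of one helix end inside a multiloop (d2)
static int e_mlstem(const NNParams &p, int type, int si1, int sj1) {
  int e = p.mm(p.mm_m, type, si1, sj1);
  if (type > 2) e += p.term_au;
  return e + p.ml_intern;
}

// contribution of one helix end in the exterior loop (d2); si1/sj1 = 0 at
// the sequence boundary
static int e_extstem(const NNParams &p, int type, int si1, int sj1) {
  int e = 0;
  if (si1 > 0 && sj1 > 0)
    e = p.mm(p.mm_e, type, si1, sj1);
  else if (si1 > 0)
    e = p.dang5(type, si1);
  else if (sj1 > 0)
    e = p.dang3(type, sj1);
  if (type > 2) e += p.term_au;
  return e;
}

static std::string ctx_string(const IntegerVector &s, int i, int j) {
  static const char B[5] = {'N', 'A', 'C', 'G', 'T'};
  std::string out;
  for (int k = i; k <= j; ++k) out.push_back(B[s[k - 1]]);
  return out;
}

// ---- exported single-face primitives (used by the R loop_energy API) ----

// [[Rcpp::export(name = ".e_hairpin_cpp")]]
int e_hairpin_cpp(List par, int size, int type, int si1, int sj1,
                  std::string ctx) {
  NNParams p = unpack(par);
  return e_hairpin(p, size, type, si1, sj1, ctx);
}

// [[Rcpp::export(name = ".e_intloop_cpp")]]
int e_intloop_cpp(List par, int n1, int n2, int type, int type2, int si1,
                  int sj1, int sp1, int sq1) {
  NNParams p = unpack(par);
  return e_intloop(p, n1, n2, type, type2, si1, sj1, sp1, sq1);
}

// [[Rcpp::export(name = ".e_mlstem_cpp")]]
int e_mlstem_cpp(List par, int type, int si1, int sj1) {
  NNParams p = unpack(par);
  return e_mlstem(p, type, si1, sj1);
}

// [[Rcpp::export(name = ".e_extstem_cpp")]]
int e_extstem_cpp(List par, int type, int si1, int sj1) {
  NNParams p = unpack(par);
  return e_extstem(p, type, si1, sj1);
}

// ---- evaluation of a given structure ------------------------------------

// s: base codes 1..4; pt: 1-based partner or 0; returns energy in
// hundredths of kcal/mol
// [[Rcpp::export(name = ".eval_energy_cpp")]]
int eval_energy_cpp(IntegerVector s, IntegerVector pt, List par) {
  NNParams p = unpack(par);
  int n = s.size();
  if (pt.size() != n) stop("sequence and structure lengths differ");
  // base at position k (1-based), 0 outside
  std::vector<int> S(n + 2, 0);
  for (int k = 1; k <= n; ++k) S[k] = s[k - 1];

  for (int i = 1; i <= n; ++i) {
    int j = pt[i - 1];
    if (j == 0) continue;
    if (j < 1 || j > n || pt[j - 1] != i || j == i)
      stop("pair table is not symmetric at position %d", i);
    if (j > i && pair_type(S[i], S[j]) == 0)
      stop("disallowed base pair between positions %d and %d", i, j);
    if (j > i && j - i - 1 < 3)
      stop("hairpin loop shorter than 3 at pair (%d,%d)", i, j);
  }

  int e = 0;
  // exterior loop
  {
    int i = 1;
    while (i <= n) {
      int j = pt[i - 1];
      if (j > i) {
        int t = pair_type(S[i], S[j]);
        e = iadd(e, e_extstem(p, t, i > 1 ? S[i - 1] : 0, j < n ? S[j + 1] : 0));
        i = j + 1;
      } else if (j != 0 && j < i) {
        stop("pseudoknotted or malformed exterior loop at position %d", i);
      } else {
        ++i;
      }
    }
  }
  // loop closed by each pair (i, j)
  for (int i = 1; i <= n; ++i) {
    int j = pt[i - 1];
    if (j <= i) continue;
    // children: maximal pairs directly inside (i, j)
    std::vector<std::pair<int, int> > kids;
    int u = 0;
    int k = i + 1;
    while (k < j) {
      int q = pt[k - 1];
      if (q == 0) { ++u; ++k; continue; }
      if (q < i || q > j) stop("pseudoknot crossing at pair (%d,%d)", k, q);
      kids.push_back(std::make_pair(k, q));
      k = q + 1;
    }
    int t = pair_type(S[i], S[j]);
    if (kids.empty()) {
      e = iadd(e, e_hairpin(p, j - i - 1, t, S[i + 1], S[j - 1],
                            ctx_string(s, i, j)));
    } else if (kids.size() == 1) {
      int pp = kids[0].first, qq = kids[0].second;
      int t2 = pair_type(S[qq], S[pp]);
      e = iadd(e, e_intloop(p, pp - i - 1, j - qq - 1, t, t2, S[i + 1],
                            S[j - 1], S[pp - 1], S[qq + 1]));
    } else {
      int ml = iadd(p.ml_closing,
                    e_mlstem(p, pair_type(S[j], S[i]), S[j - 1], S[i + 1]));
      for (size_t b = 0; b < kids.size(); ++b) {
        int pp = kids[b].first, qq = kids[b].second;
        ml = iadd(ml, e_mlstem(p, pair_type(S[pp], S[qq]), S[pp - 1], S[qq + 1]));
      }
      ml = iadd(ml, u * p.ml_base);
      e = iadd(e, ml);
    }
  }
  return e;
}

// ---- MFE folding ---------------------------------------------------------

struct DP {
  int n;
  std::vector<int> c, fml, fm1, f;
  int &C(int i, int j) { return c[(i - 1) * n + (j - 1)]; }
  int &ML(int i, int j) { return fml[(i - 1) * n + (j - 1)]; }
  int &M1(int i, int j) { return fm1[(i - 1) * n + (j - 1)]; }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector s, List par) {
  NNParams p = unpack(par);
  int n = s.size();
  std::vector<int> S(n + 2, 0);
  for (int k = 1; k <= n; ++k) S[k] = s[k - 1];

  DP dp;
  dp.n = n;
  dp.c.assign((size_t)n * n, E_INF);
  dp.fml.assign((size_t)n * n, E_INF);
  dp.fm1.assign((size_t)n * n, E_INF);
  dp.f.assign(n + 1, 0);

  // helper lambdas ----------------------------------------------------
  // d2 multiloop stem term for branch (i, j); neighbors always inside
  // the closing loop when used
  #define MLSTEM(i, j) \
    e_mlstem(p, pair_type(S[(i)], S[(j)]), S[(i) - 1], S[(j) + 1])
  #define EXTSTEM(i, j)                                              \
    e_extstem(p, pair_type(S[(i)], S[(j)]), (i) > 1 ? S[(i) - 1] : 0, \
              (j) < n ? S[(j) + 1] : 0)

  for (int len = 5; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int t = pair_type(S[i], S[j]);
      // ---- C(i, j): i pairs j --------------------------------------
      if (t > 0) {
        int best = e_hairpin(p, j - i - 1, t, S[i + 1], S[j - 1],
                             ctx_string(s, i, j));
        // interior loops / stacks, total unpaired <= MAXLOOP
        int pmax = i + 1 + MAXLOOP;
        if (pmax > j - 5) pmax = j - 5;
        for (int pp = i + 1; pp <= pmax; ++pp) {
          int n1 = pp - i - 1;
          int qmin = j - 1 - (MAXLOOP - n1);
          if (qmin < pp + 4) qmin = pp + 4;
          for (int qq = j - 1; qq >= qmin; --qq) {
            int cin = dp.C(pp, qq);
            if (cin >= E_INF) continue;
            int t2 = pair_type(S[qq], S[pp]);
            int cand = iadd(
                cin, e_intloop(p, n1, j - qq - 1, t, t2, S[i + 1], S[j - 1],
                               S[pp - 1], S[qq + 1]));
            if (cand < best) best = cand;
          }
        }
        // multiloop closing
        if (len >= 12) {  // needs >= 2 branches of >= 5 nt inside
          int mlclose =
              iadd(p.ml_closing,
                   e_mlstem(p, pair_type(S[j], S[i]), S[j - 1], S[i + 1]));
          for (int u = i + 1; u <= j - 2; ++u) {
            int cand = iadd(iadd(dp.ML(i + 1, u), dp.M1(u + 1, j - 1)), mlclose);
            if (cand < best) best = cand;
          }
        }
        dp.C(i, j) = best;
      }
      // ---- M1(i, j): exactly one branch, starting at i -------------
      {
        int best = E_INF;
        if (j - 1 >= i) best = iadd(dp.M1(i, j - 1), p.ml_base);
        if (t > 0 && dp.C(i, j) < E_INF && i > 1 && j < n) {
          int cand = iadd(dp.C(i, j), MLSTEM(i, j));
          if (cand < best) best = cand;
        }
        dp.M1(i, j) = best;
      }
      // ---- ML(i, j): >= 1 branch ------------------------------------
      {
        int best = E_INF;
        int cand = iadd(dp.ML(i + 1, j), p.ml_base);
        if (cand < best) best = cand;
        cand = iadd(dp.ML(i, j - 1), p.ml_base);
        if (cand < best) best = cand;
        if (t > 0 && dp.C(i, j) < E_INF && i > 1 && j < n) {
          cand = iadd(dp.C(i, j), MLSTEM(i, j));
          if (cand < best) best = cand;
        }
        for (int u = i + 4; u <= j - 5; ++u) {
          cand = iadd(dp.ML(i, u), dp.M1(u + 1, j));
          if (cand < best) best = cand;
        }
        dp.ML(i, j) = best;
      }
    }
  }
  // fill short spans of M1/ML with INF already done by init; exterior:
  for (int j = 1; j <= n; ++j) {
    int best = dp.f[j - 1];
    for (int i = 1; i + 4 <= j; ++i) {
      if (dp.C(i, j) >= E_INF) continue;
      int cand = iadd(dp.f[i - 1], iadd(dp.C(i, j), EXTSTEM(i, j)));
      if (cand < best) best = cand;
    }
    dp.f[j] = best;
  }

  // ---- traceback ----------------------------------------------------
  IntegerVector pt(n, 0);
  std::vector<std::pair<std::pair<int, int>, int> > stack_;  // ((i,j), which)
  // which: 0 = trace C, 1 = trace ML, 2 = trace M1

  // exterior
  {
    int j = n;
    while (j > 0) {
      bool found = false;
      // prefer the pairing branch, smaller 5' index first
      for (int i = 1; i + 4 <= j && !found; ++i) {
        if (dp.C(i, j) >= E_INF) continue;
        if (iadd(dp.f[i - 1], iadd(dp.C(i, j), EXTSTEM(i, j))) == dp.f[j]) {
          stack_.push_back(std::make_pair(std::make_pair(i, j), 0));
          j = i - 1;
          found = true;
        }
      }
      if (!found) {
        if (dp.f[j] != dp.f[j - 1]) stop("traceback failure in exterior loop");
        --j;
      }
    }
  }

  while (!stack_.empty()) {
    int i = stack_.back().first.first;
    int j = stack_.back().first.second;
    int which = stack_.back().second;
    stack_.pop_back();

    if (which == 2) {  // M1
      while (dp.M1(i, j) == iadd(dp.M1(i, j - 1), p.ml_base)) --j;
      stack_.push_back(std::make_pair(std::make_pair(i, j), 0));
      continue;
    }
    if (which == 1) {  // ML
      bool done = false;
      while (!done) {
        if (pair_type(S[i], S[j]) > 0 && dp.C(i, j) < E_INF &&
            dp.ML(i, j) == iadd(dp.C(i, j), MLSTEM(i, j))) {
          stack_.push_back(std::make_pair(std::make_pair(i, j), 0));
          done = true;
        } else if (dp.ML(i, j) == iadd(dp.ML(i + 1, j), p.ml_base)) {
          ++i;
        } else if (dp.ML(i, j) == iadd(dp.ML(i, j - 1), p.ml_base)) {
          --j;
        } else {
          bool split = false;
          for (int u = i + 4; u <= j - 5 && !split; ++u) {
            if (dp.ML(i, j) == iadd(dp.ML(i, u), dp.M1(u + 1, j))) {
              stack_.push_back(std::make_pair(std::make_pair(i, u), 1));
              stack_.push_back(std::make_pair(std::make_pair(u + 1, j), 2));
              split = true;
            }
          }
          if (!split) stop("traceback failure in multiloop segment");
          done = true;
        }
      }
      continue;
    }

    // which == 0: C(i, j), i pairs j
    pt[i - 1] = j;
    pt[j - 1] = i;
    int t = pair_type(S[i], S[j]);
    int cij = dp.C(i, j);
    bool found = false;
    // pairing branch first: interior loops, 5'-most inner pair
    int pmax = i + 1 + MAXLOOP;
    if (pmax > j - 5) pmax = j - 5;
    for (int pp = i + 1; pp <= pmax && !found; ++pp) {
      int n1 = pp - i - 1;
      int qmin = j - 1 - (MAXLOOP - n1);
      if (qmin < pp + 4) qmin = pp + 4;
      for (int qq = j - 1; qq >= qmin && !found; --qq) {
        if (dp.C(pp, qq) >= E_INF) continue;
        int t2 = pair_type(S[qq], S[pp]);
        if (iadd(dp.C(pp, qq),
                 e_intloop(p, n1, j - qq - 1, t, t2, S[i + 1], S[j - 1],
                           S[pp - 1], S[qq + 1])) == cij) {
          stack_.push_back(std::make_pair(std::make_pair(pp, qq), 0));
          found = true;
        }
      }
    }
    if (found) continue;
    if (e_hairpin(p, j - i - 1, t, S[i + 1], S[j - 1], ctx_string(s, i, j)) ==
        cij)
      continue;
    // multiloop
    {
      int mlclose = iadd(
          p.ml_closing, e_mlstem(p, pair_type(S[j], S[i]), S[j - 1], S[i + 1]));
      for (int u = i + 1; u <= j - 2 && !found; ++u) {
        if (iadd(iadd(dp.ML(i + 1, u), dp.M1(u + 1, j - 1)), mlclose) == cij) {
          stack_.push_back(std::make_pair(std::make_pair(i + 1, u), 1));
          stack_.push_back(std::make_pair(std::make_pair(u + 1, j - 1), 2));
          found = true;
        }
      }
    }
    if (!found) stop("traceback failure at pair (%d,%d)", i, j);
  }

  #undef MLSTEM
  #undef EXTSTEM

  return List::create(_["pt"] = pt, _["energy"] = dp.f[n]);
}
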