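// SHAPE-directed nearest-neighbor folding engine.
//
// Minimum free energy structure (Zuker-style DP with traceback) and
// McCaskill partition-function pair probabilities (inside-outside), under a
// reduced energy model: WC+GU stacking, loop-length penalties with
// Jacobson-Stockmayer extrapolation, affine multibranch loops, and optional
// per-nucleotide pseudo-free-energy terms applied once per helix stack a
// nucleotide participates in.
//
// The multiloop grammar is unambiguous so that the partition function counts
// every nested structure exactly once:
//   Zb(i,j)  : i pairs j (hairpin | interior | multiloop closing)
//   ZM1(i,j) : exactly one branch starting at i, 3' tail unpaired
//   ZT1(i,j) : one branch with unpaired leader (ZT1 = c*ZT1(i+1,j) + ZM1)
//   ZM(i,j)  : one or more branches (ZM = ZT1 + sum_k ZM(i,k-1) ZM1(k,j))
// The MFE recursions minimize over the same decomposition, tracking pair
// counts as a lexicographic tie-break (fewer pairs preferred), so traceback
// is deterministic.
//
// Partition-function magnitudes are controlled by a per-nucleotide scale
// q = exp(E_mfe / (RT n)); every cell spanning m nucleotides carries q^m and
// the factors cancel exactly in P(i,j) = Zb * Ob / Z.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = 1e18;
const double EPS = 1e-9;

struct Params {
  double stack[6][6];
  std::vector<double> hairpin;   // index by loop size
  std::vector<double> bulge;
  std::vector<double> internal_;
  double ml_a, ml_b, ml_c;
  double RT;
  int max_dist;
  int max_interior;
};

// pair codes: AU=0 UA=1 GC=2 CG=3 GU=4 UG=5, -1 not pairable (A=0 C=1 G=2 U=3)
inline int pairtype(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

inline double loop_tab(const std::vector<double> &tab, int sz, double RT,
                       int minsz) {
  int last = (int)tab.size() - 1;
  if (sz < minsz) return INF;
  if (sz <= last) return tab[sz];
  return tab[last] + 1.75 * RT * std::log((double)sz / (double)last);
}

struct Engine {
  int n;
  std::vector<int> s;            // 1-based codes
  std::vector<double> ps;        // 1-based pseudo energies (0 where no data)
  Params par;
  std::vector<int> pt;           // pair type per (i,j), -1 disallowed

  // MFE arrays (energy, pair count)
  std::vector<double> V, M1e, T1e, Me, W;
  std::vector<int> Vn, M1n, T1n, Mn, Wn;

  // PF arrays
  std::vector<double> Zb, ZM1, ZT1, ZM, Zf, Zr;
  std::vector<double> Ob, OM1, OT1, OM;
  std::vector<double> qpow;
  double qscale, Ztot;

  inline int ix(int i, int j) const { return i * (n + 2) + j; }

  inline bool can_pair(int i, int j) const {
    return j - i >= 4 && j - i <= par.max_dist && pt[ix(i, j)] >= 0;
  }

  inline double hairpinE(int i, int j) const {
    return loop_tab(par.hairpin, j - i - 1, par.RT, 3);
  }

  // energy of the interior loop / stack closed by (i,j) with inner pair (k,l)
  inline double interiorE(int i, int j, int k, int l) const {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 == 0 && l2 == 0) {
      return par.stack[pt[ix(i, j)]][pt[ix(k, l)]] +
             ps[i] + ps[j] + ps[k] + ps[l];
    }
    if (l1 == 0 || l2 == 0) return loop_tab(par.bulge, l1 + l2, par.RT, 1);
    return loop_tab(par.internal_, l1 + l2, par.RT, 2);
  }

  // ---- lexicographic (energy, npairs) helpers -------------------------
  static inline bool better(double e, int np, double be, int bnp) {
    if (e < be - EPS) return true;
    if (e <= be + EPS && np < bnp) return true;
    return false;
  }
  static inline bool matches(double e, int np, double be, int bnp) {
    return std::fabs(e - be) <= 1e-6 && np == bnp;
  }

  void run_mfe() {
    int N = (n + 2) * (n + 2);
    V.assign(N, INF); M1e.assign(N, INF); T1e.assign(N, INF); Me.assign(N, INF);
    Vn.assign(N, 0); M1n.assign(N, 0); T1n.assign(N, 0); Mn.assign(N, 0);
    W.assign(n + 1, 0.0); Wn.assign(n + 1, 0);

    for (int L = 5; L <= n; ++L) {
      for (int i = 1; i + L - 1 <= n; ++i) {
        int j = i + L - 1;
        // --- V(i,j)
        if (can_pair(i, j)) {
          double be = hairpinE(i, j); int bn = 1;
          int kmax = std::min(i + par.max_interior + 1, j - 5);
          for (int k = i + 1; k <= kmax; ++k) {
            int l1 = k - i - 1;
            int lmin = std::max(k + 4, j - 1 - (par.max_interior - l1));
            for (int l = lmin; l <= j - 1; ++l) {
              double vin = V[ix(k, l)];
              if (vin >= INF) continue;
              double e = interiorE(i, j, k, l) + vin;
              int np = 1 + Vn[ix(k, l)];
              if (better(e, np, be, bn)) { be = e; bn = np; }
            }
          }
          for (int k = i + 6; k <= j - 5; ++k) {
            double ml = Me[ix(i + 1, k - 1)], mr = M1e[ix(k, j - 1)];
            if (ml >= INF || mr >= INF) continue;
            double e = par.ml_a + par.ml_b + ml + mr;
            int np = 1 + Mn[ix(i + 1, k - 1)] + M1n[ix(k, j - 1)];
            if (better(e, np, be, bn)) { be = e; bn = np; }
          }
          V[ix(i, j)] = be; Vn[ix(i, j)] = bn;
        }
        // --- M1(i,j): branch starts at i
        {
          double be = INF; int bn = 0;
          if (j - 1 >= i && M1e[ix(i, j - 1)] < INF) {
            be = M1e[ix(i, j - 1)] + par.ml_c; bn = M1n[ix(i, j - 1)];
          }
          if (V[ix(i, j)] < INF) {
            double e = V[ix(i, j)] + par.ml_b; int np = Vn[ix(i, j)];
            if (better(e, np, be, bn)) { be = e; bn = np; }
          }
          M1e[ix(i, j)] = be; M1n[ix(i, j)] = bn;
        }
        // --- T1(i,j): one branch, unpaired leader allowed
        {
          double be = M1e[ix(i, j)]; int bn = M1n[ix(i, j)];
          if (i + 1 <= j && T1e[ix(i + 1, j)] < INF) {
            double e = T1e[ix(i + 1, j)] + par.ml_c; int np = T1n[ix(i + 1, j)];
            if (better(e, np, be, bn)) { be = e; bn = np; }
          }
          T1e[ix(i, j)] = be; T1n[ix(i, j)] = bn;
        }
        // --- M(i,j): >= 1 branch
        {
          double be = T1e[ix(i, j)]; int bn = T1n[ix(i, j)];
          for (int k = i + 5; k <= j - 4; ++k) {
            double ml = Me[ix(i, k - 1)], mr = M1e[ix(k, j)];
            if (ml >= INF || mr >= INF) continue;
            double e = ml + mr; int np = Mn[ix(i, k - 1)] + M1n[ix(k, j)];
            if (better(e, np, be, bn)) { be = e; bn = np; }
          }
          Me[ix(i, j)] = be; Mn[ix(i, j)] = bn;
        }
      }
    }
    // external
    for (int j = 1; j <= n; ++j) {
      double be = W[j - 1]; int bn = Wn[j - 1];
      for (int i = 1; i <= j - 4; ++i) {
        if (V[ix(i, j)] >= INF) continue;
        double e = W[i - 1] + V[ix(i, j)]; int np = Wn[i - 1] + Vn[ix(i, j)];
        if (better(e, np, be, bn)) { be = e; bn = np; }
      }
      W[j] = be; Wn[j] = bn;
    }
  }

  // deterministic traceback; fills partner vector (1-based, 0 = unpaired)
  void traceback(std::vector<int> &partner) {
    partner.assign(n + 1, 0);
    struct Item { int i, j; char arr; }; // arr: 'W','V','1','T','M'
    std::vector<Item> st;
    st.push_back({1, n, 'W'});
    while (!st.empty()) {
      Item it = st.back(); st.pop_back();
      int i = it.i, j = it.j;
      if (i > j) continue;
      if (it.arr == 'W') {
        // external over [1..j] (i unused; stored j only)
        int jj = j;
        while (jj >= 1) {
          if (matches(W[jj - 1], Wn[jj - 1], W[jj], Wn[jj])) { --jj; continue; }
          bool found = false;
          for (int i2 = 1; i2 <= jj - 4 && !found; ++i2) {
            if (V[ix(i2, jj)] >= INF) continue;
            if (matches(W[i2 - 1] + V[ix(i2, jj)], Wn[i2 - 1] + Vn[ix(i2, jj)],
                        W[jj], Wn[jj])) {
              st.push_back({i2, jj, 'V'});
              jj = i2 - 1; found = true;
            }
          }
          if (!found) stop("traceback failure in external loop");
        }
      } else if (it.arr == 'V') {
        partner[i] = j; partner[j] = i;
        double be = V[ix(i, j)]; int bn = Vn[ix(i, j)];
        if (matches(hairpinE(i, j), 1, be, bn)) continue;
        bool found = false;
        int kmax = std::min(i + par.max_interior + 1, j - 5);
        for (int k = i + 1; k <= kmax && !found; ++k) {
          int l1 = k - i - 1;
          int lmin = std::max(k + 4, j - 1 - (par.max_interior - l1));
          for (int l = lmin; l <= j - 1 && !found; ++l) {
            if (V[ix(k, l)] >= INF) continue;
            if (matches(interiorE(i, j, k, l) + V[ix(k, l)], 1 + Vn[ix(k, l)],
                        be, bn)) {
              st.push_back({k, l, 'V'}); found = true;
            }
          }
        }
        for (int k = i + 6; k <= j - 5 && !found; ++k) {
          double ml = Me[ix(i + 1, k - 1)], mr = M1e[ix(k, j - 1)];
          if (ml >= INF || mr >= INF) continue;
          if (matches(par.ml_a + par.ml_b + ml + mr,
                      1 + Mn[ix(i + 1, k - 1)] + M1n[ix(k, j - 1)], be, bn)) {
            st.push_back({i + 1, k - 1, 'M'});
            st.push_back({k, j - 1, '1'});
            found = true;
          }
        }
        if (!found) stop("traceback failure in paired state");
      } else if (it.arr == '1') {
        int jj = j;
        while (jj - 1 >= i &&
               matches(M1e[ix(i, jj - 1)] + par.ml_c, M1n[ix(i, jj - 1)],
                       M1e[ix(i, jj)], M1n[ix(i, jj)]))
          --jj;
        if (V[ix(i, jj)] < INF &&
            matches(V[ix(i, jj)] + par.ml_b, Vn[ix(i, jj)],
                    M1e[ix(i, jj)], M1n[ix(i, jj)])) {
          st.push_back({i, jj, 'V'});
        } else stop("traceback failure in branch state");
      } else if (it.arr == 'T') {
        int ii = i;
        while (ii + 1 <= j &&
               matches(T1e[ix(ii + 1, j)] + par.ml_c, T1n[ix(ii + 1, j)],
                       T1e[ix(ii, j)], T1n[ix(ii, j)]))
          ++ii;
        st.push_back({ii, j, '1'});
      } else { // 'M'
        double be = Me[ix(i, j)]; int bn = Mn[ix(i, j)];
        if (matches(T1e[ix(i, j)], T1n[ix(i, j)], be, bn)) {
          st.push_back({i, j, 'T'}); continue;
        }
        bool found = false;
        for (int k = i + 5; k <= j - 4 && !found; ++k) {
          double ml = Me[ix(i, k - 1)], mr = M1e[ix(k, j)];
          if (ml >= INF || mr >= INF) continue;
          if (matches(ml + mr, Mn[ix(i, k - 1)] + M1n[ix(k, j)], be, bn)) {
            st.push_back({i, k - 1, 'M'});
            st.push_back({k, j, '1'});
            found = true;
          }
        }
        if (!found) stop("traceback failure in multiloop state");
      }
    }
  }

  void run_pf() {
    int N = (n + 2) * (n + 2);
    Zb.assign(N, 0.0); ZM1.assign(N, 0.0); ZT1.assign(N, 0.0); ZM.assign(N, 0.0);
    Zf.assign(n + 2, 0.0); Zr.assign(n + 3, 0.0);
    double emfe = W[n];
    qscale = (n > 0) ? std::exp(emfe / (par.RT * n)) : 1.0;
    qpow.assign(n + 2, 1.0);
    for (int m = 1; m <= n + 1; ++m) qpow[m] = qpow[m - 1] * qscale;
    double ec = std::exp(-par.ml_c / par.RT) * qscale;
    double eb = std::exp(-par.ml_b / par.RT);
    double wml = std::exp(-(par.ml_a + par.ml_b) / par.RT);

    for (int L = 5; L <= n; ++L) {
      for (int i = 1; i + L - 1 <= n; ++i) {
        int j = i + L - 1;
        int id = ix(i, j);
        if (can_pair(i, j)) {
          double z = std::exp(-hairpinE(i, j) / par.RT) * qpow[L];
          int kmax = std::min(i + par.max_interior + 1, j - 5);
          for (int k = i + 1; k <= kmax; ++k) {
            int l1 = k - i - 1;
            int lmin = std::max(k + 4, j - 1 - (par.max_interior - l1));
            for (int l = lmin; l <= j - 1; ++l) {
              double zin = Zb[ix(k, l)];
              if (zin <= 0.0) continue;
              z += std::exp(-interiorE(i, j, k, l) / par.RT) *
                   qpow[L - (l - k + 1)] * zin;
            }
          }
          double zm = 0.0;
          for (int k = i + 6; k <= j - 5; ++k)
            zm += ZM[ix(i + 1, k - 1)] * ZM1[ix(k, j - 1)];
          z += wml * qpow[2] * zm;
          Zb[id] = z;
        }
        ZM1[id] = (j - 1 >= i ? ZM1[ix(i, j - 1)] * ec : 0.0) + Zb[id] * eb;
        ZT1[id] = (i + 1 <= j ? ZT1[ix(i + 1, j)] * ec : 0.0) + ZM1[id];
        double zm2 = 0.0;
        for (int k = i + 5; k <= j - 4; ++k)
          zm2 += ZM[ix(i, k - 1)] * ZM1[ix(k, j)];
        ZM[id] = ZT1[id] + zm2;
      }
    }
    Zf[0] = 1.0;
    for (int j = 1; j <= n; ++j) {
      double z = Zf[j - 1] * qscale;
      for (int i = 1; i <= j - 4; ++i) z += Zf[i - 1] * Zb[ix(i, j)];
      Zf[j] = z;
    }
    Zr[n + 1] = 1.0;
    for (int i = n; i >= 1; --i) {
      double z = Zr[i + 1] * qscale;
      for (int j = i + 4; j <= n; ++j) z += Zb[ix(i, j)] * Zr[j + 1];
      Zr[i] = z;
    }
    Ztot = Zf[n];

    // ---- outside pass -------------------------------------------------
    Ob.assign(N, 0.0); OM1.assign(N, 0.0); OT1.assign(N, 0.0); OM.assign(N, 0.0);
    for (int L = n; L >= 5; --L) {
      for (int i = 1; i + L - 1 <= n; ++i) {
        int j = i + L - 1;
        int id = ix(i, j);
        // OM complete: push
        double om = OM[id];
        if (om > 0.0) {
          OT1[id] += om;
          for (int k = i + 5; k <= j - 4; ++k) {
            OM[ix(i, k - 1)] += om * ZM1[ix(k, j)];
            OM1[ix(k, j)] += om * ZM[ix(i, k - 1)];
          }
        }
        // OT1 complete: push
        double ot = OT1[id];
        if (ot > 0.0) {
          if (i + 1 <= j) OT1[ix(i + 1, j)] += ot * ec;
          OM1[id] += ot;
        }
        // OM1 complete: push
        double o1 = OM1[id];
        if (o1 > 0.0) {
          if (j - 1 >= i) OM1[ix(i, j - 1)] += o1 * ec;
          Ob[id] += o1 * eb;
        }
        // Ob: external context, then push
        if (Zb[id] > 0.0) {
          Ob[id] += Zf[i - 1] * Zr[j + 1];
          double ob = Ob[id];
          if (ob > 0.0) {
            int kmax = std::min(i + par.max_interior + 1, j - 5);
            for (int k = i + 1; k <= kmax; ++k) {
              int l1 = k - i - 1;
              int lmin = std::max(k + 4, j - 1 - (par.max_interior - l1));
              for (int l = lmin; l <= j - 1; ++l) {
                if (Zb[ix(k, l)] <= 0.0) continue;
                Ob[ix(k, l)] += ob * std::exp(-interiorE(i, j, k, l) / par.RT) *
                                qpow[L - (l - k + 1)];
              }
            }
            double w2 = ob * wml * qpow[2];
            for (int k = i + 6; k <= j - 5; ++k) {
              OM[ix(i + 1, k - 1)] += w2 * ZM1[ix(k, j - 1)];
              OM1[ix(k, j - 1)] += w2 * ZM[ix(i + 1, k - 1)];
            }
          }
        }
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(IntegerVector seq_codes, NumericVector pseudo, List params,
                 bool want_pf) {
  Engine eng;
  eng.n = seq_codes.size();
  int n = eng.n;
  eng.s.assign(n + 1, -1);
  eng.ps.assign(n + 2, 0.0);
  for (int i = 0; i < n; ++i) {
    eng.s[i + 1] = seq_codes[i];
    eng.ps[i + 1] = pseudo[i];
  }
  NumericMatrix stk = params["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) eng.par.stack[a][b] = stk(a, b);
  NumericVector hp = params["hairpin"], bg = params["bulge"],
                il = params["internal"];
  // tables arrive as dense vectors indexed from size 0
  eng.par.hairpin.assign(hp.begin(), hp.end());
  eng.par.bulge.assign(bg.begin(), bg.end());
  eng.par.internal_.assign(il.begin(), il.end());
  eng.par.ml_a = params["ml_a"];
  eng.par.ml_b = params["ml_b"];
  eng.par.ml_c = params["ml_c"];
  eng.par.RT = params["RT"];
  eng.par.max_dist = params["max_dist"];
  eng.par.max_interior = params["max_interior"];

  eng.pt.assign((n + 2) * (n + 2), -1);
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j)
      eng.pt[eng.ix(i, j)] = pairtype(eng.s[i], eng.s[j]);

  eng.run_mfe();
  std::vector<int> partner;
  eng.traceback(partner);

  IntegerVector part(n);
  for (int i = 1; i <= n; ++i) part[i - 1] = partner[i];
  List out = List::create(_["energy"] = eng.W[n], _["partner"] = part);

  if (want_pf) {
    eng.run_pf();
    NumericMatrix P(n, n);
    for (int i = 1; i <= n; ++i)
      for (int j = i + 4; j <= n; ++j) {
        double zb = eng.Zb[eng.ix(i, j)];
        if (zb <= 0.0) continue;
        double p = zb * eng.Ob[eng.ix(i, j)] / eng.Ztot;
        if (p < 0.0) p = 0.0;
        if (p > 1.0) p = 1.0;
        P(i - 1, j - 1) = p;
        P(j - 1, i - 1) = p;
      }
    out["pairprob"] = P;
    out["log_partition"] = std::log(eng.Ztot) - n * std::log(eng.qscale);
  }
  return out;
}
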