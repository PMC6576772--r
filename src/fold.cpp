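// Nearest-neighbor RNA folding core: Zuker-style MFE with hard constraints,
// McCaskill partition function with inside-outside base-pair probabilities,
// and an intermolecular duplex DP. Energy parameters (stack table, loop
// penalty arrays, multiloop linear coefficients) are supplied from R so the
// same tables drive both this engine and the pure-R enumeration oracle.
//
// Grammar (unambiguous, used identically for MFE and PF):
//   V(i,j): i pairs j. hairpin | two-loop (interior <= max_int unpaired) |
//           multiloop: a + M2(i+1, j-1)
//   M(i,j):  >=1 multiloop branch. i unpaired (+c) | first branch V(i,k)+b,
//            tail empty / all-unpaired (c per nt) / M(k+1,j)
//   M2(i,j): >=2 branches. i unpaired (+c) | V(i,k)+b + M(k+1,j)
//   exterior: unpaired nt are free.
//
// Inner two-loop/multiloop scans only touch (k,l) cells where V is finite,
// via per-row sorted index lists (rows fill left-to-right as i descends).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF_E = 1e18;
static const double BONUS = -1e4;  // per forced pair; subtracted before reporting
static const double EPS = 1e-6;

// A=0, C=1, G=2, U=3, N=4 -> pair types 1..6 (CG GC GU UG AU UA), 0 = none
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

struct FoldCtx {
  int n;
  std::vector<int> s;          // base codes
  std::vector<int> forced;     // -2 free, -1 forced unpaired, >=0 forced partner (0-based)
  std::vector<std::pair<int,int> > fpairs;
  int maxspan, min_hp, max_int;
  const double *stack;         // 6x6 column-major from R
  const double *hp; int nhp;
  const double *bu; int nbu;
  const double *il; int nil;
  double ml_a, ml_b, ml_c;

  double stk(int pt_out, int pt_in) const { return stack[(pt_in - 1) * 6 + (pt_out - 1)]; }
  double hpE(int L) const { return (L >= 1 && L <= nhp) ? hp[L - 1] : INF_E; }

  bool can_pair(int i, int j) const {
    if (j - i - 1 < min_hp) return false;
    if (maxspan > 0 && j - i > maxspan) return false;
    if (pair_type(s[i], s[j]) == 0) return false;
    if (forced[i] == -1 || forced[j] == -1) return false;
    if (forced[i] >= 0 && forced[i] != j) return false;
    if (forced[j] >= 0 && forced[j] != i) return false;
    for (size_t t = 0; t < fpairs.size(); ++t) {
      int a = fpairs[t].first, b = fpairs[t].second;
      if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) return false;
    }
    return true;
  }
  double two_loop_E(int i, int j, int k, int l) const {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 == 0 && l2 == 0) return stk(pair_type(s[i], s[j]), pair_type(s[k], s[l]));
    int sz = l1 + l2;
    if (l1 == 0 || l2 == 0) return (sz <= nbu) ? bu[sz - 1] : INF_E;
    return (sz <= nil) ? il[sz - 1] : INF_E;
  }
};

static FoldCtx make_ctx(const IntegerVector &seqi, int maxspan,
                        const IntegerVector &forced, const NumericMatrix &stack,
                        const NumericVector &hp, const NumericVector &bu,
                        const NumericVector &il, double ml_a, double ml_b,
                        double ml_c, int min_hp, int max_int) {
  FoldCtx cx;
  cx.n = seqi.size();
  cx.s.assign(seqi.begin(), seqi.end());
  cx.forced.resize(cx.n);
  for (int i = 0; i < cx.n; ++i) {
    int f = forced[i];
    cx.forced[i] = (f == 0) ? -2 : (f == -1 ? -1 : f - 1);  // R is 1-based
  }
  for (int i = 0; i < cx.n; ++i)
    if (cx.forced[i] >= 0 && cx.forced[i] > i)
      cx.fpairs.push_back(std::make_pair(i, cx.forced[i]));
  cx.maxspan = maxspan; cx.min_hp = min_hp; cx.max_int = max_int;
  cx.stack = stack.begin();
  cx.hp = hp.begin(); cx.nhp = hp.size();
  cx.bu = bu.begin(); cx.nbu = bu.size();
  cx.il = il.begin(); cx.nil = il.size();
  cx.ml_a = ml_a; cx.ml_b = ml_b; cx.ml_c = ml_c;
  return cx;
}

// ---------------------------------------------------------------- MFE ------

// [[Rcpp::export]]
List c_mfe_fold(IntegerVector seqi, int maxspan, IntegerVector forced,
                NumericMatrix stack, NumericVector hp, NumericVector bu,
                NumericVector il, double ml_a, double ml_b, double ml_c,
                int min_hp, int max_int, bool traceback) {
  FoldCtx cx = make_ctx(seqi, maxspan, forced, stack, hp, bu, il,
                        ml_a, ml_b, ml_c, min_hp, max_int);
  const int n = cx.n;
  std::vector<double> V((size_t)n * n, INF_E), M((size_t)n * n, INF_E),
      M2((size_t)n * n, INF_E);
  std::vector<std::vector<int> > vl(n);  // per row i: sorted j with V finite
  #define IX(i, j) ((size_t)(i) * n + (j))

  for (int i = n - 1; i >= 0; --i) {
    for (int j = i; j < n; ++j) {
      // V
      if (cx.can_pair(i, j)) {
        double best = cx.hpE(j - i - 1);
        int kmax = std::min(j - 2, i + 1 + cx.max_int);
        for (int k = i + 1; k <= kmax; ++k) {
          int l1 = k - i - 1;
          const std::vector<int> &lst = vl[k];
          if (lst.empty()) continue;
          int lmin = std::max(k + 1, j - 1 - (cx.max_int - l1));
          std::vector<int>::const_iterator it =
              std::lower_bound(lst.begin(), lst.end(), lmin);
          for (; it != lst.end() && *it <= j - 1; ++it) {
            double cand = V[IX(k, *it)] + cx.two_loop_E(i, j, k, *it);
            if (cand < best) best = cand;
          }
        }
        if (j - i >= 2 && M2[IX(i + 1, j - 1)] < INF_E / 2) {
          double cand = cx.ml_a + M2[IX(i + 1, j - 1)];
          if (cand < best) best = cand;
        }
        if (best < INF_E / 2) {
          if (cx.forced[i] == j) best += BONUS;
          V[IX(i, j)] = best;
          vl[i].push_back(j);
        }
      }
      // M / M2
      if (j > i) {
        double m = (M[IX(i + 1, j)] < INF_E / 2) ? M[IX(i + 1, j)] + cx.ml_c : INF_E;
        double m2 = (M2[IX(i + 1, j)] < INF_E / 2) ? M2[IX(i + 1, j)] + cx.ml_c : INF_E;
        const std::vector<int> &row = vl[i];
        for (size_t t = 0; t < row.size(); ++t) {
          int k = row[t];
          if (k > j) break;
          double v = V[IX(i, k)];
          double tail;
          if (k == j) tail = 0.0;
          else {
            tail = cx.ml_c * (j - k);
            if (M[IX(k + 1, j)] < tail) tail = M[IX(k + 1, j)];
          }
          double cand = v + cx.ml_b + tail;
          if (cand < m) m = cand;
          if (k < j && M[IX(k + 1, j)] < INF_E / 2) {
            double cand2 = v + cx.ml_b + M[IX(k + 1, j)];
            if (cand2 < m2) m2 = cand2;
          }
        }
        M[IX(i, j)] = m;
        M2[IX(i, j)] = m2;
      }
    }
  }

  // exterior
  std::vector<double> W(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    double w = W[j];  // j unpaired
    for (int k = 0; k <= j; ++k) {
      double v = V[IX(k, j)];
      if (v >= INF_E / 2) continue;
      double cand = (k == 0 ? 0.0 : W[k]) + v;
      if (cand < w) w = cand;
    }
    W[j + 1] = w;
  }
  double etot = W[n];

  std::vector<std::pair<int,int> > pairs;
  if (traceback && etot < INF_E / 2) {
    // stack of (type, i, j): 0 = W segment [0..j], 1 = V, 2 = M, 3 = M2
    std::vector<std::array<int,3> > st;
    st.push_back(std::array<int,3>{{0, 0, n - 1}});
    while (!st.empty()) {
      std::array<int,3> it = st.back(); st.pop_back();
      int ty = it[0], i = it[1], j = it[2];
      if (ty == 0) {  // exterior [0..j]
        while (j >= 0) {
          double w = W[j + 1];
          bool found = false;
          for (int k = 0; k <= j && !found; ++k) {  // prefer 5'-most pair on ties
            double v = V[IX(k, j)];
            if (v >= INF_E / 2) continue;
            if (std::fabs((k == 0 ? 0.0 : W[k]) + v - w) < EPS) {
              st.push_back(std::array<int,3>{{1, k, j}});
              j = k - 1;
              found = true;
            }
          }
          if (!found) j = j - 1;  // j unpaired
        }
      } else if (ty == 1) {  // V(i,j)
        pairs.push_back(std::make_pair(i, j));
        double target = V[IX(i, j)] - (cx.forced[i] == j ? BONUS : 0.0);
        bool done = false;
        for (int k = i + 1; k <= j - 2 && !done; ++k) {
          int l1 = k - i - 1;
          if (l1 > cx.max_int) break;
          for (int l = j - 1; l > k; --l) {
            int l2 = j - l - 1;
            if (l1 + l2 > cx.max_int) break;
            double v = V[IX(k, l)];
            if (v >= INF_E / 2) continue;
            if (std::fabs(v + cx.two_loop_E(i, j, k, l) - target) < EPS) {
              st.push_back(std::array<int,3>{{1, k, l}});
              done = true; break;
            }
          }
        }
        if (!done && std::fabs(cx.hpE(j - i - 1) - target) < EPS) done = true;
        if (!done && j - i >= 2 &&
            std::fabs(cx.ml_a + M2[IX(i + 1, j - 1)] - target) < EPS) {
          st.push_back(std::array<int,3>{{3, i + 1, j - 1}});
          done = true;
        }
        if (!done) stop("internal error: MFE traceback failed at V");
      } else {  // M (ty==2) or M2 (ty==3)
        const std::vector<double> &A = (ty == 2) ? M : M2;
        while (true) {
          double target = A[IX(i, j)];
          if (j > i && A[IX(i + 1, j)] < INF_E / 2 &&
              std::fabs(A[IX(i + 1, j)] + cx.ml_c - target) < EPS) {
            ++i; continue;
          }
          bool done = false;
          for (int k = i + cx.min_hp + 1; k <= j && !done; ++k) {
            double v = V[IX(i, k)];
            if (v >= INF_E / 2) continue;
            if (ty == 3) {
              if (k < j && M[IX(k + 1, j)] < INF_E / 2 &&
                  std::fabs(v + cx.ml_b + M[IX(k + 1, j)] - target) < EPS) {
                st.push_back(std::array<int,3>{{1, i, k}});
                st.push_back(std::array<int,3>{{2, k + 1, j}});
                done = true;
              }
            } else {
              if (k == j && std::fabs(v + cx.ml_b - target) < EPS) {
                st.push_back(std::array<int,3>{{1, i, k}});
                done = true;
              } else if (k < j) {
                if (std::fabs(v + cx.ml_b + cx.ml_c * (j - k) - target) < EPS) {
                  st.push_back(std::array<int,3>{{1, i, k}});
                  done = true;
                } else if (M[IX(k + 1, j)] < INF_E / 2 &&
                           std::fabs(v + cx.ml_b + M[IX(k + 1, j)] - target) < EPS) {
                  st.push_back(std::array<int,3>{{1, i, k}});
                  st.push_back(std::array<int,3>{{2, k + 1, j}});
                  done = true;
                }
              }
            }
          }
          if (!done) stop("internal error: MFE traceback failed at M");
          break;
        }
      }
    }
  }

  // report: strip forced-pair bonuses
  double e_rep = etot;
  int nforced_in = 0;
  for (size_t t = 0; t < pairs.size(); ++t)
    if (cx.forced[pairs[t].first] == pairs[t].second) ++nforced_in;
  if (traceback) e_rep -= BONUS * nforced_in;
  else e_rep -= BONUS * (double)cx.fpairs.size();  // assume feasible when not tracing

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t t = 0; t < pairs.size(); ++t) {
    pm(t, 0) = pairs[t].first + 1;
    pm(t, 1) = pairs[t].second + 1;
  }
  bool feasible = !traceback || nforced_in == (int)cx.fpairs.size();
  return List::create(_["energy"] = e_rep, _["pairs"] = pm,
                      _["forced_ok"] = feasible);
}

// ------------------------------------------------- partition function ------

// [[Rcpp::export]]
List c_partfn(IntegerVector seqi, int maxspan, IntegerVector forced,
              NumericMatrix stack, NumericVector hp, NumericVector bu,
              NumericVector il, double ml_a, double ml_b, double ml_c,
              int min_hp, int max_int, double rt) {
  FoldCtx cx = make_ctx(seqi, maxspan, forced, stack, hp, bu, il,
                        ml_a, ml_b, ml_c, min_hp, max_int);
  const int n = cx.n;
  const double beta = 1.0 / rt;
  const double wb = std::exp(-beta * ml_b), wc = std::exp(-beta * ml_c),
               wa = std::exp(-beta * ml_a);
  std::vector<double> QV((size_t)n * n, 0.0), QM((size_t)n * n, 0.0),
      QM2((size_t)n * n, 0.0);
  std::vector<std::vector<int> > ql(n);  // per row i: sorted j with QV > 0
  std::vector<double> wcpow(n + 1);
  wcpow[0] = 1.0;
  for (int t = 1; t <= n; ++t) wcpow[t] = wcpow[t - 1] * wc;

  for (int i = n - 1; i >= 0; --i) {
    for (int j = i; j < n; ++j) {
      if (cx.can_pair(i, j)) {
        double q = 0.0;
        double eh = cx.hpE(j - i - 1);
        if (eh < INF_E / 2) q += std::exp(-beta * eh);
        int kmax = std::min(j - 2, i + 1 + cx.max_int);
        for (int k = i + 1; k <= kmax; ++k) {
          int l1 = k - i - 1;
          const std::vector<int> &lst = ql[k];
          if (lst.empty()) continue;
          int lmin = std::max(k + 1, j - 1 - (cx.max_int - l1));
          std::vector<int>::const_iterator it =
              std::lower_bound(lst.begin(), lst.end(), lmin);
          for (; it != lst.end() && *it <= j - 1; ++it) {
            double e2 = cx.two_loop_E(i, j, k, *it);
            if (e2 < INF_E / 2) q += QV[IX(k, *it)] * std::exp(-beta * e2);
          }
        }
        if (j - i >= 2) q += wa * QM2[IX(i + 1, j - 1)];
        if (q > 0.0) {
          QV[IX(i, j)] = q;
          ql[i].push_back(j);
        }
      }
      if (j > i) {
        double qm = QM[IX(i + 1, j)] * wc;
        double qm2 = QM2[IX(i + 1, j)] * wc;
        const std::vector<int> &row = ql[i];
        for (size_t t = 0; t < row.size(); ++t) {
          int k = row[t];
          if (k > j) break;
          double qv = QV[IX(i, k)];
          double tailq = (k == j) ? 1.0 : (wcpow[j - k] + QM[IX(k + 1, j)]);
          qm += qv * wb * tailq;
          if (k < j) qm2 += qv * wb * QM[IX(k + 1, j)];
        }
        QM[IX(i, j)] = qm;
        QM2[IX(i, j)] = qm2;
      }
    }
  }

  // exterior segments QX(i,j); empty segment = 1
  std::vector<double> QX((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double q = (j == i) ? 1.0 : QX[IX(i, j - 1)];  // j unpaired
      for (int k = i; k <= j; ++k) {
        double qv = QV[IX(k, j)];
        if (qv <= 0.0) continue;
        q += (k == i ? 1.0 : QX[IX(i, k - 1)]) * qv;
      }
      QX[IX(i, j)] = q;
    }
  }
  double Z = QX[IX(0, n - 1)];
  if (!(Z > 0.0)) stop("partition function underflow");

  // outside
  std::vector<double> QO((size_t)n * n, 0.0);
  NumericMatrix P(n, n);
  for (int span = n - 1; span >= cx.min_hp + 1; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (QV[IX(i, j)] <= 0.0) continue;
      double qo = (i == 0 ? 1.0 : QX[IX(0, i - 1)]) *
                  (j == n - 1 ? 1.0 : QX[IX(j + 1, n - 1)]);
      // enclosed in a two-loop closed by (p,q)
      for (int p = i - 1; p >= 0; --p) {
        int l1 = i - p - 1;
        if (l1 > cx.max_int) break;
        for (int q = j + 1; q < n; ++q) {
          int l2 = q - j - 1;
          if (l1 + l2 > cx.max_int) break;
          double qop = QO[IX(p, q)];
          if (qop <= 0.0) continue;
          double e2 = cx.two_loop_E(p, q, i, j);
          if (e2 < INF_E / 2) qo += qop * std::exp(-beta * e2);
        }
      }
      // branch of a multiloop closed by (p,q): >=1 further branch beside us
      for (int p = 0; p < i; ++p) {
        const std::vector<int> &lst = ql[p];
        std::vector<int>::const_iterator it =
            std::lower_bound(lst.begin(), lst.end(), j + 2);
        for (; it != lst.end(); ++it) {
          int q = *it;
          double qop = QO[IX(p, q)];
          if (qop <= 0.0) continue;
          int Ll = i - p - 1, Lr = q - j - 1;
          double uL = wcpow[Ll], uR = wcpow[Lr];
          double mxL = uL + (Ll > 0 ? QM[IX(p + 1, i - 1)] : 0.0);
          double mxR = uR + (Lr > 0 ? QM[IX(j + 1, q - 1)] : 0.0);
          double fill = mxL * mxR - uL * uR;
          if (fill <= 0.0) continue;
          qo += qop * wa * wb * fill;
        }
      }
      QO[IX(i, j)] = qo;
      P(i, j) = QV[IX(i, j)] * qo / Z;
    }
  }

  return List::create(_["bpp"] = P, _["lnZ"] = std::log(Z));
}

// ---------------------------------------------------------- duplex ---------

// [[Rcpp::export]]
double c_duplex(IntegerVector s1i, IntegerVector s2i, NumericMatrix stack,
                NumericVector bu, NumericVector il, int max_gap) {
  const int n1 = s1i.size(), n2 = s2i.size();
  std::vector<int> s1(s1i.begin(), s1i.end()), s2(s2i.begin(), s2i.end());
  std::vector<double> D((size_t)n1 * n2, INF_E);
  double best = 0.0;  // empty duplex
  const double *st = stack.begin();
  for (int i = 0; i < n1; ++i) {
    for (int k = n2 - 1; k >= 0; --k) {
      int pt = pair_type(s1[i], s2[k]);
      if (pt == 0) continue;
      double d = 0.0;  // duplex starting at this pair
      for (int ip = i - 1; ip >= 0 && i - ip - 1 <= max_gap; --ip) {
        for (int kp = k + 1; kp < n2 && kp - k - 1 <= max_gap; ++kp) {
          double dp = D[(size_t)ip * n2 + kp];
          if (dp >= INF_E / 2) continue;
          int l1 = i - ip - 1, l2 = kp - k - 1;
          double e;
          if (l1 == 0 && l2 == 0) {
            int ptp = pair_type(s1[ip], s2[kp]);
            e = st[(pt - 1) * 6 + (ptp - 1)];
          } else if (l1 == 0 || l2 == 0) {
            e = (l1 + l2 <= (int)bu.size()) ? bu[l1 + l2 - 1] : INF_E;
          } else {
            e = (l1 + l2 <= (int)il.size()) ? il[l1 + l2 - 1] : INF_E;
          }
          if (e >= INF_E / 2) continue;
          if (dp + e < d) d = dp + e;
        }
      }
      D[(size_t)i * n2 + k] = d;
      if (d < best) best = d;
    }
  }
  return best;
}
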