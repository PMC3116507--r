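#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment, affine gaps.
// Gap of length L costs gap_open + (L-1) * gap_extend.
// Sequences arrive as 0-based integer codes into the scoring matrix.
// ---------------------------------------------------------------------------

static int sw_score_one(const int* a, int m, const int* b, int n,
                        const int* S, int A, int go, int ge,
                        std::vector<int>& H, std::vector<int>& E) {
  std::fill(H.begin(), H.begin() + n + 1, 0);
  std::fill(E.begin(), E.begin() + n + 1, 0);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int* Srow = S + (size_t)A * a[i - 1];
    int Hdiag = 0, F = 0, Hprev = 0;
    int* Hp = H.data();
    int* Ep = E.data();
    for (int j = 1; j <= n; ++j) {
      int h = Hdiag + Srow[b[j - 1]];
      int e = std::max(Ep[j] - ge, Hp[j] - go);
      Ep[j] = e;
      F = std::max(F - ge, Hprev - go);
      Hdiag = Hp[j];
      int v = h > e ? h : e;
      if (F > v) v = F;
      if (v < 0) v = 0;
      Hp[j] = v;
      Hprev = v;
      if (v > best) best = v;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_batch")]]
IntegerMatrix sw_score_batch(List queries, List subjects, IntegerMatrix Smat,
                             int gap_open, int gap_extend) {
  const int A = Smat.nrow();
  std::vector<int> S((size_t)A * A);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) S[(size_t)A * i + j] = Smat(i, j);
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int>> qs(nq), ss(ns);
  int maxn = 1;
  for (int i = 0; i < nq; ++i) qs[i] = as<std::vector<int>>(queries[i]);
  for (int j = 0; j < ns; ++j) {
    ss[j] = as<std::vector<int>>(subjects[j]);
    maxn = std::max(maxn, (int)ss[j].size());
  }
  IntegerMatrix out(nq, ns);
  std::vector<int> H(maxn + 1), E(maxn + 1);
  for (int j = 0; j < ns; ++j) {
    const std::vector<int>& b = ss[j];
    for (int i = 0; i < nq; ++i) {
      out(i, j) = sw_score_one(qs[i].data(), qs[i].size(), b.data(), b.size(),
                               S.data(), A, gap_open, gap_extend, H, E);
    }
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full DP with traceback for a single pair: returns score, 1-based inclusive
// spans on both sequences, identical positions and alignment length.
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback(IntegerVector a, IntegerVector b, IntegerMatrix Smat,
                  int gap_open, int gap_extend) {
  const int A = Smat.nrow();
  const int m = a.size(), n = b.size();
  // state: 0 = H (diag), 1 = E (gap in a / move in b), 2 = F (gap in b)
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), INT_MIN / 4),
      F((m + 1) * (n + 1), INT_MIN / 4);
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0),
      tbE((m + 1) * (n + 1), 0), tbF((m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t c = (size_t)i * (n + 1) + j;
      size_t up = c - (n + 1), left = c - 1, diag = up - 1;
      int eo = H[up] - gap_open, ee = E[up] - gap_extend;
      E[c] = std::max(eo, ee);
      tbE[c] = (ee > eo) ? 1 : 0;  // 1 = extend from E
      int fo = H[left] - gap_open, fe = F[left] - gap_extend;
      F[c] = std::max(fo, fe);
      tbF[c] = (fe > fo) ? 1 : 0;
      int s = Smat(a[i - 1], b[j - 1]);
      int hd = H[diag] + s;
      int v = hd;
      unsigned char t = 0;
      if (E[c] > v) { v = E[c]; t = 1; }
      if (F[c] > v) { v = F[c]; t = 2; }
      if (v <= 0) { v = 0; t = 3; }  // stop
      H[c] = v;
      tbH[c] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj), state H
  int i = bi, j = bj, state = 0;
  int aend = bi, bend = bj, astart = bi, bstart = bj;
  int nid = 0, alen = 0;
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[c];
      if (t == 3 || H[c] == 0) break;
      if (t == 0) {
        ++alen;
        if (a[i - 1] == b[j - 1]) ++nid;
        astart = i; bstart = j;
        --i; --j;
      } else {
        state = t;
      }
    } else if (state == 1) {  // E: vertical move, consumes a[i-1], gap in b
      ++alen;
      astart = i;
      state = tbE[c] == 1 ? 1 : 0;
      --i;
    } else {  // F: horizontal move, consumes b[j-1], gap in a
      ++alen;
      bstart = j;
      state = tbF[c] == 1 ? 2 : 0;
      --j;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = astart,
                      _["a_end"] = aend, _["b_start"] = bstart,
                      _["b_end"] = bend, _["n_ident"] = nid,
                      _["align_length"] = alen);
}

// ---------------------------------------------------------------------------
// Profile-profile global alignment with affine gaps (progressive aligner).
// Profiles are residue-count matrices (A rows x L columns); column score is
// the average pairwise substitution score over all row pairs (gap rows score
// zero). Returns the move path, 0 = both, 1 = column from A only (gap in B),
// 2 = column from B only (gap in A), in alignment order.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".profile_nw")]]
IntegerVector profile_nw(NumericMatrix cntA, NumericMatrix cntB, double nA,
                         double nB, NumericMatrix Smat, double gap_open,
                         double gap_extend) {
  const int A = Smat.nrow();
  const int la = cntA.ncol(), lb = cntB.ncol();
  const double NEG = -1e30;
  // precompute column scores
  NumericMatrix cs(la, lb);
  std::vector<double> tmp(A);
  for (int i = 0; i < la; ++i) {
    for (int r = 0; r < A; ++r) {
      double v = 0;
      for (int q = 0; q < A; ++q) v += cntA(q, i) * Smat(q, r);
      tmp[r] = v;
    }
    for (int j = 0; j < lb; ++j) {
      double v = 0;
      for (int r = 0; r < A; ++r) v += tmp[r] * cntB(r, j);
      cs(i, j) = v / (nA * nB);
    }
  }
  std::vector<double> M((la + 1) * (lb + 1), NEG), X(M), Y(M);
  std::vector<unsigned char> tM(M.size(), 0), tX(M.size(), 0), tY(M.size(), 0);
  M[0] = 0;
  for (int i = 1; i <= la; ++i) {  // X = gap in B (consume A)
    size_t c = (size_t)i * (lb + 1);
    X[c] = -gap_open - (i - 1) * gap_extend;
    tX[c] = 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[j] = -gap_open - (j - 1) * gap_extend;
    tY[j] = 1;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      size_t c = (size_t)i * (lb + 1) + j;
      size_t up = c - (lb + 1), left = c - 1, diag = up - 1;
      double mo = std::max(M[up] - gap_open, Y[up] - gap_open);
      double me = X[up] - gap_extend;
      X[c] = std::max(mo, me);
      tX[c] = me > mo ? 1 : 0;
      double yo = std::max(M[left] - gap_open, X[left] - gap_open);
      double ye = Y[left] - gap_extend;
      Y[c] = std::max(yo, ye);
      tY[c] = ye > yo ? 1 : 0;
      double s = cs(i - 1, j - 1);
      double dM = M[diag], dX = X[diag], dY = Y[diag];
      double v = dM;
      unsigned char t = 0;
      if (dX > v) { v = dX; t = 1; }
      if (dY > v) { v = dY; t = 2; }
      M[c] = v + s;
      tM[c] = t;
    }
  }
  // traceback from best of three at (la, lb)
  size_t c = (size_t)la * (lb + 1) + lb;
  int state = 0;
  double v = M[c];
  if (X[c] > v) { v = X[c]; state = 1; }
  if (Y[c] > v) { v = Y[c]; state = 2; }
  std::vector<int> path;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    size_t cc = (size_t)i * (lb + 1) + j;
    if (state == 0) {
      path.push_back(0);
      state = tM[cc];
      --i; --j;
    } else if (state == 1) {
      path.push_back(1);
      int ext = tX[cc];
      --i;
      if (!ext) {
        size_t nc = (size_t)i * (lb + 1) + j;
        state = (M[nc] >= Y[nc]) ? 0 : 2;
      }
    } else {
      path.push_back(2);
      int ext = tY[cc];
      --j;
      if (!ext) {
        size_t nc = (size_t)i * (lb + 1) + j;
        state = (M[nc] >= X[nc]) ? 0 : 1;
      }
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// ---------------------------------------------------------------------------
// Pairwise maximum-likelihood distances under a reversible amino-acid model
// with discrete-gamma rate categories and an invariant-site class.
// The R side precomputes log site probabilities log[p_inv pi_a 1(a=b) +
// (1-p_inv) pi_a Pmix_ab(t)] on a dense log-spaced grid of t; each pair's
// log-likelihood is a dot product of its residue-pair counts with a grid
// column, and the optimum is refined by parabolic interpolation of the
// three best grid points in log t.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mldist_grid")]]
NumericMatrix mldist_grid(IntegerMatrix aln, NumericVector weights,
                          NumericMatrix logP, NumericVector log_t,
                          double t_max) {
  const int ntax = aln.nrow(), nsites = aln.ncol();
  const int A = 20, G = logP.ncol();
  NumericMatrix D(ntax, ntax);
  std::vector<double> C((size_t)A * A);
  std::vector<int> nz;
  nz.reserve(A * A);
  std::vector<double> s(G);
  for (int x = 0; x < ntax; ++x) {
    for (int y = x + 1; y < ntax; ++y) {
      std::fill(C.begin(), C.end(), 0.0);
      double ndiff = 0, ntot = 0;
      for (int sI = 0; sI < nsites; ++sI) {
        int a = aln(x, sI), b = aln(y, sI);
        if (a >= 0 && b >= 0 && weights[sI] > 0) {
          C[(size_t)a * A + b] += weights[sI];
          ntot += weights[sI];
          if (a != b) ndiff += weights[sI];
        }
      }
      double d;
      if (ntot == 0) {
        d = t_max;                       // no shared sites
      } else if (ndiff == 0) {
        d = 0.0;
      } else {
        nz.clear();
        for (int c = 0; c < A * A; ++c)
          if (C[c] > 0) nz.push_back(c);
        int best = 0;
        double fbest = -1e300;
        for (int g = 0; g < G; ++g) {
          double v = 0;
          for (size_t q = 0; q < nz.size(); ++q)
            v += C[nz[q]] * logP(nz[q], g);
          s[g] = v;
          if (v > fbest) { fbest = v; best = g; }
        }
        if (best == 0 || best == G - 1) {
          d = std::exp(log_t[best]);
        } else {
          // parabola through (log_t, s) at best-1, best, best+1
          double x0 = log_t[best - 1], x1 = log_t[best], x2 = log_t[best + 1];
          double f0 = s[best - 1], f1 = s[best], f2 = s[best + 1];
          double denom = (x1 - x0) * (f1 - f2) - (x1 - x2) * (f1 - f0);
          double lt = x1;
          if (std::fabs(denom) > 1e-300) {
            lt = x1 - 0.5 * ((x1 - x0) * (x1 - x0) * (f1 - f2) -
                             (x1 - x2) * (x1 - x2) * (f1 - f0)) / denom;
            if (lt < x0) lt = x0;
            if (lt > x2) lt = x2;
          }
          d = std::exp(lt);
        }
        if (d > t_max) d = t_max;
      }
      D(x, y) = d;
      D(y, x) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

static void pmat_mix(const double* V, const double* lam, const double* Vinv,
                     int A, const double* rates, int ncat, double t,
                     std::vector<double>& P, std::vector<double>& scratch) {
  std::fill(P.begin(), P.end(), 0.0);
  for (int k = 0; k < ncat; ++k) {
    for (int s = 0; s < A; ++s) scratch[s] = std::exp(lam[s] * rates[k] * t);
    for (int i = 0; i < A; ++i) {
      for (int j = 0; j < A; ++j) {
        double v = 0;
        for (int s = 0; s < A; ++s)
          v += V[(size_t)i * A + s] * scratch[s] * Vinv[(size_t)s * A + j];
        P[(size_t)i * A + j] += v / ncat;
      }
    }
  }
  for (size_t z = 0; z < P.size(); ++z)
    if (P[z] < 1e-300) P[z] = 1e-300;
}

static double pair_ll(const std::vector<double>& C, const double* pi,
                      const std::vector<double>& P, int A, double p_inv) {
  double ll = 0;
  for (int i = 0; i < A; ++i) {
    for (int j = 0; j < A; ++j) {
      double c = C[(size_t)i * A + j];
      if (c == 0) continue;
      double pr = (1.0 - p_inv) * pi[i] * P[(size_t)i * A + j];
      if (i == j) pr += p_inv * pi[i];
      ll += c * std::log(pr);
    }
  }
  return ll;
}

static double pair_mldist(const std::vector<double>& C, const double* pi,
                          const double* V, const double* lam,
                          const double* Vinv, int A, const double* rates,
                          int ncat, double p_inv, double t_max,
                          std::vector<double>& P, std::vector<double>& scr) {
  double ndiff = 0, ntot = 0;
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) {
      ntot += C[(size_t)i * A + j];
      if (i != j) ndiff += C[(size_t)i * A + j];
    }
  if (ntot == 0) return -1.0;  // no shared sites: caller assigns max
  if (ndiff == 0) return 0.0;
  const double gr = 0.6180339887498949;
  double a = 1e-8, b = t_max;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  pmat_mix(V, lam, Vinv, A, rates, ncat, x1, P, scr);
  double f1 = pair_ll(C, pi, P, A, p_inv);
  pmat_mix(V, lam, Vinv, A, rates, ncat, x2, P, scr);
  double f2 = pair_ll(C, pi, P, A, p_inv);
  for (int it = 0; it < 80 && (b - a) > 1e-7; ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      pmat_mix(V, lam, Vinv, A, rates, ncat, x2, P, scr);
      f2 = pair_ll(C, pi, P, A, p_inv);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      pmat_mix(V, lam, Vinv, A, rates, ncat, x1, P, scr);
      f1 = pair_ll(C, pi, P, A, p_inv);
    }
  }
  return 0.5 * (a + b);
}

// aln: ntaxa x nsites integer matrix, codes 0..A-1, negative = gap/missing.
// weights: per-site multiplicities (bootstrap); length nsites.
// [[Rcpp::export(name = ".mldist_matrix")]]
NumericMatrix mldist_matrix(IntegerMatrix aln, NumericVector weights,
                            NumericVector pi, NumericMatrix V,
                            NumericVector lam, NumericMatrix Vinv,
                            NumericVector rates, double p_inv, double t_max) {
  const int ntax = aln.nrow(), nsites = aln.ncol(), A = pi.size();
  const int ncat = rates.size();
  std::vector<double> Vf((size_t)A * A), Vif((size_t)A * A);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) {
      Vf[(size_t)i * A + j] = V(i, j);
      Vif[(size_t)i * A + j] = Vinv(i, j);
    }
  NumericMatrix D(ntax, ntax);
  std::vector<double> C((size_t)A * A), P((size_t)A * A), scr(A);
  for (int x = 0; x < ntax; ++x) {
    for (int y = x + 1; y < ntax; ++y) {
      std::fill(C.begin(), C.end(), 0.0);
      for (int s = 0; s < nsites; ++s) {
        int a = aln(x, s), b = aln(y, s);
        if (a >= 0 && b >= 0 && weights[s] > 0)
          C[(size_t)a * A + b] += weights[s];
      }
      double d = pair_mldist(C, REAL(pi), Vf.data(), REAL(lam), Vif.data(), A,
                             REAL(rates), ncat, p_inv, t_max, P, scr);
      if (d < 0) d = t_max;
      D(x, y) = d;
      D(y, x) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}
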