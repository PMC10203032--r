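// Recursions for top-order zonal and invariant polynomial coefficients
// d_k(A), d_{i,j}(A1,A2), d_{k,1}(A,B), d_{i,j,1}(A1,A2,B), d_{i,j,k}(A1,A2,A3),
// defined as the coefficients of the multivariate expansion of
// det(I - sum_l t_l A_l)^{-1/2}.
//
// All recursions carry a per-layer base-2 scale exponent so that mantissas stay
// inside double range at arbitrary order (true value = mantissa * 2^exponent).
// Series drivers combine the Pochhammer/Gamma weights with the coefficient
// mantissas in log space per cell, so weighted sums never form Inf * 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double THR_HI = 1e205;
static const double THR_LO = 1e-205;
static const int SHIFT = 680; // 2^680 ~ 5.0e204

static inline double pow2i(int e) { return std::ldexp(1.0, e); }

// bring maxabs into [THR_LO, THR_HI]; returns exponent increment applied
static int scale_step(double maxabs) {
  int de = 0;
  if (maxabs > 0.0) {
    while (maxabs > THR_HI) { maxabs *= pow2i(-SHIFT); de += SHIFT; }
    while (maxabs < THR_LO) { maxabs *= pow2i(SHIFT); de -= SHIFT; }
  }
  return de;
}

// log Pochhammer (a)_k for a > 0
static inline double lpoch(double a, double k) {
  return std::lgamma(a + k) - std::lgamma(a);
}

// ---------------------------------------------------------------------------
// single-index d_k(A) on eigenvalues, with scaled cumulative sum of d_k
// [[Rcpp::export]]
List cpp_d1_vec(const arma::vec& lam, int M) {
  int p = lam.n_elem;
  NumericVector mant(M + 1);
  IntegerVector ex(M + 1);
  NumericVector csm(M + 1);
  IntegerVector cse(M + 1);
  arma::vec g(p, arma::fill::zeros);
  double d = 1.0;
  long lex = 0;
  double cs = 1.0; long cex = 0;
  mant[0] = 1.0; ex[0] = 0; csm[0] = 1.0; cse[0] = 0;
  for (int k = 1; k <= M; ++k) {
    g = lam % (g + d);
    d = arma::accu(g) / (2.0 * k);
    double m = std::max(arma::abs(g).max(), std::fabs(d));
    int de = scale_step(m);
    if (de != 0) { g *= pow2i(-de); d *= pow2i(-de); lex += de; }
    mant[k] = d; ex[k] = (int) lex;
    // cumulative sum: cs*2^cex + d*2^lex
    if (cex >= lex) {
      cs += d * pow2i((int)(lex - cex));
    } else {
      cs = cs * pow2i((int)(cex - lex)) + d;
      cex = lex;
    }
    int dc = scale_step(std::fabs(cs));
    if (dc != 0) { cs *= pow2i(-dc); cex += dc; }
    csm[k] = cs; cse[k] = (int) cex;
  }
  return List::create(_["mant"] = mant, _["ex"] = ex,
                      _["csum_mant"] = csm, _["csum_ex"] = cse);
}

// single-index d_k(A) on a general symmetric matrix
// [[Rcpp::export]]
List cpp_d1_mat(const arma::mat& A, int M) {
  int p = A.n_rows;
  NumericVector mant(M + 1);
  IntegerVector ex(M + 1);
  arma::mat g(p, p, arma::fill::zeros);
  double d = 1.0;
  long lex = 0;
  mant[0] = 1.0; ex[0] = 0;
  for (int k = 1; k <= M; ++k) {
    g = A * (g + d * arma::eye(p, p));
    d = arma::trace(g) / (2.0 * k);
    double m = std::max(arma::abs(g).max(), std::fabs(d));
    int de = scale_step(m);
    if (de != 0) { g *= pow2i(-de); d *= pow2i(-de); lex += de; }
    mant[k] = d; ex[k] = (int) lex;
  }
  return List::create(_["mant"] = mant, _["ex"] = ex);
}

// ---------------------------------------------------------------------------
// d_{k,1}(A,B): two-index recursion with second index capped at 1, on the
// eigenvalues of A and diag(Q'BQ) in A's eigenbasis (exact for symmetric B:
// A diagonal keeps the diagonal evolution closed under the recursion).
// Also returns the scaled cumulative sum of d_{k,1} (for the f-bar bound).
// [[Rcpp::export]]
List cpp_d2h_vec(const arma::vec& aeig, const arma::vec& bdiag, int M) {
  int p = aeig.n_elem;
  NumericVector mant(M + 1);
  IntegerVector ex(M + 1);
  NumericVector csm(M + 1);
  IntegerVector cse(M + 1);
  arma::vec g0(p, arma::fill::zeros), g1 = bdiag;
  double d0 = 1.0, d1 = arma::accu(bdiag) / 2.0;
  long lex = 0;
  double cs = d1; long cex = 0;
  mant[0] = d1; ex[0] = 0; csm[0] = cs; cse[0] = 0;
  for (int k = 1; k <= M; ++k) {
    g0 = aeig % (g0 + d0);
    d0 = arma::accu(g0) / (2.0 * k);
    g1 = aeig % (g1 + d1) + bdiag % (g0 + d0);
    d1 = arma::accu(g1) / (2.0 * (k + 1));
    double m = std::max(std::max(arma::abs(g0).max(), arma::abs(g1).max()),
                        std::max(std::fabs(d0), std::fabs(d1)));
    int de = scale_step(m);
    if (de != 0) {
      double f = pow2i(-de);
      g0 *= f; g1 *= f; d0 *= f; d1 *= f; lex += de;
    }
    mant[k] = d1; ex[k] = (int) lex;
    if (cex >= lex) cs += d1 * pow2i((int)(lex - cex));
    else { cs = cs * pow2i((int)(cex - lex)) + d1; cex = lex; }
    int dc = scale_step(std::fabs(cs));
    if (dc != 0) { cs *= pow2i(-dc); cex += dc; }
    csm[k] = cs; cse[k] = (int) cex;
  }
  return List::create(_["mant"] = mant, _["ex"] = ex,
                      _["csum_mant"] = csm, _["csum_ex"] = cse);
}

// ---------------------------------------------------------------------------
// full triangular table of d_{i,j}(A1,A2), i + j <= M, commuting (eigenvalue)
// arguments; flattened by total order s then i. For oracle tests and the
// central moment engine.
// [[Rcpp::export]]
List cpp_d2_vec_table(const arma::vec& la1, const arma::vec& la2, int M) {
  int p = la1.n_elem;
  int ncell = (M + 1) * (M + 2) / 2;
  NumericVector mant(ncell);
  IntegerVector ex(ncell);
  arma::mat gprev(p, 1, arma::fill::zeros);
  arma::rowvec dprev(1); dprev[0] = 1.0;
  long lex = 0;
  mant[0] = 1.0; ex[0] = 0;
  int pos = 1;
  for (int s = 1; s <= M; ++s) {
    arma::mat gcur(p, s + 1, arma::fill::zeros);
    arma::rowvec dcur(s + 1);
    for (int i = 0; i <= s; ++i) {
      arma::vec g(p, arma::fill::zeros);
      if (i >= 1) g += la1 % (gprev.col(i - 1) + dprev[i - 1]);
      if (s - i >= 1) g += la2 % (gprev.col(i) + dprev[i]);
      gcur.col(i) = g;
      dcur[i] = arma::accu(g) / (2.0 * s);
    }
    double m = std::max(arma::abs(gcur).max(), arma::abs(dcur).max());
    int de = scale_step(m);
    if (de != 0) { double f = pow2i(-de); gcur *= f; dcur *= f; lex += de; }
    for (int i = 0; i <= s; ++i) { mant[pos] = dcur[i]; ex[pos] = (int) lex; ++pos; }
    gprev = gcur; dprev = dcur;
  }
  return List::create(_["mant"] = mant, _["ex"] = ex);
}

// same, general (possibly non-commuting) symmetric matrix arguments
// [[Rcpp::export]]
List cpp_d2_mat_table(const arma::mat& A1, const arma::mat& A2, int M) {
  int p = A1.n_rows;
  int ncell = (M + 1) * (M + 2) / 2;
  NumericVector mant(ncell);
  IntegerVector ex(ncell);
  arma::mat I = arma::eye(p, p);
  std::vector<arma::mat> gprev(1, arma::mat(p, p, arma::fill::zeros));
  std::vector<double> dprev(1, 1.0);
  long lex = 0;
  mant[0] = 1.0; ex[0] = 0;
  int pos = 1;
  for (int s = 1; s <= M; ++s) {
    std::vector<arma::mat> gcur(s + 1);
    std::vector<double> dcur(s + 1);
    double m = 0.0;
    for (int i = 0; i <= s; ++i) {
      arma::mat g(p, p, arma::fill::zeros);
      if (i >= 1) g += A1 * (gprev[i - 1] + dprev[i - 1] * I);
      if (s - i >= 1) g += A2 * (gprev[i] + dprev[i] * I);
      gcur[i] = g;
      dcur[i] = arma::trace(g) / (2.0 * s);
      m = std::max(m, std::max(arma::abs(g).max(), std::fabs(dcur[i])));
    }
    int de = scale_step(m);
    if (de != 0) {
      double f = pow2i(-de);
      for (int i = 0; i <= s; ++i) { gcur[i] *= f; dcur[i] *= f; }
      lex += de;
    }
    for (int i = 0; i <= s; ++i) { mant[pos] = dcur[i]; ex[pos] = (int) lex; ++pos; }
    gprev.swap(gcur); dprev.swap(dcur);
  }
  return List::create(_["mant"] = mant, _["ex"] = ex);
}

// ---------------------------------------------------------------------------
// streamed double series: sum over layers s = i+j of
//   w(i,j,s) * d_{i,j}(A1,A2),  w = (ai)_i (aj)_j / (as)_{s+sdelta}
// on commuting (eigenvalue) arguments, with stabilization stopping.
// Returns per-layer sums (weights included, overall prefactor excluded).
// [[Rcpp::export]]
List cpp_d2_vec_series(const arma::vec& la1, const arma::vec& la2,
                       double ai, double aj, double as, double sdelta,
                       int Mmax, double tol, int nstab) {
  int p = la1.n_elem;
  std::vector<double> lay;
  arma::mat gprev(p, 1, arma::fill::zeros);
  arma::rowvec dprev(1); dprev[0] = 1.0;
  long lex = 0;
  double lgai = std::lgamma(ai), lgaj = std::lgamma(aj), lgas = std::lgamma(as);
  double T0 = std::exp(lgas - std::lgamma(as + sdelta));
  lay.push_back(T0);
  double S = T0;
  int consec = 0;
  bool converged = false;
  int s;
  for (s = 1; s <= Mmax; ++s) {
    arma::mat gcur(p, s + 1, arma::fill::zeros);
    arma::rowvec dcur(s + 1);
    for (int i = 0; i <= s; ++i) {
      arma::vec g(p, arma::fill::zeros);
      if (i >= 1) g += la1 % (gprev.col(i - 1) + dprev[i - 1]);
      if (s - i >= 1) g += la2 % (gprev.col(i) + dprev[i]);
      gcur.col(i) = g;
      dcur[i] = arma::accu(g) / (2.0 * s);
    }
    double lwden = std::lgamma(as + s + sdelta) - lgas;
    double Ts = 0.0;
    for (int i = 0; i <= s; ++i) {
      double d = dcur[i];
      if (d == 0.0) continue;
      double lw = std::lgamma(ai + i) - lgai + std::lgamma(aj + (s - i)) - lgaj
        - lwden + std::log(std::fabs(d)) + lex * M_LN2;
      Ts += (d > 0 ? 1.0 : -1.0) * std::exp(lw);
    }
    lay.push_back(Ts);
    S += Ts;
    if (S != 0.0 && std::fabs(Ts) <= tol * std::fabs(S)) {
      if (++consec >= nstab) { converged = true; break; }
    } else consec = 0;
    double m = std::max(arma::abs(gcur).max(), arma::abs(dcur).max());
    int de = scale_step(m);
    if (de != 0) { double f = pow2i(-de); gcur *= f; dcur *= f; lex += de; }
    gprev = gcur; dprev = dcur;
  }
  return List::create(_["layer_terms"] = NumericVector(lay.begin(), lay.end()),
                      _["M_used"] = std::min(s, Mmax),
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// streamed sum over layers s = i+j of w(i,j,s) * d_{i,j,1}(A1,A2,B),
// commuting (eigenvalue) arguments; third index capped at 1.
// [[Rcpp::export]]
List cpp_d3l_vec_series(const arma::vec& la1, const arma::vec& la2,
                        const arma::vec& b,
                        double ai, double aj, double as, double sdelta,
                        int Mmax, double tol, int nstab) {
  int p = la1.n_elem;
  std::vector<double> lay;
  arma::mat g0p(p, 1, arma::fill::zeros), g1p(p, 1);
  arma::rowvec d0p(1), d1p(1);
  d0p[0] = 1.0;
  g1p.col(0) = b;
  d1p[0] = arma::accu(b) / 2.0;
  long lex = 0;
  double lgai = std::lgamma(ai), lgaj = std::lgamma(aj), lgas = std::lgamma(as);
  double T0 = 0.0;
  if (d1p[0] != 0.0)
    T0 = (d1p[0] > 0 ? 1.0 : -1.0) *
      std::exp(lgas - std::lgamma(as + sdelta) + std::log(std::fabs(d1p[0])));
  lay.push_back(T0);
  double S = T0;
  int consec = 0;
  bool converged = false;
  int s;
  for (s = 1; s <= Mmax; ++s) {
    arma::mat g0c(p, s + 1, arma::fill::zeros), g1c(p, s + 1, arma::fill::zeros);
    arma::rowvec d0c(s + 1), d1c(s + 1);
    for (int i = 0; i <= s; ++i) {
      arma::vec g0(p, arma::fill::zeros), g1(p, arma::fill::zeros);
      if (i >= 1) {
        g0 += la1 % (g0p.col(i - 1) + d0p[i - 1]);
        g1 += la1 % (g1p.col(i - 1) + d1p[i - 1]);
      }
      if (s - i >= 1) {
        g0 += la2 % (g0p.col(i) + d0p[i]);
        g1 += la2 % (g1p.col(i) + d1p[i]);
      }
      double d0 = arma::accu(g0) / (2.0 * s);
      g1 += b % (g0 + d0);
      g0c.col(i) = g0; d0c[i] = d0;
      g1c.col(i) = g1; d1c[i] = arma::accu(g1) / (2.0 * (s + 1));
    }
    double lwden = std::lgamma(as + s + sdelta) - lgas;
    double Ts = 0.0;
    for (int i = 0; i <= s; ++i) {
      double d = d1c[i];
      if (d == 0.0) continue;
      double lw = std::lgamma(ai + i) - lgai + std::lgamma(aj + (s - i)) - lgaj
        - lwden + std::log(std::fabs(d)) + lex * M_LN2;
      Ts += (d > 0 ? 1.0 : -1.0) * std::exp(lw);
    }
    lay.push_back(Ts);
    S += Ts;
    if (S != 0.0 && std::fabs(Ts) <= tol * std::fabs(S)) {
      if (++consec >= nstab) { converged = true; break; }
    } else consec = 0;
    double m = std::max(std::max(arma::abs(g0c).max(), arma::abs(g1c).max()),
                        std::max(arma::abs(d0c).max(), arma::abs(d1c).max()));
    int de = scale_step(m);
    if (de != 0) {
      double f = pow2i(-de);
      g0c *= f; g1c *= f; d0c *= f; d1c *= f; lex += de;
    }
    g0p = g0c; d0p = d0c; g1p = g1c; d1p = d1c;
  }
  return List::create(_["layer_terms"] = NumericVector(lay.begin(), lay.end()),
                      _["M_used"] = std::min(s, Mmax),
                      _["converged"] = converged);
}

// same, general symmetric matrix arguments (non-commuting case)
// [[Rcpp::export]]
List cpp_d3l_mat_series(const arma::mat& A1, const arma::mat& A2,
                        const arma::mat& B,
                        double ai, double aj, double as, double sdelta,
                        int Mmax, double tol, int nstab) {
  int p = A1.n_rows;
  arma::mat I = arma::eye(p, p);
  std::vector<double> lay;
  std::vector<arma::mat> g0p(1, arma::mat(p, p, arma::fill::zeros)), g1p(1, B);
  std::vector<double> d0p(1, 1.0), d1p(1, arma::trace(B) / 2.0);
  long lex = 0;
  double lgai = std::lgamma(ai), lgaj = std::lgamma(aj), lgas = std::lgamma(as);
  double T0 = 0.0;
  if (d1p[0] != 0.0)
    T0 = (d1p[0] > 0 ? 1.0 : -1.0) *
      std::exp(lgas - std::lgamma(as + sdelta) + std::log(std::fabs(d1p[0])));
  lay.push_back(T0);
  double S = T0;
  int consec = 0;
  bool converged = false;
  int s;
  for (s = 1; s <= Mmax; ++s) {
    std::vector<arma::mat> g0c(s + 1), g1c(s + 1);
    std::vector<double> d0c(s + 1), d1c(s + 1);
    double m = 0.0;
    for (int i = 0; i <= s; ++i) {
      arma::mat g0(p, p, arma::fill::zeros), g1(p, p, arma::fill::zeros);
      if (i >= 1) {
        g0 += A1 * (g0p[i - 1] + d0p[i - 1] * I);
        g1 += A1 * (g1p[i - 1] + d1p[i - 1] * I);
      }
      if (s - i >= 1) {
        g0 += A2 * (g0p[i] + d0p[i] * I);
        g1 += A2 * (g1p[i] + d1p[i] * I);
      }
      double d0 = arma::trace(g0) / (2.0 * s);
      g1 += B * (g0 + d0 * I);
      g0c[i] = g0; d0c[i] = d0;
      g1c[i] = g1; d1c[i] = arma::trace(g1) / (2.0 * (s + 1));
      m = std::max(m, std::max(arma::abs(g0).max(), arma::abs(g1).max()));
      m = std::max(m, std::max(std::fabs(d0c[i]), std::fabs(d1c[i])));
    }
    double lwden = std::lgamma(as + s + sdelta) - lgas;
    double Ts = 0.0;
    for (int i = 0; i <= s; ++i) {
      double d = d1c[i];
      if (d == 0.0) continue;
      double lw = std::lgamma(ai + i) - lgai + std::lgamma(aj + (s - i)) - lgaj
        - lwden + std::log(std::fabs(d)) + lex * M_LN2;
      Ts += (d > 0 ? 1.0 : -1.0) * std::exp(lw);
    }
    lay.push_back(Ts);
    S += Ts;
    if (S != 0.0 && std::fabs(Ts) <= tol * std::fabs(S)) {
      if (++consec >= nstab) { converged = true; break; }
    } else consec = 0;
    int de = scale_step(m);
    if (de != 0) {
      double f = pow2i(-de);
      for (int i = 0; i <= s; ++i) { g0c[i] *= f; g1c[i] *= f; d0c[i] *= f; d1c[i] *= f; }
      lex += de;
    }
    g0p.swap(g0c); d0p.swap(d0c); g1p.swap(g1c); d1p.swap(d1c);
  }
  return List::create(_["layer_terms"] = NumericVector(lay.begin(), lay.end()),
                      _["M_used"] = std::min(s, Mmax),
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// small triangular tables of d_{i,j,0} and d_{i,j,1} (commuting arguments),
// i + j <= M; for oracle tests.
// [[Rcpp::export]]
List cpp_d3l_vec_table(const arma::vec& la1, const arma::vec& la2,
                       const arma::vec& b, int M) {
  int p = la1.n_elem;
  int ncell = (M + 1) * (M + 2) / 2;
  NumericVector m0(ncell), m1(ncell);
  IntegerVector e0(ncell), e1(ncell);
  arma::mat g0p(p, 1, arma::fill::zeros), g1p(p, 1);
  arma::rowvec d0p(1), d1p(1);
  d0p[0] = 1.0; g1p.col(0) = b; d1p[0] = arma::accu(b) / 2.0;
  long lex = 0;
  m0[0] = 1.0; e0[0] = 0; m1[0] = d1p[0]; e1[0] = 0;
  int pos = 1;
  for (int s = 1; s <= M; ++s) {
    arma::mat g0c(p, s + 1, arma::fill::zeros), g1c(p, s + 1, arma::fill::zeros);
    arma::rowvec d0c(s + 1), d1c(s + 1);
    for (int i = 0; i <= s; ++i) {
      arma::vec g0(p, arma::fill::zeros), g1(p, arma::fill::zeros);
      if (i >= 1) {
        g0 += la1 % (g0p.col(i - 1) + d0p[i - 1]);
        g1 += la1 % (g1p.col(i - 1) + d1p[i - 1]);
      }
      if (s - i >= 1) {
        g0 += la2 % (g0p.col(i) + d0p[i]);
        g1 += la2 % (g1p.col(i) + d1p[i]);
      }
      double d0 = arma::accu(g0) / (2.0 * s);
      g1 += b % (g0 + d0);
      g0c.col(i) = g0; d0c[i] = d0;
      g1c.col(i) = g1; d1c[i] = arma::accu(g1) / (2.0 * (s + 1));
    }
    double m = std::max(std::max(arma::abs(g0c).max(), arma::abs(g1c).max()),
                        std::max(arma::abs(d0c).max(), arma::abs(d1c).max()));
    int de = scale_step(m);
    if (de != 0) {
      double f = pow2i(-de);
      g0c *= f; g1c *= f; d0c *= f; d1c *= f; lex += de;
    }
    for (int i = 0; i <= s; ++i) {
      m0[pos] = d0c[i]; e0[pos] = (int) lex;
      m1[pos] = d1c[i]; e1[pos] = (int) lex;
      ++pos;
    }
    g0p = g0c; d0p = d0c; g1p = g1c; d1p = d1c;
  }
  return List::create(_["mant0"] = m0, _["ex0"] = e0,
                      _["mant1"] = m1, _["ex1"] = e1);
}

// ---------------------------------------------------------------------------
// full three-index table d_{i,j,k}(A1,A2,A3), i+j+k <= M, general symmetric
// arguments (third typically the rank-one mu mu'). Flattened by total order s,
// then k, then i (j = s - k - i). For the noncentral moment engine.
// [[Rcpp::export]]
List cpp_d3_mat_table(const arma::mat& A1, const arma::mat& A2,
                      const arma::mat& A3, int M) {
  int p = A1.n_rows;
  arma::mat I = arma::eye(p, p);
  int ncell = (M + 1) * (M + 2) * (M + 3) / 6;
  NumericVector mant(ncell);
  IntegerVector ex(ncell);
  // layer t: cells (k, i), i <= t - k; offset(k) = k*(t+1) - k*(k-1)/2
  std::vector<arma::mat> gprev(1, arma::mat(p, p, arma::fill::zeros));
  std::vector<double> dprev(1, 1.0);
  long lex = 0;
  mant[0] = 1.0; ex[0] = 0;
  int pos = 1;
  for (int s = 1; s <= M; ++s) {
    int ncur = (s + 1) * (s + 2) / 2;
    std::vector<arma::mat> gcur(ncur);
    std::vector<double> dcur(ncur);
    double m = 0.0;
    int t = s - 1; // previous layer
    int idx = 0;
    for (int k = 0; k <= s; ++k) {
      for (int i = 0; i + k <= s; ++i, ++idx) {
        int j = s - k - i;
        arma::mat g(p, p, arma::fill::zeros);
        if (i >= 1) {
          int q = k * (t + 1) - k * (k - 1) / 2 + (i - 1);
          g += A1 * (gprev[q] + dprev[q] * I);
        }
        if (j >= 1) {
          int q = k * (t + 1) - k * (k - 1) / 2 + i;
          g += A2 * (gprev[q] + dprev[q] * I);
        }
        if (k >= 1) {
          int q = (k - 1) * (t + 1) - (k - 1) * (k - 2) / 2 + i;
          g += A3 * (gprev[q] + dprev[q] * I);
        }
        gcur[idx] = g;
        dcur[idx] = arma::trace(g) / (2.0 * s);
        m = std::max(m, std::max(arma::abs(g).max(), std::fabs(dcur[idx])));
      }
    }
    int de = scale_step(m);
    if (de != 0) {
      double f = pow2i(-de);
      for (int q = 0; q < ncur; ++q) { gcur[q] *= f; dcur[q] *= f; }
      lex += de;
    }
    for (int q = 0; q < ncur; ++q) { mant[pos] = dcur[q]; ex[pos] = (int) lex; ++pos; }
    gprev.swap(gcur); dprev.swap(dcur);
  }
  return List::create(_["mant"] = mant, _["ex"] = ex);
}
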