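#include <Rcpp.h>
using namespace Rcpp;

// Negative binomial log-pmf in (mean, dispersion) form:
//   r = 1/phi,  log P(y) = lgamma(y+r) - lgamma(r) - lgamma(y+1)
//                          + r*log(r/(r+m)) + y*log(m/(r+m))
// phi == 0 is the exact Poisson limit.  All routines assume m > 0.

static inline double nb_ll(double y, double m, double phi) {
  if (phi == 0.0)
    return -m + y * std::log(m) - R::lgammafn(y + 1.0);
  double r = 1.0 / phi;
  return R::lgammafn(y + r) - R::lgammafn(r) - R::lgammafn(y + 1.0) +
         r * std::log(r / (r + m)) + y * std::log(m / (r + m));
}

// Per-group log-likelihood of every gene under every global atom.
// Returns a list of L matrices (N x K); entry [i,k] of matrix l is
//   sum_{j : lambda(j)=l} log NB(y_ij | c_j * mu_i * exp(atoms_k), phi_i).
// The k-independent terms are computed once per (i,j) cell.
// [[Rcpp::export]]
List cpp_atom_loglik(NumericMatrix y, NumericVector phi, NumericVector mu,
                     NumericVector cf, IntegerVector lambda, int L,
                     NumericVector atoms) {
  int N = y.nrow(), M = y.ncol(), K = atoms.size();
  List out(L);
  std::vector<double> ebeta(K);
  for (int k = 0; k < K; ++k) ebeta[k] = std::exp(atoms[k]);
  for (int l = 0; l < L; ++l) {
    NumericMatrix ll(N, K);
    for (int j = 0; j < M; ++j) {
      if (lambda[j] - 1 != l) continue;
      double c = cf[j];
      for (int i = 0; i < N; ++i) {
        double yij = y(i, j), r = 1.0 / phi[i];
        double a = c * mu[i];  // m = a * exp(beta_k)
        double cst = R::lgammafn(yij + r) - R::lgammafn(r) -
                     R::lgammafn(yij + 1.0) + r * std::log(r) +
                     yij * std::log(a);
        for (int k = 0; k < K; ++k) {
          ll(i, k) += cst + yij * atoms[k] -
                      (yij + r) * std::log(r + a * ebeta[k]);
        }
      }
    }
    out[l] = ll;
  }
  return out;
}

// N x L matrix of group-summed log-likelihoods at the current per-cell
// log-fold-changes beta_il (gene parameters mu, phi fixed).
// [[Rcpp::export]]
NumericMatrix cpp_obs_loglik(NumericMatrix y, NumericVector phi,
                             NumericVector mu, NumericVector cf,
                             IntegerVector lambda, int L,
                             NumericMatrix beta_il) {
  int N = y.nrow(), M = y.ncol();
  NumericMatrix out(N, L);
  for (int j = 0; j < M; ++j) {
    int l = lambda[j] - 1;
    for (int i = 0; i < N; ++i) {
      double m = cf[j] * mu[i] * std::exp(beta_il(i, l));
      out(i, l) += nb_ll(y(i, j), m, phi[i]);
    }
  }
  return out;
}

// Row-wise categorical sampling by inverse CDF.  logp holds unnormalised
// log-probabilities; u one Uniform(0,1) draw per row (supplied by the
// caller so that the RNG stream stays under R's control).  1-based result.
// [[Rcpp::export]]
IntegerVector cpp_sample_rows(NumericMatrix logp, NumericVector u) {
  int N = logp.nrow(), K = logp.ncol();
  IntegerVector z(N);
  std::vector<double> p(K);
  for (int i = 0; i < N; ++i) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k)
      if (logp(i, k) > mx) mx = logp(i, k);
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      p[k] = std::exp(logp(i, k) - mx);
      tot += p[k];
    }
    double target = u[i] * tot, acc = 0.0;
    int pick = K - 1;
    for (int k = 0; k < K; ++k) {
      acc += p[k];
      if (acc >= target) { pick = k; break; }
    }
    z[i] = pick + 1;
  }
  return z;
}
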