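// Adaptive componentwise random-walk Metropolis samplers for the two
// model-based designs.  Both posteriors are low-dimensional (5 and 11
// parameters) with cheap likelihoods; the samplers use R's RNG so that
// set.seed() in R makes every fit reproducible.  Patients are indexed
// into their dose cell so the dose-response curves are evaluated once
// per cell and sweep, not once per patient.  The R-level functions
// gumbel_cell_prob() / blrm_loglik() / pocrm_joint_loglik() mirror these
// likelihoods and are cross-checked against them in the test suite.

#include <Rcpp.h>
#include <functional>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// P(Y_A = a, Y_T = b) for Bernoulli marginals (pa, pt) coupled by the
// Gumbel model; tpsi = (e^psi - 1)/(e^psi + 1) = tanh(psi/2).
// Floored at 0 for likelihood stability.
static inline double gumbel_cell(double pa, double pt, double tpsi,
                                 int a, int b) {
  double ma = a ? pa : 1.0 - pa;
  double mb = b ? pt : 1.0 - pt;
  double sgn = ((a + b) & 1) ? -1.0 : 1.0;
  double p = ma * mb + sgn * pa * (1.0 - pa) * pt * (1.0 - pt) * tpsi;
  return p > 0.0 ? p : 0.0;
}

// [[Rcpp::export]]
double gumbel_cell_cpp(double pa, double pt, double psi, int a, int b) {
  return gumbel_cell(pa, pt, std::tanh(0.5 * psi), a, b);
}

// Joint weighted likelihood of the POCRM part-2 model.
// theta = (b0_T, log b1_T, b0_A, log b1_A, psi); xtc, xac hold the
// skeleton value of each dose cell under the selected orderings and
// cell[i] (0-based) is patient i's dose cell.
static double pocrm_ll(const std::vector<double>& th,
                       const NumericVector& xtc, const NumericVector& xac,
                       const IntegerVector& cell,
                       const NumericVector& wt, const NumericVector& wa,
                       const IntegerVector& yt, const IntegerVector& ya) {
  const double b0t = th[0], b1t = std::exp(th[1]);
  const double b0a = th[2], b1a = std::exp(th[3]);
  const double tpsi = std::tanh(0.5 * th[4]);
  const int C = xtc.size();
  std::vector<double> ft(C), fa(C);
  for (int c = 0; c < C; ++c) {
    ft[c] = logistic(b0t + b1t * xtc[c]);
    fa[c] = logistic(b0a + b1a * xac[c]);
  }
  double ll = 0.0;
  for (int i = 0; i < cell.size(); ++i) {
    double pt = wt[i] * ft[cell[i]];
    double pa = wa[i] * fa[cell[i]];
    double p = gumbel_cell(pa, pt, tpsi, ya[i], yt[i]);
    if (p <= 0.0) return R_NegInf;
    ll += std::log(p);
  }
  return ll;
}

// [[Rcpp::export]]
double pocrm_loglik_cpp(NumericVector theta, NumericVector xtc,
                        NumericVector xac, IntegerVector cell,
                        NumericVector wt, NumericVector wa,
                        IntegerVector yt, IntegerVector ya) {
  std::vector<double> th(theta.begin(), theta.end());
  return pocrm_ll(th, xtc, xac, cell, wt, wa, yt, ya);
}

// Combination probability of the BLRM: per-agent logistic models on the
// scaled doses, odds combined additively with a product interaction term.
static inline double comb_prob(double d1, double d2, double b01, double b11,
                               double b02, double b12, double eta) {
  double f1 = logistic(b01 + b11 * d1);
  double f2 = logistic(b02 + b12 * d2);
  double o1 = f1 / (1.0 - f1), o2 = f2 / (1.0 - f2);
  double odds = (o1 + o2 + o1 * o2) * std::exp(eta * d1 * d2);
  return odds / (1.0 + odds);
}

// theta = (b0_W1T, log b1_W1T, b0_W2T, log b1_W2T,
//          b0_W1A, log b1_W1A, b0_W2A, log b1_W2A, eta_T, eta_A, psi);
// d1c, d2c hold the scaled agent doses of each grid cell.
static double blrm_ll(const std::vector<double>& th,
                      const NumericVector& d1c, const NumericVector& d2c,
                      const IntegerVector& cell,
                      const NumericVector& wt, const NumericVector& wa,
                      const IntegerVector& yt, const IntegerVector& ya) {
  const double tpsi = std::tanh(0.5 * th[10]);
  const int C = d1c.size();
  std::vector<double> Pt(C), Pa(C);
  for (int c = 0; c < C; ++c) {
    Pt[c] = comb_prob(d1c[c], d2c[c], th[0], std::exp(th[1]),
                      th[2], std::exp(th[3]), th[8]);
    Pa[c] = comb_prob(d1c[c], d2c[c], th[4], std::exp(th[5]),
                      th[6], std::exp(th[7]), th[9]);
  }
  double ll = 0.0;
  for (int i = 0; i < cell.size(); ++i) {
    double pt = wt[i] * Pt[cell[i]];
    double pa = wa[i] * Pa[cell[i]];
    double p = gumbel_cell(pa, pt, tpsi, ya[i], yt[i]);
    if (p <= 0.0) return R_NegInf;
    ll += std::log(p);
  }
  return ll;
}

// [[Rcpp::export]]
double blrm_loglik_cpp(NumericVector theta, NumericVector d1c,
                       NumericVector d2c, IntegerVector cell,
                       NumericVector wt, NumericVector wa,
                       IntegerVector yt, IntegerVector ya) {
  std::vector<double> th(theta.begin(), theta.end());
  return blrm_ll(th, d1c, d2c, cell, wt, wa, yt, ya);
}

// Componentwise adaptive random-walk Metropolis.  Proposal scales adapt
// during burn-in towards a 0.44 per-component acceptance rate and are
// frozen afterwards.
static List run_metropolis(const std::function<double(const std::vector<double>&)>& ll,
                           NumericVector prior_mean, NumericVector prior_sd,
                           NumericVector init, LogicalVector fixed,
                           int n_burn, int n_keep) {
  const int p = init.size();
  std::vector<double> cur(init.begin(), init.end());
  std::vector<double> lscale(p, std::log(0.5));
  std::vector<int> acc(p, 0), tries(p, 0);
  RNGScope scope;

  auto logpost = [&](const std::vector<double>& th) {
    double lp = ll(th);
    if (!R_FINITE(lp)) return lp;
    for (int k = 0; k < p; ++k)
      lp += R::dnorm(th[k], prior_mean[k], prior_sd[k], 1);
    return lp;
  };

  double lp_cur = logpost(cur);
  if (!R_FINITE(lp_cur)) {
    // re-initialise from the prior until the posterior is finite
    for (int attempt = 0; attempt < 100 && !R_FINITE(lp_cur); ++attempt) {
      for (int k = 0; k < p; ++k)
        if (!fixed[k]) cur[k] = R::rnorm(prior_mean[k], prior_sd[k]);
      lp_cur = logpost(cur);
    }
    if (!R_FINITE(lp_cur))
      stop("could not find a starting point with finite log-posterior");
  }

  NumericMatrix draws(n_keep, p);
  std::vector<double> acc_rate(p, 0.0);
  const int total = n_burn + n_keep;
  for (int it = 0; it < total; ++it) {
    for (int k = 0; k < p; ++k) {
      if (fixed[k]) continue;
      double old = cur[k];
      cur[k] = old + std::exp(lscale[k]) * R::norm_rand();
      double lp_new = logpost(cur);
      ++tries[k];
      if (R_FINITE(lp_new) &&
          std::log(R::unif_rand()) < lp_new - lp_cur) {
        lp_cur = lp_new;
        ++acc[k];
      } else {
        cur[k] = old;
      }
      if (it < n_burn && tries[k] % 50 == 0) {
        double rate = acc[k] / 50.0;
        lscale[k] += (rate - 0.44);
        if (lscale[k] < -8.0) lscale[k] = -8.0;
        if (lscale[k] > 4.0) lscale[k] = 4.0;
        acc[k] = 0;
      }
    }
    if (it == n_burn - 1)
      for (int k = 0; k < p; ++k) { acc[k] = 0; tries[k] = 0; }
    if (it >= n_burn)
      for (int k = 0; k < p; ++k) draws(it - n_burn, k) = cur[k];
  }
  for (int k = 0; k < p; ++k)
    acc_rate[k] = tries[k] > 0 ? static_cast<double>(acc[k]) / tries[k] : NA_REAL;
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = NumericVector(acc_rate.begin(),
                                                       acc_rate.end()));
}

// [[Rcpp::export]]
List mcmc_pocrm_cpp(NumericVector xtc, NumericVector xac, IntegerVector cell,
                    NumericVector wt, NumericVector wa,
                    IntegerVector yt, IntegerVector ya,
                    NumericVector prior_mean, NumericVector prior_sd,
                    NumericVector init, LogicalVector fixed,
                    int n_burn, int n_keep) {
  auto ll = [&](const std::vector<double>& th) {
    return pocrm_ll(th, xtc, xac, cell, wt, wa, yt, ya);
  };
  return run_metropolis(ll, prior_mean, prior_sd, init, fixed,
                        n_burn, n_keep);
}

// [[Rcpp::export]]
List mcmc_blrm_cpp(NumericVector d1c, NumericVector d2c, IntegerVector cell,
                   NumericVector wt, NumericVector wa,
                   IntegerVector yt, IntegerVector ya,
                   NumericVector prior_mean, NumericVector prior_sd,
                   NumericVector init, LogicalVector fixed,
                   int n_burn, int n_keep) {
  auto ll = [&](const std::vector<double>& th) {
    return blrm_ll(th, d1c, d2c, cell, wt, wa, yt, ya);
  };
  return run_metropolis(ll, prior_mean, prior_sd, init, fixed,
                        n_burn, n_keep);
}
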