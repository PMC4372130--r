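#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grouped binomial-logistic log-likelihood given the linear predictor kappa:
//   sum_g  y_g * kappa_g - w_g * log(1 + exp(kappa_g))
// where group g collapses w_g cells sharing one covariate row, of which y_g
// experienced the transition. Computed in the numerically stable form
// (never under/overflows for finite kappa; equivalent to clamping
// probabilities away from 0 and 1).
static double loglik(const std::vector<double>& kappa,
                     const NumericVector& y, const NumericVector& w) {
  double s = 0.0;
  const int n = kappa.size();
  for (int i = 0; i < n; ++i) {
    const double k = kappa[i];
    const double l1pe = (k > 0.0) ? k + std::log1p(std::exp(-k))
                                  : std::log1p(std::exp(k));
    s += y[i] * k - w[i] * l1pe;
  }
  return s;
}

// Component-wise Gaussian random-walk Metropolis sampler for logistic
// regression coefficients under independent uniform box priors, on
// row-grouped (weighted) data. Per-coefficient proposal scales adapt during
// burn-in only (windows of 50 updates, nudged toward ~0.4 acceptance); the
// post-burn-in chain runs with frozen scales, thinned to at most n_keep
// retained draws. Uses R's RNG, so results are reproducible under
// set.seed() in the caller.
// [[Rcpp::export]]
List mh_logistic(NumericMatrix X, NumericVector y, NumericVector w,
                 int n_iter, int n_burn, int n_keep,
                 double lower, double upper) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n || w.size() != n)
    stop("lengths of y and w must match rows of X");
  if (n_burn >= n_iter) stop("burn-in must be shorter than the chain");

  std::vector<double> beta(p, 0.0), step(p, 0.1);
  std::vector<double> kappa(n, 0.0), kappa_prop(n);
  double ll = loglik(kappa, y, w);
  if (!std::isfinite(ll)) stop("non-finite likelihood at initial point");

  const int n_post = n_iter - n_burn;
  const int thin = std::max(1, n_post / n_keep);
  const int n_out = n_post / thin;
  NumericMatrix samples(n_out, p);
  std::vector<int> acc_win(p, 0), try_win(p, 0);
  long acc_post = 0, try_post = 0;
  int row = 0;

  for (int it = 0; it < n_iter; ++it) {
    const bool burn = it < n_burn;
    for (int j = 0; j < p; ++j) {
      const double prop = beta[j] + R::rnorm(0.0, step[j]);
      bool accept = false;
      if (prop >= lower && prop <= upper) {
        const double d = prop - beta[j];
        for (int i = 0; i < n; ++i) kappa_prop[i] = kappa[i] + X(i, j) * d;
        const double ll_prop = loglik(kappa_prop, y, w);
        if (std::log(R::runif(0.0, 1.0)) < ll_prop - ll) {
          beta[j] = prop;
          kappa.swap(kappa_prop);
          ll = ll_prop;
          accept = true;
        }
      }
      if (burn) {
        ++try_win[j];
        if (accept) ++acc_win[j];
        if (try_win[j] == 50) {  // adapt toward ~0.4 acceptance
          const double rate = acc_win[j] / 50.0;
          if (rate < 0.25) step[j] *= 0.8;
          else if (rate > 0.5) step[j] *= 1.25;
          acc_win[j] = 0;
          try_win[j] = 0;
        }
      } else {
        ++try_post;
        if (accept) ++acc_post;
      }
    }
    if (!burn && (it - n_burn) % thin == thin - 1 && row < n_out) {
      for (int j = 0; j < p; ++j) samples(row, j) = beta[j];
      ++row;
    }
  }

  return List::create(_["samples"] = samples,
                      _["acceptance"] = (double)acc_post / (double)try_post,
                      _["step"] = NumericVector(step.begin(), step.end()));
}
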