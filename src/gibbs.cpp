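// Gibbs sampler for the NCII hierarchical mixed model
//   y_ijk = mu + dam_i + sire_j + inter_ij + e_ijk
// with zero-mean normal random effects and inverse-gamma priors on each
// variance. All draws use R's RNG so set.seed() in R controls the chain.
// Terms can be switched off (for nested-model DIC comparisons); a disabled
// term contributes nothing to the fit and its variance is not sampled.

#include <Rcpp.h>
using namespace Rcpp;

static double rinvgamma(double shape, double rate_param) {
  // X ~ InvGamma(shape, scale=rate_param)  <=>  1/X ~ Gamma(shape, rate=rate_param)
  double g = R::rgamma(shape, 1.0 / rate_param);
  return 1.0 / g;
}

// sample one batch of random effects given residuals that exclude this term
static void sample_effects(NumericVector& eff, const NumericVector& partial,
                           const IntegerVector& idx, int n_lev,
                           double sigma2_e, double sigma2_u) {
  std::vector<double> sum(n_lev, 0.0);
  std::vector<int> cnt(n_lev, 0);
  int n = partial.size();
  for (int i = 0; i < n; i++) {
    sum[idx[i]] += partial[i];
    cnt[idx[i]]++;
  }
  for (int l = 0; l < n_lev; l++) {
    double prec = cnt[l] / sigma2_e + 1.0 / sigma2_u;
    double mean = (sum[l] / sigma2_e) / prec;
    eff[l] = R::rnorm(mean, std::sqrt(1.0 / prec));
  }
}

// [[Rcpp::export(name = ".gibbs_ncii_cpp")]]
List gibbs_ncii_cpp(NumericVector y,
                    IntegerVector dam, IntegerVector sire, IntegerVector inter,
                    int n_dam, int n_sire, int n_inter,
                    bool use_dam, bool use_sire, bool use_inter,
                    int n_iter, int burn, int thin,
                    double prior_shape, double prior_scale) {
  int n = y.size();
  double ybar = mean(y);
  NumericVector d(n_dam), s(n_sire), u(n_inter);
  double mu = ybar;
  double s2d = prior_scale / (prior_shape + 1.0);
  double s2s = s2d, s2u = s2d, s2e = s2d;
  {
    double v = var(y);
    if (v > 0) s2e = v;
  }
  int n_keep = (n_iter - burn) / thin;
  NumericMatrix samples(n_keep, 6);
  colnames(samples) = CharacterVector::create(
      "sigma2_dam", "sigma2_sire", "sigma2_inter", "sigma2_res",
      "mu", "deviance");
  NumericVector d_mean(n_dam), s_mean(n_sire), u_mean(n_inter);
  double mu_mean = 0.0, s2e_mean = 0.0;
  NumericVector partial(n);
  int kept = 0;

  for (int it = 0; it < n_iter; it++) {
    // mu (flat prior)
    double acc = 0.0;
    for (int i = 0; i < n; i++)
      acc += y[i] - (use_dam ? d[dam[i]] : 0.0) - (use_sire ? s[sire[i]] : 0.0)
                  - (use_inter ? u[inter[i]] : 0.0);
    mu = R::rnorm(acc / n, std::sqrt(s2e / n));

    if (use_dam) {
      for (int i = 0; i < n; i++)
        partial[i] = y[i] - mu - (use_sire ? s[sire[i]] : 0.0)
                     - (use_inter ? u[inter[i]] : 0.0);
      sample_effects(d, partial, dam, n_dam, s2e, s2d);
      double ss = 0.0; for (int l = 0; l < n_dam; l++) ss += d[l] * d[l];
      s2d = rinvgamma(prior_shape + n_dam / 2.0, prior_scale + ss / 2.0);
    }
    if (use_sire) {
      for (int i = 0; i < n; i++)
        partial[i] = y[i] - mu - (use_dam ? d[dam[i]] : 0.0)
                     - (use_inter ? u[inter[i]] : 0.0);
      sample_effects(s, partial, sire, n_sire, s2e, s2s);
      double ss = 0.0; for (int l = 0; l < n_sire; l++) ss += s[l] * s[l];
      s2s = rinvgamma(prior_shape + n_sire / 2.0, prior_scale + ss / 2.0);
    }
    if (use_inter) {
      for (int i = 0; i < n; i++)
        partial[i] = y[i] - mu - (use_dam ? d[dam[i]] : 0.0)
                     - (use_sire ? s[sire[i]] : 0.0);
      sample_effects(u, partial, inter, n_inter, s2e, s2u);
      double ss = 0.0; for (int l = 0; l < n_inter; l++) ss += u[l] * u[l];
      s2u = rinvgamma(prior_shape + n_inter / 2.0, prior_scale + ss / 2.0);
    }
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; i++) {
      double r = y[i] - mu - (use_dam ? d[dam[i]] : 0.0)
                 - (use_sire ? s[sire[i]] : 0.0)
                 - (use_inter ? u[inter[i]] : 0.0);
      sse += r * r;
    }
    s2e = rinvgamma(prior_shape + n / 2.0, prior_scale + sse / 2.0);

    if (it >= burn && (it - burn) % thin == 0) {
      double dev = 0.0;
      for (int i = 0; i < n; i++) {
        double fit = mu + (use_dam ? d[dam[i]] : 0.0)
                     + (use_sire ? s[sire[i]] : 0.0)
                     + (use_inter ? u[inter[i]] : 0.0);
        dev += R::dnorm4(y[i], fit, std::sqrt(s2e), 1);
      }
      dev *= -2.0;
      samples(kept, 0) = use_dam ? s2d : NA_REAL;
      samples(kept, 1) = use_sire ? s2s : NA_REAL;
      samples(kept, 2) = use_inter ? s2u : NA_REAL;
      samples(kept, 3) = s2e;
      samples(kept, 4) = mu;
      samples(kept, 5) = dev;
      for (int l = 0; l < n_dam; l++) d_mean[l] += d[l];
      for (int l = 0; l < n_sire; l++) s_mean[l] += s[l];
      for (int l = 0; l < n_inter; l++) u_mean[l] += u[l];
      mu_mean += mu;
      s2e_mean += s2e;
      kept++;
    }
  }
  for (int l = 0; l < n_dam; l++) d_mean[l] /= kept;
  for (int l = 0; l < n_sire; l++) s_mean[l] /= kept;
  for (int l = 0; l < n_inter; l++) u_mean[l] /= kept;
  mu_mean /= kept;
  s2e_mean /= kept;

  // deviance at the posterior means (for pD / DIC)
  double dev_hat = 0.0;
  for (int i = 0; i < n; i++) {
    double fit = mu_mean + (use_dam ? d_mean[dam[i]] : 0.0)
                 + (use_sire ? s_mean[sire[i]] : 0.0)
                 + (use_inter ? u_mean[inter[i]] : 0.0);
    dev_hat += R::dnorm4(y[i], fit, std::sqrt(s2e_mean), 1);
  }
  dev_hat *= -2.0;

  return List::create(_["samples"] = samples,
                      _["dam_mean"] = d_mean,
                      _["sire_mean"] = s_mean,
                      _["inter_mean"] = u_mean,
                      _["mu_mean"] = mu_mean,
                      _["deviance_hat"] = dev_hat);
}
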