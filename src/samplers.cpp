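#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs samplers for whole-genome regression:
//   y = 1*mu + W g + e,  e ~ N(0, sigma2e I)
// with marker-effect priors
//   variant 0 (BayesA):  g_k ~ N(0, s2_k), s2_k ~ nu*S/chisq(nu)
//   variant 1 (BayesB):  with prob pi as BayesA, else g_k = 0 (point mass)
//   variant 2 (BayesC):  two normal classes, shared sampled variances
//                        (large / small, labels kept ordered), pi optionally
//                        sampled from a Beta full conditional
//   variant 3 (Lasso):   g_k ~ N(0, sigma2e tau2_k), tau2_k ~ Exp(lambda2/2),
//                        lambda2 optionally Gamma-sampled
// Residual variance has a flat scaled-inv-chisq prior (nu = -2, S = 0).
// Markers are updated in fixed column order each cycle; all randomness comes
// from R's RNG, so set.seed() makes chains reproducible.

static double rinvchisq(double nu, double scale) {
  // scaled inverse chi-squared draw: nu * scale / chisq_nu
  return nu * scale / R::rchisq(nu);
}

static double rinvgauss(double mu, double lambda) {
  // Michael, Schucany & Haas
  double z = R::norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(NumericVector y, NumericMatrix W, int variant,
               double pi0, bool sample_pi, double beta_a, double beta_b,
               double nu, double S,
               double lambda2_init, bool sample_lambda2,
               double l2_shape, double l2_rate,
               bool tie_variances,
               int n_iter, int burn_in, int thin) {
  const int n = W.nrow(), p = W.ncol();
  if (y.size() != n) stop("y and W are incompatible");
  for (int i = 0; i < n; ++i)
    if (!R_finite(y[i])) stop("non-finite phenotype");

  std::vector<double> wtw(p);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, k) * W(i, k);
    wtw[k] = s;
  }

  // state
  double mu = mean(y);
  std::vector<double> g(p, 0.0), s2k(p, S), tau2(p, 1.0);
  std::vector<int> delta(p, 1);
  if (variant == 1) {  // BayesB starts with the prior share included
    for (int k = 0; k < p; ++k) delta[k] = (R::unif_rand() < pi0) ? 1 : 0;
  }
  double sigma2e = 0.0;
  for (int i = 0; i < n; ++i) sigma2e += (y[i] - mu) * (y[i] - mu);
  sigma2e = std::max(sigma2e / n / 2.0, 1e-8);
  double s2_large = S, s2_small = S / 100.0;
  double pi_cur = pi0;
  double lambda2 = lambda2_init;

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // accumulators
  std::vector<double> g_sum(p, 0.0), incl_sum(p, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0, pi_sum = 0.0;
  double s2L_sum = 0.0, s2S_sum = 0.0, l2_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i];
    double mu_new = (esum / n + mu) + R::norm_rand() * std::sqrt(sigma2e / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= shift;
    mu = mu_new;

    int n_in = 0;
    double ss_large = 0.0, ss_small = 0.0;
    int n_large = 0, n_small = 0;
    double tau2_sum_cycle = 0.0;

    for (int k = 0; k < p; ++k) {
      const double wk = wtw[k];
      if (wk <= 0.0) { g[k] = 0.0; continue; }
      // rhs = w_k' (e + w_k g_k)
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += W(i, k) * e[i];
      const double rhs = dot + wk * g[k];
      double g_old = g[k], g_new = 0.0;

      if (variant == 0) {            // BayesA
        double C = wk + sigma2e / s2k[k];
        double m = rhs / C;
        g_new = m + R::norm_rand() * std::sqrt(sigma2e / C);
        s2k[k] = rinvchisq(nu + 1.0, (nu * S + g_new * g_new) / (nu + 1.0));
      } else if (variant == 1) {     // BayesB
        double v0 = wk * sigma2e;
        double v1 = wk * wk * s2k[k] + v0;
        double log_odds = std::log(pi_cur / (1.0 - pi_cur)) +
          0.5 * (std::log(v0 / v1)) + 0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double p1 = 1.0 / (1.0 + std::exp(-log_odds));
        if (R::unif_rand() < p1) {
          delta[k] = 1; ++n_in;
          double C = wk + sigma2e / s2k[k];
          double m = rhs / C;
          g_new = m + R::norm_rand() * std::sqrt(sigma2e / C);
          s2k[k] = rinvchisq(nu + 1.0, (nu * S + g_new * g_new) / (nu + 1.0));
        } else {
          delta[k] = 0;
          g_new = 0.0;
          s2k[k] = rinvchisq(nu, S);  // refresh from the prior
        }
      } else if (variant == 2) {     // BayesC, two normal classes
        double v0 = wk * sigma2e;
        double vL = wk * wk * s2_large + v0;
        double vS = wk * wk * s2_small + v0;
        double log_odds = std::log(pi_cur / (1.0 - pi_cur)) +
          0.5 * std::log(vS / vL) + 0.5 * rhs * rhs * (1.0 / vS - 1.0 / vL);
        double p1 = 1.0 / (1.0 + std::exp(-log_odds));
        bool large = (R::unif_rand() < p1);
        double s2c = large ? s2_large : s2_small;
        double C = wk + sigma2e / s2c;
        double m = rhs / C;
        g_new = m + R::norm_rand() * std::sqrt(sigma2e / C);
        delta[k] = large ? 1 : 0;
        if (large) { ++n_large; ss_large += g_new * g_new; }
        else       { ++n_small; ss_small += g_new * g_new; }
      } else {                       // Bayesian Lasso
        double C = wk + 1.0 / tau2[k];
        double m = rhs / C;
        g_new = m + R::norm_rand() * std::sqrt(sigma2e / C);
        double g2 = std::max(g_new * g_new, 1e-12);
        double inv_tau2 = rinvgauss(std::sqrt(lambda2 * sigma2e / g2), lambda2);
        tau2[k] = 1.0 / std::max(inv_tau2, 1e-12);
        tau2_sum_cycle += tau2[k];
      }

      double diff = g_new - g_old;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= W(i, k) * diff;
      g[k] = g_new;
    }

    // class variances / mixing proportion / lasso rate
    if (variant == 2) {
      if (tie_variances) {
        double pooled = rinvchisq(nu + n_large + n_small,
                                  (nu * S + ss_large + ss_small) /
                                  (nu + n_large + n_small));
        s2_large = s2_small = pooled;
      } else {
        s2_large = rinvchisq(nu + n_large, (nu * S + ss_large) / (nu + n_large));
        double nuS_small = nu * S / 100.0;
        s2_small = rinvchisq(nu + n_small, (nuS_small + ss_small) / (nu + n_small));
        if (s2_small > s2_large) {  // keep labels ordered: "large" class larger
          std::swap(s2_small, s2_large);
          for (int k = 0; k < p; ++k) delta[k] = 1 - delta[k];
          int tmp = n_large; n_large = n_small; n_small = tmp;
        }
      }
      if (sample_pi)
        pi_cur = R::rbeta(beta_a + n_large, beta_b + p - n_large);
    }
    if (variant == 3 && sample_lambda2) {
      lambda2 = R::rgamma(l2_shape + p, 1.0 / (l2_rate + tau2_sum_cycle / 2.0));
    }

    // residual variance, flat scaled-inv-chisq prior (nu = -2, S = 0)
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = sse / R::rchisq((double)n - 2.0);

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++kept;
      mu_sum += mu; s2e_sum += sigma2e; pi_sum += pi_cur;
      s2L_sum += s2_large; s2S_sum += s2_small; l2_sum += lambda2;
      for (int k = 0; k < p; ++k) {
        g_sum[k] += g[k];
        incl_sum[k] += (variant == 0 || variant == 3) ? 1.0 : (double)delta[k];
      }
    }
  }

  if (kept == 0) stop("no post-burn-in samples kept");
  NumericVector gm(p), ip(p);
  for (int k = 0; k < p; ++k) {
    gm[k] = g_sum[k] / kept;
    ip[k] = incl_sum[k] / kept;
  }
  return List::create(
    _["g_mean"] = gm, _["inclusion_prob"] = ip,
    _["mu_mean"] = mu_sum / kept, _["sigma2e_mean"] = s2e_sum / kept,
    _["pi_mean"] = pi_sum / kept,
    _["sigma2_large_mean"] = s2L_sum / kept,
    _["sigma2_small_mean"] = s2S_sum / kept,
    _["lambda2_mean"] = l2_sum / kept,
    _["kept"] = kept);
}
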