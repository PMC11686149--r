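// Marginalised N-mixture likelihood and adaptive random-walk
// Metropolis-within-Gibbs sampler. The discrete latent abundance N_i is
// summed out of the likelihood (log-space, stable summation), so the chain
// moves only over (log lambda, alpha, beta, hyperparameters); N_i is
// recovered at retained iterations from its exact conditional.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact marginal log-likelihood for one site:
// log sum_{N = max(y)}^{K} Poisson(N; lambda) * prod_j Binomial(y_j; N, p_j)
// Full sum over the truncation range, no early exit: this is the
// oracle-facing path used by marginal_site_loglik().
// [[Rcpp::export]]
double site_marginal_loglik_cpp(IntegerVector y, double lambda,
                                NumericVector p, int K) {
  int J = y.size();
  int Nmin = 0;
  for (int j = 0; j < J; ++j) if (y[j] > Nmin) Nmin = y[j];
  if (K < Nmin) stop("K must be at least max(y)");
  double m = R_NegInf, s = 0.0;
  for (int N = Nmin; N <= K; ++N) {
    double lt = R::dpois((double)N, lambda, 1);
    for (int j = 0; j < J; ++j)
      lt += R::dbinom((double)y[j], (double)N, p[j], 1);
    if (!R_finite(lt)) { if (lt > 0) return NA_REAL; else continue; }
    if (lt > m) { s = s * std::exp(m - lt) + 1.0; m = lt; }
    else s += std::exp(lt - m);
  }
  if (!R_finite(m)) return R_NegInf;
  return m + std::log(s);
}

namespace {

struct NmixData {
  int S, J;
  std::vector<int> y;      // S x J, column-major
  std::vector<int> Nmin;   // per site: max_j y_ij
  std::vector<int> K;      // truncation per site
  std::vector<double> z;   // covariate
  std::vector<double> lgam; // lgamma(0..maxK+1) table: lgam[n] = lgamma(n+1)
  std::vector<double> buf; // scratch for conditional N sampling

  void init(const IntegerMatrix& ym, const NumericVector& zv,
            const IntegerVector& Kv) {
    S = ym.nrow(); J = ym.ncol();
    y.assign((size_t)S * J, 0);
    Nmin.assign(S, 0); K.assign(S, 0); z.assign(S, 0.0);
    int maxK = 0;
    for (int i = 0; i < S; ++i) {
      z[i] = zv[i]; K[i] = Kv[i];
      if (K[i] > maxK) maxK = K[i];
      for (int j = 0; j < J; ++j) {
        int v = ym(i, j);
        y[(size_t)j * S + i] = v;
        if (v > Nmin[i]) Nmin[i] = v;
      }
    }
    lgam.assign(maxK + 2, 0.0);
    for (int n = 0; n <= maxK + 1; ++n) lgam[n] = std::lgamma((double)n + 1.0);
    buf.assign(maxK + 2, 0.0);
  }
};

// Marginal log-likelihood for site i with early exit once terms are
// unimodal-decreasing and 45 log-units below the running maximum (error
// < exp(-45) relative). logp/log1mp are S x J column-major.
double site_ll(const NmixData& d, int i, double lambda,
               const std::vector<double>& logp,
               const std::vector<double>& log1mp) {
  if (lambda <= 0.0) return R_NegInf;
  if (lambda > (double)d.K[i]) return R_NegInf;  // outside truncation support
  double loglam = std::log(lambda);
  // per-N cost: J table lookups + a few flops:
  //  lt(N) = (J-1)*lgam[N] - sum_j lgam[N - y_ij] + N*(sl + loglam)
  //          - lambda + c0
  double sl = 0.0, c0 = 0.0;
  for (int j = 0; j < d.J; ++j) {
    int yij = d.y[(size_t)j * d.S + i];
    double lp = logp[(size_t)j * d.S + i];
    double l1 = log1mp[(size_t)j * d.S + i];
    sl += l1;
    c0 += yij * (lp - l1) - d.lgam[yij];
  }
  double m = R_NegInf, s = 0.0, prev = R_NegInf;
  for (int N = d.Nmin[i]; N <= d.K[i]; ++N) {
    double lb = (double)(d.J - 1) * d.lgam[N];
    for (int j = 0; j < d.J; ++j)
      lb -= d.lgam[N - d.y[(size_t)j * d.S + i]];
    double lt = lb + N * (sl + loglam) - lambda + c0;
    if (lt > m) { s = s * std::exp(m - lt) + 1.0; m = lt; }
    else {
      s += std::exp(lt - m);
      if (lt < prev && lt < m - 45.0) break;
    }
    prev = lt;
  }
  if (!R_finite(m)) return R_NegInf;
  return m + std::log(s);
}

// Draw N_i from its exact conditional given lambda_i and detection.
int sample_N_cond(NmixData& d, int i, double lambda,
                  const std::vector<double>& logp,
                  const std::vector<double>& log1mp) {
  double loglam = std::log(lambda);
  double sl = 0.0, c0 = 0.0;
  for (int j = 0; j < d.J; ++j) {
    int yij = d.y[(size_t)j * d.S + i];
    sl += log1mp[(size_t)j * d.S + i];
    c0 += yij * (logp[(size_t)j * d.S + i] - log1mp[(size_t)j * d.S + i])
          - d.lgam[yij];
  }
  int n0 = d.Nmin[i], hi = n0;
  double m = R_NegInf, prev = R_NegInf;
  for (int N = n0; N <= d.K[i]; ++N) {
    double lb = (double)(d.J - 1) * d.lgam[N];
    for (int j = 0; j < d.J; ++j)
      lb -= d.lgam[N - d.y[(size_t)j * d.S + i]];
    double lt = lb + N * (sl + loglam) - lambda + c0;
    d.buf[N - n0] = lt;
    hi = N;
    if (lt > m) m = lt;
    else if (lt < prev && lt < m - 45.0) break;
    prev = lt;
  }
  double tot = 0.0;
  for (int N = n0; N <= hi; ++N) {
    d.buf[N - n0] = std::exp(d.buf[N - n0] - m);
    tot += d.buf[N - n0];
  }
  double u = unif_rand() * tot, acc = 0.0;
  for (int N = n0; N <= hi; ++N) {
    acc += d.buf[N - n0];
    if (u <= acc) return N;
  }
  return hi;
}

inline double dlogis_log(double x) {
  // standard logistic log-density
  return -x - 2.0 * std::log1p(std::exp(-x));
}

inline double halfnorm_lp(double s, double scale) {
  return -0.5 * (s * s) / (scale * scale);
}

inline void set_p_col(const NmixData& d, int j, double alpha, double beta,
                      std::vector<double>& logp, std::vector<double>& log1mp) {
  for (int i = 0; i < d.S; ++i) {
    double eta = alpha + beta * d.z[i];
    double l1p = std::log1p(std::exp(-std::fabs(eta)));
    // log p = -log(1+exp(-eta)), log(1-p) = -eta - log(1+exp(-eta))
    double lp = eta >= 0 ? -l1p : eta - l1p;
    double l1 = eta >= 0 ? -eta - l1p : -l1p;
    logp[(size_t)j * d.S + i] = lp;
    log1mp[(size_t)j * d.S + i] = l1;
  }
}

struct Adapt {
  std::vector<double> ls;   // log proposal scales
  std::vector<int> acc, tot;
  std::vector<int> batch;
  void init(int n, double ls0) {
    ls.assign(n, ls0); acc.assign(n, 0); tot.assign(n, 0); batch.assign(n, 0);
  }
  void hit(int k, bool accepted) { tot[k]++; if (accepted) acc[k]++; }
  void maybe_adapt(int k, bool adapting) {
    if (tot[k] < 25) return;
    if (adapting) {
      double rate = (double)acc[k] / tot[k];
      batch[k]++;
      double delta = std::min(0.25, 1.0 / std::sqrt((double)batch[k]));
      ls[k] += (rate > 0.44 ? delta : -delta);
    }
    acc[k] = 0; tot[k] = 0;
  }
};

} // namespace

// One MCMC chain over the marginalised posterior.
// lambda_mode: 0 = site-specific lambda_i, 1 = shared scalar lambda,
// 2 = log-linear regression of lambda_i on z.
// [[Rcpp::export]]
List nmix_mcmc_cpp(IntegerMatrix y, NumericVector z, IntegerVector K,
                   int n_iter, int burn_in, int thin,
                   NumericVector loglam0, NumericVector alpha0,
                   NumericVector beta0, double mu_l0, double sig_l0,
                   double sig_b0, double gamma0, int lambda_mode,
                   double prior_mu_sd, double prior_sig_l_scale,
                   double prior_sig_b_scale, double prior_gamma_sd,
                   bool sample_N) {
  NmixData d;
  d.init(y, z, K);
  int S = d.S, J = d.J;
  int nlam = (lambda_mode == 1) ? 1 : S;

  std::vector<double> loglam(loglam0.begin(), loglam0.end());
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  double mu_l = mu_l0, sig_l = sig_l0, sig_b = sig_b0, gamma = gamma0;

  std::vector<double> logp((size_t)S * J), log1mp((size_t)S * J);
  for (int j = 0; j < J; ++j) set_p_col(d, j, alpha[j], beta[j], logp, log1mp);

  std::vector<double> sll(S);  // cached per-site marginal log-likelihood
  bool ok = true;
  for (int i = 0; i < S; ++i) {
    double lam = std::exp(loglam[lambda_mode == 1 ? 0 : i]);
    sll[i] = site_ll(d, i, lam, logp, log1mp);
    if (!R_finite(sll[i])) ok = false;
  }
  if (!ok) return List::create(_["ok"] = false);

  // blocks: lambda (nlam), alpha (J), beta (J), sig_l, sig_b, ridge
  Adapt ad;
  ad.init(nlam + 2 * J + 3, std::log(0.3));
  const int k_ridge = nlam + 2 * J + 2;
  int n_keep = (n_iter - burn_in) / thin;
  int npar = nlam + 2 * J + 3 + (lambda_mode == 2 ? 1 : 0) +
             (sample_N ? S : 0);
  NumericMatrix draws(n_keep, npar);
  int row = 0;

  auto lam_prior_mean = [&](int i) {
    return mu_l + (lambda_mode == 2 ? gamma * d.z[i] : 0.0);
  };

  for (int it = 1; it <= n_iter; ++it) {
    bool adapting = it <= burn_in;

    // --- lambda updates ---
    if (lambda_mode == 1) {
      double prop = loglam[0] + std::exp(ad.ls[0]) * norm_rand();
      double lamp = std::exp(prop);
      double nll = 0.0;
      std::vector<double> nsll(S);
      for (int i = 0; i < S; ++i) {
        nsll[i] = site_ll(d, i, lamp, logp, log1mp);
        nll += nsll[i];
      }
      double cll = 0.0;
      for (int i = 0; i < S; ++i) cll += sll[i];
      double lacc = nll - cll +
        R::dnorm(prop, mu_l, sig_l, 1) - R::dnorm(loglam[0], mu_l, sig_l, 1);
      bool a = R_finite(lacc) && std::log(unif_rand()) < lacc;
      if (a) { loglam[0] = prop; sll = nsll; }
      ad.hit(0, a); ad.maybe_adapt(0, adapting);
    } else {
      for (int i = 0; i < S; ++i) {
        double prop = loglam[i] + std::exp(ad.ls[i]) * norm_rand();
        double nll = site_ll(d, i, std::exp(prop), logp, log1mp);
        double mu_i = lam_prior_mean(i);
        double lacc = nll - sll[i] +
          R::dnorm(prop, mu_i, sig_l, 1) - R::dnorm(loglam[i], mu_i, sig_l, 1);
        bool a = R_finite(lacc) && std::log(unif_rand()) < lacc;
        if (a) { loglam[i] = prop; sll[i] = nll; }
        ad.hit(i, a); ad.maybe_adapt(i, adapting);
      }
    }

    // --- alpha / beta updates (per source, whole-column likelihood) ---
    std::vector<double> nsll(S);
    for (int j = 0; j < J; ++j) {
      int k = nlam + j;
      double prop = alpha[j] + std::exp(ad.ls[k]) * norm_rand();
      set_p_col(d, j, prop, beta[j], logp, log1mp);
      double dll = 0.0;
      for (int i = 0; i < S; ++i) {
        double lam = std::exp(loglam[lambda_mode == 1 ? 0 : i]);
        nsll[i] = site_ll(d, i, lam, logp, log1mp);
        dll += nsll[i] - sll[i];
      }
      double lacc = dll + dlogis_log(prop) - dlogis_log(alpha[j]);
      bool a = R_finite(lacc) && std::log(unif_rand()) < lacc;
      if (a) { alpha[j] = prop; for (int i = 0; i < S; ++i) sll[i] = nsll[i]; }
      else set_p_col(d, j, alpha[j], beta[j], logp, log1mp);
      ad.hit(k, a); ad.maybe_adapt(k, adapting);
    }
    for (int j = 0; j < J; ++j) {
      int k = nlam + J + j;
      double prop = beta[j] + std::exp(ad.ls[k]) * norm_rand();
      set_p_col(d, j, alpha[j], prop, logp, log1mp);
      double dll = 0.0;
      for (int i = 0; i < S; ++i) {
        double lam = std::exp(loglam[lambda_mode == 1 ? 0 : i]);
        nsll[i] = site_ll(d, i, lam, logp, log1mp);
        dll += nsll[i] - sll[i];
      }
      double lacc = dll + R::dnorm(prop, 0.0, sig_b, 1) -
        R::dnorm(beta[j], 0.0, sig_b, 1);
      bool a = R_finite(lacc) && std::log(unif_rand()) < lacc;
      if (a) { beta[j] = prop; for (int i = 0; i < S; ++i) sll[i] = nsll[i]; }
      else set_p_col(d, j, alpha[j], beta[j], logp, log1mp);
      ad.hit(k, a); ad.maybe_adapt(k, adapting);
    }

    // --- hyperparameters ---
    {
      // mu_l: conjugate normal draw given loglam
      double n_eff = (double)nlam;
      double sum = 0.0;
      for (int i = 0; i < nlam; ++i)
        sum += loglam[i] - (lambda_mode == 2 ? gamma * d.z[i] : 0.0);
      double prec = n_eff / (sig_l * sig_l) + 1.0 / (prior_mu_sd * prior_mu_sd);
      double mean = (sum / (sig_l * sig_l)) / prec;
      mu_l = mean + norm_rand() / std::sqrt(prec);
    }
    if (lambda_mode == 2) {
      double szz = 0.0, szr = 0.0;
      for (int i = 0; i < S; ++i) {
        szz += d.z[i] * d.z[i];
        szr += d.z[i] * (loglam[i] - mu_l);
      }
      double prec = szz / (sig_l * sig_l) +
        1.0 / (prior_gamma_sd * prior_gamma_sd);
      gamma = (szr / (sig_l * sig_l)) / prec + norm_rand() / std::sqrt(prec);
    }
    {
      // sig_l: random walk on log scale, half-normal prior + Jacobian
      int k = nlam + 2 * J;
      double prop = sig_l * std::exp(std::exp(ad.ls[k]) * norm_rand());
      double lacc = halfnorm_lp(prop, prior_sig_l_scale) -
        halfnorm_lp(sig_l, prior_sig_l_scale) +
        std::log(prop) - std::log(sig_l);
      for (int i = 0; i < nlam; ++i) {
        double mu_i = lambda_mode == 2 ? mu_l + gamma * d.z[i] : mu_l;
        lacc += R::dnorm(loglam[i], mu_i, prop, 1) -
          R::dnorm(loglam[i], mu_i, sig_l, 1);
      }
      bool a = R_finite(lacc) && std::log(unif_rand()) < lacc;
      if (a) sig_l = prop;
      ad.hit(k, a); ad.maybe_adapt(k, adapting);
    }
    {
      // sig_b likewise, from the beta vector
      int k = nlam + 2 * J + 1;
      double prop = sig_b * std::exp(std::exp(ad.ls[k]) * norm_rand());
      double lacc = halfnorm_lp(prop, prior_sig_b_scale) -
        halfnorm_lp(sig_b, prior_sig_b_scale) +
        std::log(prop) - std::log(sig_b);
      for (int j = 0; j < J; ++j)
        lacc += R::dnorm(beta[j], 0.0, prop, 1) -
          R::dnorm(beta[j], 0.0, sig_b, 1);
      bool a = R_finite(lacc) && std::log(unif_rand()) < lacc;
      if (a) sig_b = prop;
      ad.hit(k, a); ad.maybe_adapt(k, adapting);
    }

    // --- joint ridge move along the abundance/detection trade-off ---
    // Multiplying abundance by c while dividing detection by ~c leaves
    // expected counts nearly invariant; single-parameter updates cross this
    // ridge slowly. Propose log lambda_i + delta (and mu_l + delta, so the
    // hierarchy slides with it) jointly with alpha_j - delta. Repeated a few
    // times per sweep: it is cheap relative to the per-parameter scans and
    // dominates the integrated autocorrelation time.
    for (int rep = 0; rep < 5; ++rep) {
      double delta = std::exp(ad.ls[k_ridge]) * norm_rand();
      std::vector<double> plogp((size_t)S * J), plog1mp((size_t)S * J);
      for (int j = 0; j < J; ++j)
        set_p_col(d, j, alpha[j] - delta, beta[j], plogp, plog1mp);
      double dll = 0.0;
      bool finite = true;
      for (int i = 0; i < S; ++i) {
        double lam = std::exp(loglam[lambda_mode == 1 ? 0 : i] + delta);
        nsll[i] = site_ll(d, i, lam, plogp, plog1mp);
        if (!R_finite(nsll[i])) { finite = false; break; }
        dll += nsll[i] - sll[i];
      }
      double lacc = R_NegInf;
      if (finite) {
        lacc = dll +
          R::dnorm(mu_l + delta, 0.0, prior_mu_sd, 1) -
          R::dnorm(mu_l, 0.0, prior_mu_sd, 1);
        for (int j = 0; j < J; ++j)
          lacc += dlogis_log(alpha[j] - delta) - dlogis_log(alpha[j]);
      }
      bool a = R_finite(lacc) && std::log(unif_rand()) < lacc;
      if (a) {
        for (int i = 0; i < nlam; ++i) loglam[i] += delta;
        mu_l += delta;
        for (int j = 0; j < J; ++j) alpha[j] -= delta;
        logp.swap(plogp); log1mp.swap(plog1mp);
        for (int i = 0; i < S; ++i) sll[i] = nsll[i];
      }
      ad.hit(k_ridge, a); ad.maybe_adapt(k_ridge, adapting);
    }

    // --- retention ---
    if (it > burn_in && (it - burn_in) % thin == 0 && row < n_keep) {
      int c = 0;
      for (int i = 0; i < nlam; ++i) draws(row, c++) = std::exp(loglam[i]);
      for (int j = 0; j < J; ++j) draws(row, c++) = alpha[j];
      for (int j = 0; j < J; ++j) draws(row, c++) = beta[j];
      draws(row, c++) = mu_l;
      draws(row, c++) = sig_l;
      draws(row, c++) = sig_b;
      if (lambda_mode == 2) draws(row, c++) = gamma;
      if (sample_N) {
        for (int i = 0; i < S; ++i) {
          double lam = std::exp(loglam[lambda_mode == 1 ? 0 : i]);
          draws(row, c++) = (double)sample_N_cond(d, i, lam, logp, log1mp);
        }
      }
      ++row;
    }
  }

  NumericVector scales(ad.ls.begin(), ad.ls.end());
  return List::create(_["ok"] = true, _["draws"] = draws,
                      _["log_scales"] = scales, _["n_keep"] = row);
}
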