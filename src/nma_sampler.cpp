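#include <Rcpp.h>
using namespace Rcpp;

// Random-walk Metropolis-within-Gibbs sampler for a two-arm random-effects
// network meta-analysis.
//
// likelihood = 0: arm-level binomial-logit
//   r_b ~ Bin(n_b, plogis(mu_i)), r_t ~ Bin(n_t, plogis(mu_i + delta_i))
// likelihood = 1: contrast-level normal
//   y_i ~ N(delta_i, se_i^2)
// in both: delta_i ~ N(sum_j A(i,j) d_j, tau^2),
//          mu_i, d_j ~ N(0, prior sd), tau ~ U(0, tau_upper).
//
// Per-parameter proposal scales adapt toward 44% acceptance during burn-in
// only; adaptation is frozen afterward so the retained chain satisfies
// detailed balance. Uses R's RNG: seeding via set.seed() in R makes a chain
// fully deterministic.

static inline double log_lik_binary(int r, int n, double eta) {
  // Bin(r | n, plogis(eta)) up to the constant binomial coefficient;
  // log(1 + exp(eta)) evaluated overflow-safely
  double l1pe = eta > 0 ? eta + log1p(exp(-eta)) : log1p(exp(eta));
  return r * eta - n * l1pe;
}

// [[Rcpp::export]]
NumericMatrix nma_chain_cpp(int likelihood,
                            IntegerVector r_b, IntegerVector n_b,
                            IntegerVector r_t, IntegerVector n_t,
                            NumericVector y, NumericVector se,
                            NumericMatrix A,
                            double mu_sd, double d_sd, double tau_upper,
                            int iterations, int burnin, int thin,
                            NumericVector mu0, NumericVector delta0,
                            NumericVector d0, double tau0) {
  const int N = A.nrow();       // trials
  const int P = A.ncol();       // basic parameters
  const bool binary = likelihood == 0;
  const int n_mu = binary ? N : 0;
  const int n_par = P + 1 + n_mu + N;   // d, tau, mu, delta
  const int n_keep = (iterations - burnin) / thin;

  std::vector<double> d(d0.begin(), d0.end());
  std::vector<double> delta(delta0.begin(), delta0.end());
  std::vector<double> mu(n_mu, 0.0);
  for (int i = 0; i < n_mu; ++i) mu[i] = mu0[i];
  double tau = tau0;
  if (tau <= 0 || tau >= tau_upper) tau = 0.5 * tau_upper;

  // prior means of delta under the current d
  std::vector<double> md(N, 0.0);
  auto refresh_md = [&](void) {
    for (int i = 0; i < N; ++i) {
      double m = 0.0;
      for (int j = 0; j < P; ++j) m += A(i, j) * d[j];
      md[i] = m;
    }
  };
  refresh_md();

  // adaptive proposal scales (log scale) and acceptance counters
  std::vector<double> ls(n_par, log(0.5));
  ls[P] = log(0.1 * tau_upper);  // tau starts with a smaller step
  std::vector<int> acc(n_par, 0);
  const int batch = 50;
  int batch_no = 0;

  NumericMatrix out(n_keep, n_par);
  int keep_row = 0;

  for (int iter = 0; iter < iterations; ++iter) {
    // --- basic parameters d_j ---
    for (int j = 0; j < P; ++j) {
      double prop = d[j] + exp(ls[j]) * norm_rand();
      double dlp = (-prop * prop + d[j] * d[j]) / (2.0 * d_sd * d_sd);
      for (int i = 0; i < N; ++i) {
        double a = A(i, j);
        if (a != 0.0) {
          double m_new = md[i] + a * (prop - d[j]);
          double z_new = delta[i] - m_new, z_old = delta[i] - md[i];
          dlp += (-z_new * z_new + z_old * z_old) / (2.0 * tau * tau);
        }
      }
      if (log(unif_rand()) < dlp) {
        for (int i = 0; i < N; ++i) md[i] += A(i, j) * (prop - d[j]);
        d[j] = prop;
        acc[j]++;
      }
    }

    // --- between-trial SD tau ---
    {
      double prop = tau + exp(ls[P]) * norm_rand();
      if (prop > 0.0 && prop < tau_upper) {
        double dlp = N * (log(tau) - log(prop));
        for (int i = 0; i < N; ++i) {
          double z = delta[i] - md[i];
          dlp += z * z * (1.0 / (2.0 * tau * tau) - 1.0 / (2.0 * prop * prop));
        }
        if (log(unif_rand()) < dlp) { tau = prop; acc[P]++; }
      }
    }

    // --- trial baselines mu_i (binary likelihood only) ---
    for (int i = 0; i < n_mu; ++i) {
      double prop = mu[i] + exp(ls[P + 1 + i]) * norm_rand();
      double dlp = log_lik_binary(r_b[i], n_b[i], prop)
                 - log_lik_binary(r_b[i], n_b[i], mu[i])
                 + log_lik_binary(r_t[i], n_t[i], prop + delta[i])
                 - log_lik_binary(r_t[i], n_t[i], mu[i] + delta[i])
                 + (-prop * prop + mu[i] * mu[i]) / (2.0 * mu_sd * mu_sd);
      if (log(unif_rand()) < dlp) { mu[i] = prop; acc[P + 1 + i]++; }
    }

    // --- trial-specific effects delta_i ---
    for (int i = 0; i < N; ++i) {
      int idx = P + 1 + n_mu + i;
      double prop = delta[i] + exp(ls[idx]) * norm_rand();
      double z_new = prop - md[i], z_old = delta[i] - md[i];
      double dlp = (-z_new * z_new + z_old * z_old) / (2.0 * tau * tau);
      if (binary) {
        dlp += log_lik_binary(r_t[i], n_t[i], mu[i] + prop)
             - log_lik_binary(r_t[i], n_t[i], mu[i] + delta[i]);
      } else {
        double e_new = y[i] - prop, e_old = y[i] - delta[i];
        dlp += (-e_new * e_new + e_old * e_old) / (2.0 * se[i] * se[i]);
      }
      if (log(unif_rand()) < dlp) { delta[i] = prop; acc[idx]++; }
    }

    // --- adapt proposal scales during burn-in ---
    if (iter < burnin && (iter + 1) % batch == 0) {
      batch_no++;
      double step = std::min(0.1, 1.0 / sqrt((double)batch_no));
      for (int p = 0; p < n_par; ++p) {
        double rate = (double)acc[p] / batch;
        ls[p] += (rate > 0.44 ? step : -step);
        acc[p] = 0;
      }
    }

    // --- retain ---
    if (iter >= burnin && (iter - burnin) % thin == 0 && keep_row < n_keep) {
      int c = 0;
      for (int j = 0; j < P; ++j) out(keep_row, c++) = d[j];
      out(keep_row, c++) = tau;
      for (int i = 0; i < n_mu; ++i) out(keep_row, c++) = mu[i];
      for (int i = 0; i < N; ++i) out(keep_row, c++) = delta[i];
      keep_row++;
    }
  }
  return out;
}
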