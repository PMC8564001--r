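// Slice-within-Gibbs samplers for beta mean-precision models.
//
// Every model in the package is a beta regression on the logit scale:
// either a GLMM (fixed effects + random intercepts for up to two
// grouping factors) or a two-component mixture with the discrete labels
// marginalized out. Univariate slice sampling (stepping out + shrinkage)
// is used for every coordinate: it is tuning-free and has no rejection
// pathologies, at the price of a few likelihood evaluations per update.
// Coordinates touching only one group's observations evaluate only that
// group's likelihood.

#include <Rcpp.h>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double clamp_mu(double mu) {
  const double eps = 1e-12;
  if (mu < eps) return eps;
  if (mu > 1.0 - eps) return 1.0 - eps;
  return mu;
}

// log Beta(y; mu*phi, (1-mu)*phi)
static inline double betamp_log(double y, double mu, double phi) {
  mu = clamp_mu(mu);
  double a = mu * phi, b = (1.0 - mu) * phi;
  return (a - 1.0) * std::log(y) + (b - 1.0) * std::log1p(-y) -
         (R::lgammafn(a) + R::lgammafn(b) - R::lgammafn(a + b));
}

// Univariate slice sampler (Neal 2003), stepping out with width w and at
// most m total steps, then shrinkage. Returns the new point.
static double slice1(double x0, const std::function<double(double)>& logf,
                     double w, int m) {
  double lf0 = logf(x0);
  if (!R_finite(lf0)) return x0;  // should not happen; stay put
  double logy = lf0 - R::exp_rand();
  double u = R::unif_rand();
  double L = x0 - w * u;
  double Rr = L + w;
  int J = (int)std::floor(m * R::unif_rand());
  int K = m - 1 - J;
  while (J-- > 0 && logf(L) > logy) L -= w;
  while (K-- > 0 && logf(Rr) > logy) Rr += w;
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + R::unif_rand() * (Rr - L);
    double lf1 = logf(x1);
    if (lf1 >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// prior matrix row: (type, p1, p2, p3)
// type 0: normal(mean p1, sd p2); 1: student_t(df p1, mean p2, scale p3);
// type 2: exponential(rate p1), support (0, inf).
static inline double coef_lprior(const NumericMatrix& pr, int j, double x) {
  int type = (int)pr(j, 0);
  if (type == 0) return R::dnorm(x, pr(j, 1), pr(j, 2), 1);
  if (type == 1)
    return R::dt((x - pr(j, 2)) / pr(j, 3), pr(j, 1), 1) - std::log(pr(j, 3));
  if (type == 2)
    return x > 0 ? R::dexp(x, 1.0 / pr(j, 1), 1) : R_NegInf;
  return R_NegInf;
}

// [[Rcpp::export]]
NumericMatrix cpp_fit_beta_glmm(NumericVector y, NumericMatrix X,
                                List group_assign, NumericVector sigma_hn_sd,
                                NumericMatrix beta_priors,
                                double phi_shape, double phi_rate,
                                int iter, int warmup,
                                NumericVector init_beta, double init_jitter) {
  int n = y.size(), p = X.ncol(), K = group_assign.size();
  bool has_intercept = true;
  for (int i = 0; i < n; ++i)
    if (X(i, 0) != 1.0) { has_intercept = false; break; }

  std::vector<std::vector<std::vector<int> > > idx(K);
  std::vector<int> nlev(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector g = group_assign[k];  // 1-based
    int nl = 0;
    for (int i = 0; i < n; ++i) nl = std::max(nl, g[i]);
    nlev[k] = nl;
    idx[k].assign(nl, std::vector<int>());
    for (int i = 0; i < n; ++i) idx[k][g[i] - 1].push_back(i);
  }

  std::vector<double> beta(p), lsig(K), eta(n, 0.0);
  std::vector<std::vector<double> > u(K);
  for (int j = 0; j < p; ++j) {
    beta[j] = init_beta[j] + init_jitter * R::norm_rand();
    if ((int)beta_priors(j, 0) == 2 && beta[j] <= 0)
      beta[j] = init_beta[j];  // keep exponential-prior coefficients positive
  }
  for (int k = 0; k < K; ++k) {
    u[k].assign(nlev[k], 0.0);
    lsig[k] = std::log(0.2) + init_jitter * R::norm_rand();
  }
  double lphi = std::log(phi_shape / phi_rate) +
                init_jitter * R::norm_rand();

  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += beta[j] * X(i, j);
    eta[i] = e;  // u starts at 0
  }

  int n_keep = iter - warmup;
  int P = p;
  for (int k = 0; k < K; ++k) P += nlev[k];
  P += K + 1;
  NumericMatrix out(n_keep, P);

  for (int it = 0; it < iter; ++it) {
    double phi = std::exp(lphi);

    for (int j = 0; j < p; ++j) {
      double bj = beta[j];
      auto logf = [&](double bnew) {
        if ((int)beta_priors(j, 0) == 2 && bnew <= 0) return R_NegInf;
        double d = bnew - bj, s = coef_lprior(beta_priors, j, bnew);
        for (int i = 0; i < n; ++i)
          s += betamp_log(y[i], inv_logit(eta[i] + d * X(i, j)), phi);
        return s;
      };
      double bn = slice1(bj, logf, 0.3, 40);
      if (bn != bj) {
        double d = bn - bj;
        for (int i = 0; i < n; ++i) eta[i] += d * X(i, j);
        beta[j] = bn;
      }
    }

    for (int k = 0; k < K; ++k) {
      double sig = std::exp(lsig[k]);
      for (int l = 0; l < nlev[k]; ++l) {
        double ul = u[k][l];
        auto logf = [&](double unew) {
          double d = unew - ul;
          double s = R::dnorm(unew, 0.0, sig, 1);
          for (size_t t = 0; t < idx[k][l].size(); ++t) {
            int i = idx[k][l][t];
            s += betamp_log(y[i], inv_logit(eta[i] + d), phi);
          }
          return s;
        };
        double un = slice1(ul, logf, 0.3, 40);
        if (un != ul) {
          double d = un - ul;
          for (size_t t = 0; t < idx[k][l].size(); ++t) eta[idx[k][l][t]] += d;
          u[k][l] = un;
        }
      }
      auto logf_s = [&](double ls) {
        double s2 = std::exp(ls);
        double s = std::log(2.0) + R::dnorm(s2, 0.0, sigma_hn_sd[k], 1) + ls;
        for (int l = 0; l < nlev[k]; ++l) s += R::dnorm(u[k][l], 0.0, s2, 1);
        return s;
      };
      lsig[k] = slice1(lsig[k], logf_s, 0.5, 40);

      // interweaving (non-centered) update for sigma: holding z = u/sigma
      // fixed, a change of sigma rescales every random intercept, so the
      // likelihood informs sigma directly; this breaks the slow
      // sigma-phi ridge when groups have few observations
      {
        double sig_c = std::exp(lsig[k]);
        if (sig_c > 1e-8) {
          std::vector<double> z(nlev[k]);
          for (int l = 0; l < nlev[k]; ++l) z[l] = u[k][l] / sig_c;
          auto logf_nc = [&](double ls2) {
            double s2 = std::exp(ls2);
            double s = std::log(2.0) +
              R::dnorm(s2, 0.0, sigma_hn_sd[k], 1) + ls2;
            for (int l = 0; l < nlev[k]; ++l) {
              double d = (s2 - sig_c) * z[l];
              for (size_t t = 0; t < idx[k][l].size(); ++t) {
                int i = idx[k][l][t];
                s += betamp_log(y[i], inv_logit(eta[i] + d), phi);
              }
            }
            return s;
          };
          double ls_new = slice1(lsig[k], logf_nc, 0.5, 40);
          if (ls_new != lsig[k]) {
            double s2 = std::exp(ls_new);
            for (int l = 0; l < nlev[k]; ++l) {
              double d = (s2 - sig_c) * z[l];
              for (size_t t = 0; t < idx[k][l].size(); ++t)
                eta[idx[k][l][t]] += d;
              u[k][l] = s2 * z[l];
            }
            lsig[k] = ls_new;
          }
        }
      }

      // translation sweep: (b0, u) -> (b0 + d, u - d) leaves the
      // likelihood invariant (the intercept column is all ones), so d is
      // sampled from the priors alone; this decouples the slow
      // intercept/random-intercept direction
      if (has_intercept) {
        double sig2 = std::exp(lsig[k]);
        auto logf_d = [&](double dd) {
          double s = coef_lprior(beta_priors, 0, beta[0] + dd);
          if (!R_finite(s)) return R_NegInf;
          for (int l = 0; l < nlev[k]; ++l)
            s += R::dnorm(u[k][l] - dd, 0.0, sig2, 1);
          return s;
        };
        double d = slice1(0.0, logf_d, 0.3, 40);
        if (d != 0.0) {
          beta[0] += d;
          for (int l = 0; l < nlev[k]; ++l) u[k][l] -= d;
        }
      }
    }

    auto logf_p = [&](double lp) {
      double ph = std::exp(lp);
      double s = R::dgamma(ph, phi_shape, 1.0 / phi_rate, 1) + lp;
      for (int i = 0; i < n; ++i)
        s += betamp_log(y[i], inv_logit(eta[i]), ph);
      return s;
    };
    lphi = slice1(lphi, logf_p, 0.5, 40);

    if (it >= warmup) {
      int r = it - warmup, c = 0;
      for (int j = 0; j < p; ++j) out(r, c++) = beta[j];
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < nlev[k]; ++l) out(r, c++) = u[k][l];
      for (int k = 0; k < K; ++k) out(r, c++) = std::exp(lsig[k]);
      out(r, c++) = std::exp(lphi);
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Two-component beta mixture with the participant-level membership label
// marginalized out (log-sum-exp across components, within participant).
// placement: 0 none, 1 covariate on the group-2 mean logit, 2 covariate
// on the membership logit.
// prior_pars: a1_m, a1_s, a2_m, a2_s, phi_shape, phi_rate, b_sd,
//             pi0_sd, b1_sd
// [[Rcpp::export]]
NumericMatrix cpp_fit_beta_mixture(NumericVector y, IntegerVector pid,
                                   int n_pid, NumericVector x_mu2,
                                   NumericVector x_pi, int placement,
                                   NumericVector prior_pars,
                                   NumericVector init,
                                   int iter, int warmup, double init_jitter) {
  int n = y.size();
  double a1_m = prior_pars[0], a1_s = prior_pars[1];
  double a2_m = prior_pars[2], a2_s = prior_pars[3];
  double phi_shape = prior_pars[4], phi_rate = prior_pars[5];
  double b_sd = prior_pars[6], pi0_sd = prior_pars[7], b1_sd = prior_pars[8];

  int n_extra = (placement == 0) ? 1 : 2;
  int D = 4 + n_extra;
  std::vector<double> th(D);
  for (int j = 0; j < D; ++j)
    th[j] = init[j] + init_jitter * R::norm_rand();

  std::vector<double> lp1(n_pid), lp2(n_pid);
  auto logpost = [&](const std::vector<double>& t) {
    double a1 = t[0], a2 = t[1];
    double phi1 = std::exp(t[2]), phi2 = std::exp(t[3]);
    double b_mu2 = (placement == 1) ? t[4] : 0.0;
    double mu1 = inv_logit(a1);
    for (int i = 0; i < n_pid; ++i) { lp1[i] = 0.0; lp2[i] = 0.0; }
    for (int i = 0; i < n; ++i) {
      int g = pid[i] - 1;
      lp1[g] += betamp_log(y[i], mu1, phi1);
      double mu2 = inv_logit(a2 + b_mu2 * x_mu2[g]);
      lp2[g] += betamp_log(y[i], mu2, phi2);
    }
    double s = 0.0;
    for (int g = 0; g < n_pid; ++g) {
      double lpi;  // log pi_g on logit scale input
      if (placement == 2) lpi = t[4] + t[5] * x_pi[g];
      else lpi = (placement == 1) ? t[5] : t[4];
      // log(pi), log(1-pi) from the logit, stably
      double lse = (lpi > 0) ? lpi + std::log1p(std::exp(-lpi))
                             : std::log1p(std::exp(lpi));
      double log_pi = lpi - lse, log_1mpi = -lse;
      double A = log_1mpi + lp1[g], B = log_pi + lp2[g];
      double mx = std::max(A, B);
      s += mx + std::log(std::exp(A - mx) + std::exp(B - mx));
    }
    s += R::dnorm(a1, a1_m, a1_s, 1) + R::dnorm(a2, a2_m, a2_s, 1);
    s += R::dgamma(phi1, phi_shape, 1.0 / phi_rate, 1) + t[2];
    s += R::dgamma(phi2, phi_shape, 1.0 / phi_rate, 1) + t[3];
    if (placement == 0) s += R::dlogis(t[4], 0.0, 1.0, 1);
    if (placement == 1) {
      s += R::dnorm(t[4], 0.0, b_sd, 1);
      s += R::dlogis(t[5], 0.0, 1.0, 1);
    }
    if (placement == 2) {
      s += R::dnorm(t[4], 0.0, pi0_sd, 1);
      s += R::dnorm(t[5], 0.0, b1_sd, 1);
    }
    return s;
  };

  int n_keep = iter - warmup;
  NumericMatrix out(n_keep, D);
  for (int it = 0; it < iter; ++it) {
    for (int j = 0; j < D; ++j) {
      auto logf = [&](double v) {
        std::vector<double> t2 = th;
        t2[j] = v;
        return logpost(t2);
      };
      th[j] = slice1(th[j], logf, 0.4, 40);
    }
    if (it >= warmup)
      for (int j = 0; j < D; ++j) out(it - warmup, j) = th[j];
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Participant-level marginal log-likelihood of the graded model,
// integrating the random intercept out by Gauss-Hermite quadrature:
//   log int N(t; 0, sigma) prod_j Beta(y_ij; invlogit(eta_i + t), phi) dt
// eta_fix: S x n_pid matrix of fixed-effect linear predictors per draw.
// [[Rcpp::export]]
NumericMatrix cpp_graded_marginal_loglik(NumericVector y, IntegerVector pid,
                                         int n_pid, NumericMatrix eta_fix,
                                         NumericVector sigma,
                                         NumericVector phi,
                                         NumericVector gh_nodes,
                                         NumericVector gh_logw) {
  int n = y.size(), S = eta_fix.nrow(), Q = gh_nodes.size();
  std::vector<std::vector<int> > idx(n_pid);
  for (int i = 0; i < n; ++i) idx[pid[i] - 1].push_back(i);
  NumericMatrix out(S, n_pid);
  const double sqrt2 = std::sqrt(2.0), lsqrtpi = 0.5 * std::log(M_PI);
  for (int s = 0; s < S; ++s) {
    for (int g = 0; g < n_pid; ++g) {
      double best = R_NegInf;
      std::vector<double> terms(Q);
      for (int q = 0; q < Q; ++q) {
        double t = sqrt2 * sigma[s] * gh_nodes[q];
        double mu = inv_logit(eta_fix(s, g) + t);
        double ll = 0.0;
        for (size_t j = 0; j < idx[g].size(); ++j)
          ll += betamp_log(y[idx[g][j]], mu, phi[s]);
        terms[q] = gh_logw[q] - lsqrtpi + ll;
        if (terms[q] > best) best = terms[q];
      }
      double acc = 0.0;
      for (int q = 0; q < Q; ++q) acc += std::exp(terms[q] - best);
      out(s, g) = best + std::log(acc);
    }
    if (s % 100 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
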