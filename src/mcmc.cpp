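// Compiled likelihoods for the hybrid two-step model, the stay regression
// and the discounting models, plus the joint posterior density and an
// adaptive Metropolis-within-Gibbs sampler over all model variants.
//
// Parameter vectors are on the sampler scale: group SDs as log(sigma),
// subject-level k and theta as logs. Layouts (n = number of subjects):
//   RL variant (form = 1): 16 group parameters
//     [mu_alpha, log_sigma_alpha, mu_mb, log_sigma_mb, omega_mb,
//      mu_mf, log_sigma_mf, omega_mf, mu_beta2, log_sigma_beta2,
//      mu_p, log_sigma_p, mu_k, log_sigma_k, mu_theta, log_sigma_theta]
//     then per subject: [alpha_raw, beta_mb, beta_mf, beta2, p, beta_bias,
//                        log_k, log_theta]
//   Regression variant (form = 0): 16 group parameters
//     [mu_stay, log_sigma_stay, mu_reward, log_sigma_reward,
//      mu_common, log_sigma_common, mu_rc, log_sigma_rc,
//      omega_stay, omega_mf, omega_common, omega_mb,
//      mu_k, log_sigma_k, mu_theta, log_sigma_theta]
//     then per subject: [b_stay, b_reward, b_common, b_rc, log_k, log_theta]
// fn: 0 = exponential, 1 = hyperbolic discounting.
// gdist: 0 = half-Gaussian group distribution of k (f = identity),
//        1 = log-normal (f = log).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NGROUP = 16;
static const double P_COMMON = 0.7;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export]]
double cpp_rl_loglik(IntegerMatrix ts, double alpha_raw, double beta_mb,
                     double beta_mf, double beta2, double p,
                     double beta_bias) {
  const double alpha = logistic(alpha_raw);
  double Q[3][2] = {{0.5, 0.5}, {0.5, 0.5}, {0.5, 0.5}};
  int cdiff = 0, prev_a1 = -1;
  double ll = 0.0;
  const int T = ts.nrow();
  for (int t = 0; t < T; ++t) {
    const int a1 = ts(t, 0), s2 = ts(t, 1), a2 = ts(t, 2);
    const double r = ts(t, 3);
    // Bellman backup with the veridical transition function, mapping chosen
    // by the sign of the transition-evidence tally (ties -> canonical map)
    const double mA = std::max(Q[1][0], Q[1][1]);
    const double mB = std::max(Q[2][0], Q[2][1]);
    double qmb0, qmb1;
    if (cdiff >= 0) {
      qmb0 = P_COMMON * mA + (1.0 - P_COMMON) * mB;
      qmb1 = P_COMMON * mB + (1.0 - P_COMMON) * mA;
    } else {
      qmb0 = P_COMMON * mB + (1.0 - P_COMMON) * mA;
      qmb1 = P_COMMON * mA + (1.0 - P_COMMON) * mB;
    }
    double v0 = beta_mb * qmb0 + beta_mf * Q[0][0];
    double v1 = beta_mb * qmb1 + beta_mf * Q[0][1] + beta_bias;
    if (prev_a1 == 0) v0 += p;
    if (prev_a1 == 1) v1 += p;
    // log softmax of the chosen action
    const double d1 = (a1 == 0) ? (v1 - v0) : (v0 - v1);
    ll += -log1pexp_(d1);
    const double w0 = beta2 * Q[s2][0], w1 = beta2 * Q[s2][1];
    const double d2 = (a2 == 0) ? (w1 - w0) : (w0 - w1);
    ll += -log1pexp_(d2);
    // SARSA(lambda = 1): stage-1 backup toward Q(s2,a2), stage-2 backup
    // toward r, eligibility trace carrying the stage-2 error to stage 1
    const double q1 = Q[0][a1], q2 = Q[s2][a2];
    Q[0][a1] = q1 + alpha * (q2 - q1);
    const double delta2 = r - q2;
    Q[s2][a2] = q2 + alpha * delta2;
    Q[0][a1] += alpha * delta2;
    // unchosen values decay to the 0.5 baseline
    for (int s = 0; s < 3; ++s)
      for (int a = 0; a < 2; ++a) {
        if ((s == 0 && a == a1) || (s == s2 && a == a2)) continue;
        Q[s][a] += alpha * (0.5 - Q[s][a]);
      }
    cdiff += ((a1 == 0 && s2 == 1) || (a1 == 1 && s2 == 2)) ? 1 : -1;
    prev_a1 = a1;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_itc_loglik(NumericMatrix m, double k, double theta, int hyper) {
  double ll = 0.0;
  const int T = m.nrow();
  for (int t = 0; t < T; ++t) {
    const double D = m(t, 0), now = m(t, 1), later = m(t, 2);
    const double V = hyper ? later / (1.0 + k * D) : later * std::exp(-k * D);
    const double x = theta * (V - now);  // P(later) = logistic(x)
    ll += (m(t, 3) == 1.0) ? -log1pexp_(-x) : -log1pexp_(x);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_stay_loglik(NumericMatrix rows, double b_stay, double b_reward,
                       double b_common, double b_rc, double z,
                       double om_stay, double om_mf, double om_common,
                       double om_mb) {
  double ll = 0.0;
  const int T = rows.nrow();
  for (int t = 0; t < T; ++t) {
    const double rw = rows(t, 1), cm = rows(t, 2);
    const double eta = (b_stay + om_stay * z) + (b_reward + om_mf * z) * rw +
                       (b_common + om_common * z) * cm +
                       (b_rc + om_mb * z) * rw * cm;
    ll += (rows(t, 0) == 1.0) ? -log1pexp_(-eta) : -log1pexp_(eta);
  }
  return ll;
}

// ---------------------------------------------------------------------------

// hyperprior constants, in the order produced by prior_spec() on the R side:
// [0] coef_mean_sd, [1] weight_mean_sd, [2] alpha_mean_sd, [3] k_mean_sd,
// [4] theta_mean_sd, [5] sigma_scale (half-Cauchy), [6] omega_sd, [7] bias_sd
struct Ctx {
  int form, fn, gdist, n, spp;  // spp: sampler params per subject
  std::vector<IntegerMatrix> ts;
  std::vector<NumericMatrix> stay, itc;
  std::vector<double> pc;
};

static Ctx make_ctx(List ts_list, List stay_list, List itc_list, int form,
                    int fn, int gdist, NumericVector prior_c) {
  Ctx c;
  c.form = form; c.fn = fn; c.gdist = gdist;
  if (prior_c.size() != 8) stop("prior constants must have length 8");
  c.pc.assign(prior_c.begin(), prior_c.end());
  c.n = itc_list.size();
  c.spp = form == 1 ? 8 : 6;
  for (int i = 0; i < c.n; ++i) {
    if (form == 1) c.ts.push_back(as<IntegerMatrix>(ts_list[i]));
    else c.stay.push_back(as<NumericMatrix>(stay_list[i]));
    c.itc.push_back(as<NumericMatrix>(itc_list[i]));
  }
  return c;
}

static inline double dn(double x, double mu, double sd) {
  const double zz = (x - mu) / sd;
  return -0.91893853320467274178 - std::log(sd) - 0.5 * zz * zz;
}

static inline double half_cauchy(double sigma, double scale) {
  return std::log(2.0 / M_PI) - std::log(scale) -
         std::log1p((sigma / scale) * (sigma / scale));
}

// z-scored f(k) across subjects; returns false when degenerate
static bool compute_z(const Ctx& c, const double* th, std::vector<double>& z) {
  const int n = c.n;
  double mean = 0.0;
  for (int i = 0; i < n; ++i) {
    const double lk = th[NGROUP + i * c.spp + (c.spp - 2)];
    z[i] = c.gdist == 1 ? lk : std::exp(lk);
    mean += z[i];
  }
  mean /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (z[i] - mean) * (z[i] - mean);
  if (n < 2 || ss <= 0.0 || !R_finite(ss)) return false;
  const double sd = std::sqrt(ss / (n - 1));
  for (int i = 0; i < n; ++i) z[i] = (z[i] - mean) / sd;
  return true;
}

// group-level quantities entering the subject-level prior terms
struct GD {
  bool valid;
  double mu[5], sd[5];    // hierarchical means/SDs (5 used by RL, 4 by reg)
  double om[4];           // coupling slopes (RL uses om[0], om[1])
  double mu_k, s_k, mu_th, s_th, lphi_k, lphi_th;
};

static GD make_gd(const Ctx& c, const double* th) {
  GD g;
  g.valid = true;
  const int nh = c.form == 1 ? 5 : 4;
  if (c.form == 1) {
    const int mu_idx[5] = {0, 2, 5, 8, 10}, ls_idx[5] = {1, 3, 6, 9, 11};
    for (int j = 0; j < 5; ++j) {
      g.mu[j] = th[mu_idx[j]];
      g.sd[j] = std::exp(th[ls_idx[j]]);
    }
    g.om[0] = th[4]; g.om[1] = th[7]; g.om[2] = g.om[3] = 0.0;
  } else {
    for (int j = 0; j < 4; ++j) {
      g.mu[j] = th[2 * j];
      g.sd[j] = std::exp(th[2 * j + 1]);
      g.om[j] = th[8 + j];
    }
  }
  // half-Gaussian locations are constrained positive (sampled as logs),
  // which identifies the truncated-normal location against its scale
  g.mu_k = c.gdist == 1 ? th[12] : std::exp(th[12]);
  g.s_k = std::exp(th[13]);
  g.mu_th = std::exp(th[14]); g.s_th = std::exp(th[15]);
  for (int j = 0; j < nh; ++j)
    if (!R_finite(g.sd[j]) || g.sd[j] <= 0.0) g.valid = false;
  if (!R_finite(g.s_k) || g.s_k <= 0.0 || !R_finite(g.s_th) || g.s_th <= 0.0)
    g.valid = false;
  if (!g.valid) return g;
  g.lphi_k = R::pnorm(g.mu_k / g.s_k, 0.0, 1.0, 1, 1);
  g.lphi_th = R::pnorm(g.mu_th / g.s_th, 0.0, 1.0, 1, 1);
  return g;
}

// hyperprior terms (group-level parameters only)
static double group_prior(const Ctx& c, const double* th) {
  double lp = 0.0;
  if (c.form == 1) {
    lp += dn(th[0], 0, c.pc[2]) + dn(th[2], 0, c.pc[1]) +
          dn(th[5], 0, c.pc[1]) + dn(th[8], 0, c.pc[1]) +
          dn(th[10], 0, c.pc[1]) + dn(th[4], 0, c.pc[6]) +
          dn(th[7], 0, c.pc[6]);
    lp += c.gdist == 1 ? dn(th[12], 0, c.pc[3])
                       : dn(std::exp(th[12]), 0, c.pc[3]) + th[12];
    lp += dn(std::exp(th[14]), 0, c.pc[4]) + th[14];
    const int sig_idx[7] = {1, 3, 6, 9, 11, 13, 15};
    for (int j = 0; j < 7; ++j)
      lp += half_cauchy(std::exp(th[sig_idx[j]]), c.pc[5]) + th[sig_idx[j]];
  } else {
    for (int j = 0; j < 4; ++j) {
      lp += dn(th[2 * j], 0, c.pc[0]);
      lp += half_cauchy(std::exp(th[2 * j + 1]), c.pc[5]) + th[2 * j + 1];
      lp += dn(th[8 + j], 0, c.pc[6]);
    }
    lp += c.gdist == 1 ? dn(th[12], 0, c.pc[3])
                       : dn(std::exp(th[12]), 0, c.pc[3]) + th[12];
    lp += dn(std::exp(th[14]), 0, c.pc[4]) + th[14];
    lp += half_cauchy(std::exp(th[13]), c.pc[5]) + th[13];
    lp += half_cauchy(std::exp(th[15]), c.pc[5]) + th[15];
  }
  return lp;
}

// prior terms attached to subject i (includes the half-Gaussian truncation
// normalizers, which depend on the group location/scale, and the exp
// Jacobians of log_k / log_theta)
static double subj_prior(const Ctx& c, const double* th, const GD& g,
                         double z_i, int i) {
  const double* s = th + NGROUP + i * c.spp;
  double lp = 0.0;
  if (c.form == 1) {
    lp += dn(s[0], g.mu[0], g.sd[0]);
    lp += dn(s[1], g.mu[1] + g.om[0] * z_i, g.sd[1]);
    lp += dn(s[2], g.mu[2] + g.om[1] * z_i, g.sd[2]);
    lp += dn(s[3], g.mu[3], g.sd[3]);
    lp += dn(s[4], g.mu[4], g.sd[4]);
    lp += dn(s[5], 0, c.pc[7]);  // independent side-bias prior
  } else {
    for (int j = 0; j < 4; ++j) lp += dn(s[j], g.mu[j], g.sd[j]);
  }
  const double lk = s[c.spp - 2], lth = s[c.spp - 1];
  if (c.gdist == 1) {
    lp += dn(lk, g.mu_k, g.s_k);          // log k ~ N(mu_k, s_k)
  } else {
    lp += dn(std::exp(lk), g.mu_k, g.s_k) - g.lphi_k + lk;
  }
  lp += dn(std::exp(lth), g.mu_th, g.s_th) - g.lphi_th + lth;
  return lp;
}

static double lik_ts_i(const Ctx& c, const double* th,
                       const std::vector<double>& z, int i) {
  if (c.form == 1) {
    const double* s = th + NGROUP + i * 8;
    if (c.ts[i].nrow() == 0) return 0.0;
    return cpp_rl_loglik(c.ts[i], s[0], s[1], s[2], s[3], s[4], s[5]);
  }
  const double* s = th + NGROUP + i * 6;
  if (c.stay[i].nrow() == 0) return 0.0;
  return cpp_stay_loglik(c.stay[i], s[0], s[1], s[2], s[3], z[i], th[8],
                         th[9], th[10], th[11]);
}

static double lik_itc_i(const Ctx& c, const double* th, int i) {
  const double* s = th + NGROUP + i * c.spp;
  if (c.itc[i].nrow() == 0) return 0.0;
  return cpp_itc_loglik(c.itc[i], std::exp(s[c.spp - 2]),
                        std::exp(s[c.spp - 1]), c.fn);
}

// [[Rcpp::export]]
double cpp_joint_logdensity(List ts_list, List stay_list, List itc_list,
                            int form, int fn, int gdist,
                            NumericVector prior_c, NumericVector th) {
  Ctx c = make_ctx(ts_list, stay_list, itc_list, form, fn, gdist, prior_c);
  std::vector<double> z(c.n);
  const double* p = th.begin();
  if (!compute_z(c, p, z)) return R_NegInf;
  GD g = make_gd(c, p);
  if (!g.valid) return R_NegInf;
  double lp = group_prior(c, p);
  for (int i = 0; i < c.n; ++i) {
    lp += subj_prior(c, p, g, z[i], i);
    lp += lik_ts_i(c, p, z, i) + lik_itc_i(c, p, i);
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_run_chain(List ts_list, List stay_list, List itc_list, int form,
                   int fn, int gdist, NumericVector prior_c,
                   NumericVector init, int n_iter, int n_warmup, double ls0,
                   int adapt_interval, double target_accept) {
  Ctx c = make_ctx(ts_list, stay_list, itc_list, form, fn, gdist, prior_c);
  const int n = c.n, npar = NGROUP + n * c.spp;
  if (init.size() != npar) stop("init has wrong length");
  std::vector<double> th(init.begin(), init.end());
  std::vector<double> z(n), z2(n);
  if (!compute_z(c, th.data(), z))
    stop("non-finite log-density at the initial point (degenerate z)");
  GD gd = make_gd(c, th.data());
  if (!gd.valid) stop("non-finite log-density at the initial point");
  double gp = group_prior(c, th.data());
  std::vector<double> sp(n), sp2(n), ts_ll(n), ts_ll2(n), itc_ll(n);
  for (int i = 0; i < n; ++i) {
    sp[i] = subj_prior(c, th.data(), gd, z[i], i);
    ts_ll[i] = lik_ts_i(c, th.data(), z, i);
    itc_ll[i] = lik_itc_i(c, th.data(), i);
  }
  std::vector<double> ls(npar, ls0);
  std::vector<int> acc(npar, 0), acc_total(npar, 0);
  NumericMatrix draws(n_iter, npar);
  int batch = 0;

  // interweaved parameter-expansion moves: each hierarchy gets a joint
  // translation (mu and all subject values shift together) and a joint
  // rescale (subject deviations and sigma scale together), which mix the
  // group location/scale through the funnel far faster than coordinate
  // updates alone. lik: 0 = two-step, 1 = ITC, 2 = stay. type: 0 =
  // translation, 1 = Gaussian-hierarchy rescale, 2 = rescale of a positive
  // (half-Gaussian) hierarchy sampled on the log scale, 3 = natural-scale
  // spread rescale of a positive hierarchy (deviations around the group
  // mean scale with sigma; rejected when a value would leave the support).
  // All moves leave the z-scored covariate invariant (z is affine-invariant
  // in f(k); the type-3 k move changes spread, which z-scoring absorbs).
  struct Move { int mu_idx, sig_idx, jj, lik, type, om_idx; };
  std::vector<Move> moves;
  if (form == 1) {
    const int mu_idx[5] = {0, 2, 5, 8, 10}, sg_idx[5] = {1, 3, 6, 9, 11};
    const int om_idx[5] = {-1, 4, 7, -1, -1};  // beta_mb/beta_mf coupled
    for (int h = 0; h < 5; ++h) {
      moves.push_back({mu_idx[h], sg_idx[h], h, 0, 0, om_idx[h]});
      moves.push_back({mu_idx[h], sg_idx[h], h, 0, 1, om_idx[h]});
    }
    if (gdist == 1) {
      moves.push_back({12, 13, 6, 1, 0, -1});
      moves.push_back({12, 13, 6, 1, 1, -1});
    } else {
      moves.push_back({12, 13, 6, 1, 2, -1});
      moves.push_back({12, 13, 6, 1, 3, -1});
    }
    moves.push_back({14, 15, 7, 1, 2, -1});
    moves.push_back({14, 15, 7, 1, 3, -1});
    moves.push_back({4, 4, 1, 0, 4, -1});    // omega_mb with beta_mb[i]
    moves.push_back({7, 7, 2, 0, 4, -1});    // omega_mf with beta_mf[i]
  } else {
    for (int h = 0; h < 4; ++h) {
      moves.push_back({2 * h, 2 * h + 1, h, 2, 0, -1});
      moves.push_back({2 * h, 2 * h + 1, h, 2, 1, -1});
    }
    if (gdist == 1) {
      moves.push_back({12, 13, 4, 1, 0, -1});
      moves.push_back({12, 13, 4, 1, 1, -1});
    } else {
      moves.push_back({12, 13, 4, 1, 2, -1});
      moves.push_back({12, 13, 4, 1, 3, -1});
    }
    moves.push_back({14, 15, 5, 1, 2, -1});
    moves.push_back({14, 15, 5, 1, 3, -1});
    for (int h = 0; h < 4; ++h)          // discount slopes with coefs
      moves.push_back({8 + h, 8 + h, h, 2, 4, -1});
  }
  const int nmoves = (int)moves.size();
  std::vector<double> ls_m(nmoves, ls0), backup(n);
  std::vector<int> acc_m(nmoves, 0);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int j = 0; j < npar; ++j) {
      const double old = th[j];
      th[j] = old + std::exp(ls[j]) * norm_rand();
      bool accepted = false;
      if (j < NGROUP) {
        // group-level coordinate: z is unchanged; all subject prior terms
        // move, the likelihood only for the regression discount slopes
        GD gd2 = make_gd(c, th.data());
        if (gd2.valid) {
          double delta = group_prior(c, th.data()) - gp;
          for (int i = 0; i < n; ++i) {
            sp2[i] = subj_prior(c, th.data(), gd2, z[i], i);
            delta += sp2[i] - sp[i];
          }
          const bool slopes = (c.form == 0 && j >= 8 && j <= 11);
          if (slopes) {
            for (int i = 0; i < n; ++i) {
              ts_ll2[i] = lik_ts_i(c, th.data(), z, i);
              delta += ts_ll2[i] - ts_ll[i];
            }
          }
          if (R_finite(delta) && std::log(unif_rand()) < delta) {
            gd = gd2;
            gp = group_prior(c, th.data());
            sp.swap(sp2);
            if (slopes) ts_ll.swap(ts_ll2);
            accepted = true;
          }
        }
      } else {
        const int i = (j - NGROUP) / c.spp;
        const int jj = (j - NGROUP) % c.spp;
        if (jj == c.spp - 2) {
          // log k: reshuffles the z-scores of everyone, so every coupled
          // prior term (and, in the regression form, every stay likelihood)
          // is re-evaluated; plus subject i's own ITC likelihood
          if (compute_z(c, th.data(), z2)) {
            double delta = 0.0;
            for (int m = 0; m < n; ++m) {
              sp2[m] = subj_prior(c, th.data(), gd, z2[m], m);
              delta += sp2[m] - sp[m];
            }
            const double itc2 = lik_itc_i(c, th.data(), i);
            delta += itc2 - itc_ll[i];
            if (c.form == 0) {
              for (int m = 0; m < n; ++m) {
                ts_ll2[m] = lik_ts_i(c, th.data(), z2, m);
                delta += ts_ll2[m] - ts_ll[m];
              }
            }
            if (R_finite(delta) && std::log(unif_rand()) < delta) {
              z.swap(z2);
              sp.swap(sp2);
              itc_ll[i] = itc2;
              if (c.form == 0) ts_ll.swap(ts_ll2);
              accepted = true;
            }
          }
        } else if (jj == c.spp - 1) {  // log theta
          const double spi2 = subj_prior(c, th.data(), gd, z[i], i);
          const double itc2 = lik_itc_i(c, th.data(), i);
          const double delta = spi2 - sp[i] + itc2 - itc_ll[i];
          if (R_finite(delta) && std::log(unif_rand()) < delta) {
            sp[i] = spi2; itc_ll[i] = itc2;
            accepted = true;
          }
        } else {                       // two-step parameter of subject i
          const double spi2 = subj_prior(c, th.data(), gd, z[i], i);
          const double tsi2 = lik_ts_i(c, th.data(), z, i);
          const double delta = spi2 - sp[i] + tsi2 - ts_ll[i];
          if (R_finite(delta) && std::log(unif_rand()) < delta) {
            sp[i] = spi2; ts_ll[i] = tsi2;
            accepted = true;
          }
        }
      }
      if (accepted) { ++acc[j]; ++acc_total[j]; }
      else th[j] = old;
    }
    for (int mi = 0; mi < nmoves; ++mi) {
      const Move& mv = moves[mi];
      const double old_mu = th[mv.mu_idx], old_sig = th[mv.sig_idx];
      for (int i = 0; i < n; ++i) backup[i] = th[NGROUP + i * c.spp + mv.jj];
      double jac = 0.0;
      if (mv.type == 0) {
        const double eps = std::exp(ls_m[mi]) * norm_rand();
        th[mv.mu_idx] += eps;
        for (int i = 0; i < n; ++i) th[NGROUP + i * c.spp + mv.jj] += eps;
      } else if (mv.type == 1) {
        // rescale deviations around each subject's prior mean (which for a
        // coupled hierarchy includes the omega z_i shift), jointly with sigma
        const double lsg = std::exp(ls_m[mi]) * norm_rand();
        const double s = std::exp(lsg);
        for (int i = 0; i < n; ++i) {
          double& x = th[NGROUP + i * c.spp + mv.jj];
          const double ctr = old_mu +
            (mv.om_idx >= 0 ? th[mv.om_idx] * z[i] : 0.0);
          x = ctr + s * (x - ctr);
        }
        th[mv.sig_idx] += lsg;
        jac = n * lsg;
      } else if (mv.type == 2) {
        // all coordinates (log mu, log sigma, log x_i) shift together:
        // volume-preserving in the sampled coordinates
        const double lsg = std::exp(ls_m[mi]) * norm_rand();
        th[mv.mu_idx] += lsg;
        th[mv.sig_idx] += lsg;
        for (int i = 0; i < n; ++i) th[NGROUP + i * c.spp + mv.jj] += lsg;
      } else if (mv.type == 3) {
        // spread rescale on the natural scale: x_i <- mu + s (x_i - mu),
        // sigma <- s sigma; subject coordinates are logs, so the Jacobian
        // picks up log s + log x_i - log x_i' per subject
        const double lsg = std::exp(ls_m[mi]) * norm_rand();
        const double s = std::exp(lsg);
        const double mu_nat = std::exp(old_mu);
        bool ok = true;
        for (int i = 0; i < n; ++i) {
          double& lx = th[NGROUP + i * c.spp + mv.jj];
          const double x2 = mu_nat + s * (std::exp(lx) - mu_nat);
          if (x2 <= 0.0) { ok = false; break; }
          jac += lsg + lx - std::log(x2);
          lx = std::log(x2);
        }
        th[mv.sig_idx] += lsg;
        if (!ok) {
          th[mv.mu_idx] = old_mu;
          th[mv.sig_idx] = old_sig;
          for (int i = 0; i < n; ++i)
            th[NGROUP + i * c.spp + mv.jj] = backup[i];
          continue;
        }
      } else {
        // coupling interweave: shift omega and move each coupled subject
        // value along the covariate direction. In the RL form the shift
        // keeps the subject-prior deviations invariant; in the regression
        // form the compensating shift keeps the linear predictor invariant.
        const double eps = std::exp(ls_m[mi]) * norm_rand();
        th[mv.mu_idx] += eps;
        const double sgn = (c.form == 1) ? 1.0 : -1.0;
        for (int i = 0; i < n; ++i)
          th[NGROUP + i * c.spp + mv.jj] += sgn * eps * z[i];
      }
      bool accepted = false;
      GD gd2 = make_gd(c, th.data());
      if (gd2.valid) {
        const double gp2 = group_prior(c, th.data());
        double delta = gp2 - gp + jac;
        for (int i = 0; i < n; ++i) {
          sp2[i] = subj_prior(c, th.data(), gd2, z[i], i);
          delta += sp2[i] - sp[i];
        }
        std::vector<double>& lcache = (mv.lik == 1) ? itc_ll : ts_ll;
        for (int i = 0; i < n; ++i) {
          ts_ll2[i] = (mv.lik == 1) ? lik_itc_i(c, th.data(), i)
                                    : lik_ts_i(c, th.data(), z, i);
          delta += ts_ll2[i] - lcache[i];
        }
        if (R_finite(delta) && std::log(unif_rand()) < delta) {
          gd = gd2;
          gp = gp2;
          sp.swap(sp2);
          lcache.swap(ts_ll2);
          accepted = true;
          ++acc_m[mi];
        }
      }
      if (!accepted) {
        th[mv.mu_idx] = old_mu;
        th[mv.sig_idx] = old_sig;
        for (int i = 0; i < n; ++i) th[NGROUP + i * c.spp + mv.jj] = backup[i];
      }
    }
    if (iter < n_warmup && (iter + 1) % adapt_interval == 0) {
      ++batch;
      const double step = std::min(0.25, 1.0 / std::sqrt((double)batch));
      for (int j = 0; j < npar; ++j) {
        const double rate = (double)acc[j] / adapt_interval;
        ls[j] += (rate > target_accept) ? step : -step;
        acc[j] = 0;
      }
      for (int mi = 0; mi < nmoves; ++mi) {
        const double rate = (double)acc_m[mi] / adapt_interval;
        ls_m[mi] += (rate > target_accept) ? step : -step;
        acc_m[mi] = 0;
      }
    }
    for (int j = 0; j < npar; ++j) draws(iter, j) = th[j];
  }
  NumericVector rates(npar);
  for (int j = 0; j < npar; ++j) rates[j] = (double)acc_total[j] / n_iter;
  return List::create(_["draws"] = draws, _["accept"] = rates,
                      _["log_scales"] = NumericVector(ls.begin(), ls.end()));
}
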