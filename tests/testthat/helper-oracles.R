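# Independent scalar oracles, written directly from the model definitions
# and kept deliberately separate from the package implementation paths they
# check (no calls into the package's likelihood or prior code).

# --- two-step hybrid likelihood, explicit eligibility-trace recursion ------
oracle_rl_loglik <- function(m, alpha_raw, beta_mb, beta_mf, beta2, p_w,
                             beta_bias, lambda = 1) {
  alpha <- 1 / (1 + exp(-alpha_raw))
  Q <- matrix(0.5, 3, 2)  # rows: stage1, state A, state B
  cdiff <- 0
  prev <- NA
  ll <- 0
  for (t in seq_len(nrow(m))) {
    a1 <- m[t, 1] + 1; s2 <- m[t, 2] + 1; a2 <- m[t, 3] + 1; r <- m[t, 4]
    mA <- max(Q[2, ]); mB <- max(Q[3, ])
    if (cdiff >= 0) {
      qmb <- c(0.7 * mA + 0.3 * mB, 0.7 * mB + 0.3 * mA)
    } else {
      qmb <- c(0.7 * mB + 0.3 * mA, 0.7 * mA + 0.3 * mB)
    }
    v <- beta_mb * qmb + beta_mf * Q[1, ] + beta_bias * c(0, 1)
    if (!is.na(prev)) v[prev] <- v[prev] + p_w
    pr1 <- exp(v) / sum(exp(v))
    ll <- ll + log(pr1[a1])
    w <- beta2 * Q[s2, ]
    pr2 <- exp(w) / sum(exp(w))
    ll <- ll + log(pr2[a2])
    # SARSA updates with eligibility trace, written out step by step
    d1 <- 0 + Q[s2, a2] - Q[1, a1]
    Q[1, a1] <- Q[1, a1] + alpha * d1
    d2 <- r - Q[s2, a2]
    Q[s2, a2] <- Q[s2, a2] + alpha * d2
    Q[1, a1] <- Q[1, a1] + lambda * alpha * d2
    for (s in 1:3) for (a in 1:2) {
      if ((s == 1 && a == a1) || (s == s2 && a == a2)) next
      Q[s, a] <- Q[s, a] + alpha * (0.5 - Q[s, a])
    }
    cdiff <- cdiff + if ((a1 == 1 && s2 == 2) || (a1 == 2 && s2 == 3)) 1 else -1
    prev <- a1
  }
  unname(ll)
}

# --- discounting likelihood ------------------------------------------------
oracle_itc_loglik <- function(m, k, theta, fn) {
  ll <- 0
  for (t in seq_len(nrow(m))) {
    D <- m[t, 1]; now <- m[t, 2]; later <- m[t, 3]
    V <- if (fn == "hyper") later / (1 + k * D) else later * exp(-k * D)
    pl <- 1 / (1 + exp(-theta * (V - now)))
    ll <- ll + if (m[t, 4] == 1) log(pl) else log(1 - pl)
  }
  unname(ll)
}

# --- stay-regression likelihood -------------------------------------------
oracle_stay_loglik <- function(m, b, om, z) {
  # b = c(stay, reward, common, rc); om = c(om_stay, om_mf, om_common, om_mb)
  ll <- 0
  for (t in seq_len(nrow(m))) {
    x <- c(1, m[t, 2], m[t, 3], m[t, 2] * m[t, 3])
    eta <- sum((b + om * z) * x)
    pr <- 1 / (1 + exp(-eta))
    ll <- ll + if (m[t, 1] == 1) log(pr) else log(1 - pr)
  }
  unname(ll)
}

# --- joint posterior density on the sampler scale --------------------------
# mirrors the model definition term by term: likelihoods via the scalar
# oracles above, priors written straight from the hyperprior table
oracle_joint_logdensity <- function(model, th) {
  cfg <- model$config
  n <- model$n_subjects
  pc <- model$prior_c
  names(th) <- model$par_names
  spp <- if (cfg$twostep_form == "rl") 8 else 6
  sub <- function(i) th[16 + (i - 1) * spp + seq_len(spp)]
  lhc <- function(lsig) {
    s <- exp(lsig)
    log(2 / pi) - log(pc[6]) - log1p((s / pc[6])^2) + lsig
  }
  log_k <- vapply(seq_len(n), function(i) sub(i)[spp - 1], 0)
  log_th <- vapply(seq_len(n), function(i) sub(i)[spp], 0)
  fk <- if (cfg$group_dist == "lognormal") log_k else exp(log_k)
  z <- (fk - mean(fk)) / sd(fk)
  mu_k <- if (cfg$group_dist == "lognormal") th[13] else exp(th[13])
  s_k <- exp(th[14]); mu_t <- exp(th[15]); s_t <- exp(th[16])
  lp <- 0
  if (cfg$twostep_form == "rl") {
    lp <- lp + dnorm(th["mu_alpha"], 0, pc[3], log = TRUE) +
      dnorm(th["mu_mb"], 0, pc[2], log = TRUE) +
      dnorm(th["mu_mf"], 0, pc[2], log = TRUE) +
      dnorm(th["mu_beta2"], 0, pc[2], log = TRUE) +
      dnorm(th["mu_p"], 0, pc[2], log = TRUE) +
      dnorm(th["omega_mb"], 0, pc[7], log = TRUE) +
      dnorm(th["omega_mf"], 0, pc[7], log = TRUE)
    for (nm in c("log_sigma_alpha", "log_sigma_mb", "log_sigma_mf",
                 "log_sigma_beta2", "log_sigma_p", "log_sigma_k",
                 "log_sigma_theta"))
      lp <- lp + lhc(th[nm])
  } else {
    for (nm in c("mu_stay", "mu_reward", "mu_common", "mu_rc"))
      lp <- lp + dnorm(th[nm], 0, pc[1], log = TRUE)
    for (nm in c("omega_stay", "omega_mf", "omega_common", "omega_mb"))
      lp <- lp + dnorm(th[nm], 0, pc[7], log = TRUE)
    for (nm in c("log_sigma_stay", "log_sigma_reward", "log_sigma_common",
                 "log_sigma_rc", "log_sigma_k", "log_sigma_theta"))
      lp <- lp + lhc(th[nm])
  }
  lp <- lp + if (cfg$group_dist == "lognormal") {
    dnorm(th[13], 0, pc[4], log = TRUE)
  } else {
    dnorm(mu_k, 0, pc[4], log = TRUE) + th[13]
  }
  lp <- lp + dnorm(mu_t, 0, pc[5], log = TRUE) + th[15]
  for (i in seq_len(n)) {
    s <- sub(i)
    if (cfg$twostep_form == "rl") {
      lp <- lp + dnorm(s[1], th["mu_alpha"], exp(th["log_sigma_alpha"]), log = TRUE) +
        dnorm(s[2], th["mu_mb"] + th["omega_mb"] * z[i],
              exp(th["log_sigma_mb"]), log = TRUE) +
        dnorm(s[3], th["mu_mf"] + th["omega_mf"] * z[i],
              exp(th["log_sigma_mf"]), log = TRUE) +
        dnorm(s[4], th["mu_beta2"], exp(th["log_sigma_beta2"]), log = TRUE) +
        dnorm(s[5], th["mu_p"], exp(th["log_sigma_p"]), log = TRUE) +
        dnorm(s[6], 0, pc[8], log = TRUE)
      if (nrow(model$ts_list[[i]]) > 0)
        lp <- lp + oracle_rl_loglik(model$ts_list[[i]], s[1], s[2], s[3],
                                    s[4], s[5], s[6])
    } else {
      lp <- lp + dnorm(s[1], th["mu_stay"], exp(th["log_sigma_stay"]), log = TRUE) +
        dnorm(s[2], th["mu_reward"], exp(th["log_sigma_reward"]), log = TRUE) +
        dnorm(s[3], th["mu_common"], exp(th["log_sigma_common"]), log = TRUE) +
        dnorm(s[4], th["mu_rc"], exp(th["log_sigma_rc"]), log = TRUE)
      if (nrow(model$stay_list[[i]]) > 0)
        lp <- lp + oracle_stay_loglik(model$stay_list[[i]], s[1:4],
                                      th[c("omega_stay", "omega_mf",
                                           "omega_common", "omega_mb")], z[i])
    }
    lp <- lp + if (cfg$group_dist == "lognormal") {
      dnorm(log_k[i], mu_k, s_k, log = TRUE)
    } else {
      dnorm(exp(log_k[i]), mu_k, s_k, log = TRUE) -
        pnorm(mu_k / s_k, log.p = TRUE) + log_k[i]
    }
    lp <- lp + dnorm(exp(log_th[i]), mu_t, s_t, log = TRUE) -
      pnorm(mu_t / s_t, log.p = TRUE) + log_th[i]
    lp <- lp + oracle_itc_loglik(model$itc_list[[i]],
                                 exp(log_k[i]), exp(log_th[i]),
                                 cfg$discount_fn)
  }
  unname(lp)
}

# small synthetic cohort shared across tests
make_cohort <- function(n = 4, seed = 42, n_trials = 30,
                        group = group_spec(), fn = "hyper",
                        configs = study_config(2, n_twostep_trials = n_trials)) {
  generate_population(n, group, configs, fn = fn, seed = seed)
}

random_rl_params <- function() {
  rl_params(rnorm(1, 0, 1), rnorm(1, 1, 1), rnorm(1, 1, 1), rnorm(1, 1, 1),
            rnorm(1, 0, 0.5), rnorm(1, 0, 0.5))
}
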