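# Hybrid model-free / model-based likelihood for the two-step task, plus the
# consecutive-trial stay regression design. The functions here are the
# reference (scalar, step-by-step) implementation; the MCMC sampler uses a
# C++ translation of the same recursion (see rl_session_loglik(engine=)).
#
# State space: 3 primary states (1 = first stage, 2 = second-stage A,
# 3 = second-stage B), two actions each. Rewards are binary; the first stage
# pays nothing. Q-values start at 0.5, midway between the two known extremes.

P_COMMON <- 0.7  # veridical common-transition probability, fixed by design

#' Six-parameter set of the hybrid reinforcement-learning model
#'
#' `alpha_raw` is the unconstrained learning rate; it is passed through the
#' logistic function before use, so `plogis(alpha_raw)` is the learning rate
#' proper. `beta_mb`, `beta_mf` weight the model-based and model-free
#' first-stage values, `beta2` the second-stage values. `p` is the
#' perseveration weight (repeat the previous first-stage action when p > 0,
#' switch when p < 0) and `beta_bias` a side bias toward the second action
#' (toward the first action when negative).
#'
#' @param alpha_raw,beta_mb,beta_mf,beta2,p,beta_bias numeric scalars.
#' @return list of class `rl_params`.
#' @export
rl_params <- function(alpha_raw = 0, beta_mb = 1, beta_mf = 1, beta2 = 1,
                      p = 0, beta_bias = 0) {
  structure(list(alpha_raw = alpha_raw, beta_mb = beta_mb, beta_mf = beta_mf,
                 beta2 = beta2, p = p, beta_bias = beta_bias),
            class = "rl_params")
}

#' Fresh learner state
#'
#' Q-values for all 3 states x 2 actions initialized to 0.5, and the signed
#' transition-evidence tally at 0 (ties resolve to the canonical mapping:
#' action 0 commonly leads to state A).
#'
#' @return list with `Q` (3 x 2 matrix) and `count_diff` (integer).
#' @export
q_init <- function() {
  list(Q = matrix(0.5, nrow = 3, ncol = 2), count_diff = 0L)
}

# convert a validated twostep data.frame (or matrix) to the internal integer
# matrix: columns a1 (0/1), s2 (1 = A, 2 = B), a2 (0/1), reward (0/1)
twostep_matrix <- function(trials) {
  if (is.matrix(trials)) {
    storage.mode(trials) <- "integer"
    return(trials)
  }
  s2 <- if (is.character(trials$s2)) match(trials$s2, c("A", "B")) else trials$s2 + 1L
  cbind(a1 = as.integer(trials$a1), s2 = as.integer(s2),
        a2 = as.integer(trials$a2), reward = as.integer(trials$reward))
}

#' SARSA(lambda) learning step
#'
#' Applies the two temporal-difference updates of one trial with lambda = 1:
#' the first-stage value moves toward the second-stage value (stage-1
#' prediction error, immediate reward identically 0), the second-stage value
#' moves toward the reward, and the eligibility trace propagates the
#' second-stage prediction error back to the first-stage pair. Traces reset
#' every trial, so no trace state is carried. With lambda = 1 the net
#' first-stage update collapses to `(1 - alpha) * Q1 + alpha * r`.
#'
#' @param q learner state from [q_init()].
#' @param a1,s2,a2,reward trial events; `s2` is 1 (state A) or 2 (state B),
#'   actions are 0/1.
#' @param alpha learning rate in (0, 1).
#' @param lambda eligibility-trace weight; fixed to 1 in the model, exposed
#'   for the algebraic identity checks.
#' @return updated learner state (chosen pairs only; see [decay_unchosen()]).
#' @export
mf_learn <- function(q, a1, s2, a2, reward, alpha, lambda = 1) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  srow <- s2 + 1L            # Q row of the second-stage state
  q1 <- q$Q[1L, a1 + 1L]
  q2 <- q$Q[srow, a2 + 1L]
  # stage-1 backup: delta1 = 0 + Q(s2, a2) - Q(s1, a1)
  q$Q[1L, a1 + 1L] <- q1 + alpha * (q2 - q1)
  # stage-2 backup: delta2 = r - Q(s2, a2); no third stage, Q(s3, .) = 0
  delta2 <- reward - q2
  q$Q[srow, a2 + 1L] <- q2 + alpha * delta2
  # eligibility trace carries delta2 back to the first-stage pair
  q$Q[1L, a1 + 1L] <- q$Q[1L, a1 + 1L] + lambda * alpha * delta2
  q
}

#' Decay non-chosen action values to baseline
#'
#' Every state-action pair not visited on the current trial relaxes toward
#' the initialization baseline 0.5: `Q <- Q + alpha * (0.5 - Q)`.
#'
#' @param q learner state.
#' @param a1,s2,a2 the visited pairs of this trial (as in [mf_learn()]).
#' @param alpha decay rate (the model reuses the learning rate).
#' @param baseline decay target, default 0.5.
#' @return updated learner state.
#' @export
decay_unchosen <- function(q, a1, s2, a2, alpha, baseline = 0.5) {
  srow <- s2 + 1L
  for (s in 1:3) {
    for (a in 1:2) {
      if ((s == 1L && a == a1 + 1L) || (s == srow && a == a2 + 1L)) next
      q$Q[s, a] <- q$Q[s, a] + alpha * (baseline - q$Q[s, a])
    }
  }
  q
}

#' Update transition-mapping evidence
#'
#' Signed tally of evidence for the canonical transition mapping (action 0
#' commonly to state A and action 1 commonly to state B): +1 when the
#' observed transition is consistent with it, -1 otherwise. The model-based
#' backup uses the mapping currently favoured by the tally.
#'
#' @param count_diff current signed tally.
#' @param a1,s2 first-stage action (0/1) and second-stage state (1 = A, 2 = B).
#' @return updated tally.
#' @export
update_transition_evidence <- function(count_diff, a1, s2) {
  consistent <- (a1 == 0L && s2 == 1L) || (a1 == 1L && s2 == 2L)
  count_diff + (if (consistent) 1L else -1L)
}

#' Model-based first-stage action values
#'
#' One Bellman backup combining the learned second-stage values with the
#' veridical transition probabilities (0.7 common / 0.3 rare), under the
#' mapping currently favoured by the transition-evidence tally (ties go to
#' the canonical mapping):
#' `Q_mb(a) = 0.7 * max_a' Q(common(a), a') + 0.3 * max_a' Q(rare(a), a')`.
#'
#' @param q learner state.
#' @return numeric vector of length 2 (actions 0 and 1).
#' @export
mb_stage1_values <- function(q) {
  mA <- max(q$Q[2L, ])
  mB <- max(q$Q[3L, ])
  if (q$count_diff >= 0L) {
    c(P_COMMON * mA + (1 - P_COMMON) * mB, P_COMMON * mB + (1 - P_COMMON) * mA)
  } else {
    c(P_COMMON * mB + (1 - P_COMMON) * mA, P_COMMON * mA + (1 - P_COMMON) * mB)
  }
}

.softmax2 <- function(v) {
  m <- max(v)
  e <- exp(v - m)
  e / sum(e)
}

#' First-stage choice probabilities
#'
#' Softmax over the two first-stage actions of
#' `beta_mb * Q_mb + beta_mf * Q_mf(s1, .) + p * rep(.) + beta_bias * bias(.)`,
#' where `rep(a)` is 1 for the action taken at the first stage of the
#' previous trial (0 on the first trial) and `bias(a)` is 1 for the second
#' action.
#'
#' @param q learner state.
#' @param prev_a1 previous first-stage action (0/1) or `NA` on the first trial.
#' @param params an [rl_params()] set.
#' @return probability vector of length 2 summing to 1.
#' @export
stage1_choice_prob <- function(q, prev_a1, params) {
  qmb <- mb_stage1_values(q)
  v <- params$beta_mb * qmb + params$beta_mf * q$Q[1L, ]
  if (!is.na(prev_a1)) v[prev_a1 + 1L] <- v[prev_a1 + 1L] + params$p
  v[2L] <- v[2L] + params$beta_bias
  .softmax2(v)
}

#' Second-stage choice probabilities
#'
#' Softmax of `beta2 * Q(s2, .)`; the model-based and model-free values
#' coincide at the second stage, so a single set of Q-values governs choice.
#'
#' @param q learner state.
#' @param s2 second-stage state (1 = A, 2 = B).
#' @param beta2 inverse temperature.
#' @return probability vector of length 2.
#' @export
stage2_choice_prob <- function(q, s2, beta2) {
  .softmax2(beta2 * q$Q[s2 + 1L, ])
}

#' Log-likelihood of a two-step session
#'
#' Threads the learner state through an ordered trial list, accumulating the
#' log probability of both observed choices each trial and applying the
#' learning updates (SARSA backup on chosen pairs, decay on unchosen pairs,
#' transition-evidence tally) after the choices are scored.
#'
#' @param trials validated two-step table (data.frame) or internal integer
#'   matrix.
#' @param params an [rl_params()] set.
#' @param engine `"cpp"` for the compiled implementation used by the sampler,
#'   `"r"` for the scalar reference recursion built from the exported
#'   single-step operations. Both return identical values to numerical
#'   precision.
#' @return scalar log-likelihood (0 for an empty session).
#' @export
rl_session_loglik <- function(trials, params, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  m <- twostep_matrix(trials)
  if (nrow(m) == 0) return(0)
  if (engine == "cpp") {
    return(cpp_rl_loglik(m, params$alpha_raw, params$beta_mb, params$beta_mf,
                         params$beta2, params$p, params$beta_bias))
  }
  alpha <- stats::plogis(params$alpha_raw)
  q <- q_init()
  prev_a1 <- NA
  ll <- 0
  for (t in seq_len(nrow(m))) {
    a1 <- m[t, 1L]; s2 <- m[t, 2L]; a2 <- m[t, 3L]; r <- m[t, 4L]
    p1 <- stage1_choice_prob(q, prev_a1, params)
    ll <- ll + log(p1[a1 + 1L])
    p2 <- stage2_choice_prob(q, s2, params$beta2)
    ll <- ll + log(p2[a2 + 1L])
    q <- mf_learn(q, a1, s2, a2, r, alpha)
    q <- decay_unchosen(q, a1, s2, a2, alpha)
    q$count_diff <- update_transition_evidence(q$count_diff, a1, s2)
    prev_a1 <- a1
  }
  ll
}

#' Consecutive-trial stay-regression rows
#'
#' Builds the design of the logistic regression on pairs of consecutive
#' trials: `stay` is 1 when the same first-stage action was repeated,
#' `reward` is +1/-1 for a rewarded/unrewarded previous trial, and `common`
#' is +1/-1 for a common/rare previous transition. Only pairs whose trial
#' indices differ by exactly 1 are used, so aborted (missing) trials break
#' the chain. The subject's z-scored discount covariate is attached to every
#' row.
#'
#' @param trials validated two-step table with `trial`, `a1`, `transition`,
#'   `reward` columns.
#' @param discount_z scalar covariate (z-scored discount rate), default 0.
#' @return data.frame with columns `stay`, `reward`, `common`, `discount_z`;
#'   empty when fewer than two adjacent trials exist.
#' @export
build_stay_rows <- function(trials, discount_z = 0) {
  empty <- data.frame(stay = integer(0), reward = numeric(0),
                      common = numeric(0), discount_z = numeric(0))
  if (is.null(trials) || nrow(trials) < 2) return(empty)
  trials <- trials[order(trials$trial), , drop = FALSE]
  prev <- seq_len(nrow(trials) - 1L)
  adj <- which(diff(trials$trial) == 1L)
  if (length(adj) == 0) return(empty)
  data.frame(
    stay = as.integer(trials$a1[adj + 1L] == trials$a1[adj]),
    reward = ifelse(trials$reward[adj] == 1, 1, -1),
    common = ifelse(trials$transition[adj] == "common", 1, -1),
    discount_z = discount_z
  )
}

#' Maximum-likelihood fit of the hybrid model to one session
#'
#' Direct numerical maximization of [rl_session_loglik()] over the six
#' parameters, used by the parameter-recovery diagnostics. Not part of the
#' hierarchical pipeline (which is Bayesian); provided as an independent
#' per-subject estimator.
#'
#' The likelihood surface is ridged (model-based and model-free values are
#' correlated regressors), so the search runs Nelder-Mead from several
#' starting points emphasizing different control mixtures and polishes the
#' best solution with a restart.
#'
#' @param trials two-step trial table.
#' @param start optional extra start values (an [rl_params()]).
#' @return list with `params` (fitted [rl_params()]) and `loglik`.
#' @export
rl_mle <- function(trials, start = NULL) {
  m <- twostep_matrix(trials)
  obj <- function(x) -cpp_rl_loglik(m, x[1], x[2], x[3], x[4], x[5], x[6])
  starts <- list(c(0, 1, 1, 1, 0, 0),      # balanced control
                 c(0, 3, 0.5, 3, 0, 0),    # model-based dominant
                 c(0, 0.5, 3, 3, 0, 0))    # model-free dominant
  if (!is.null(start)) starts <- c(list(unlist(start)), starts)
  best <- NULL
  for (x0 in starts) {
    fit <- stats::optim(x0, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 3000))
  pars <- as.list(best$par)
  names(pars) <- c("alpha_raw", "beta_mb", "beta_mf", "beta2", "p",
                   "beta_bias")
  list(params = do.call(rl_params, pars), loglik = -best$value)
}
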