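# Generators for complete synthetic studies: the drifting two-step
# environment, agents driven by the package's own likelihoods, the adaptive
# intertemporal-choice staircase (session 1) and the individually calibrated
# second session, and a population generator with a known ground-truth
# coupling between discount rate and the decision-system weights.
#
# All generators draw from R's global RNG; seed with set.seed() (or use the
# seed arguments of the higher-level functions, which derive independent
# per-subject substreams from one master seed).

#' Group-level generating distribution of a synthetic population
#'
#' Means and SDs of the subject-level parameter distributions, the group
#' distribution of the discount rate, and the coupling coefficients
#' `omega_mb`/`omega_mf` that shift each subject's model-based and
#' model-free weights by a multiple of the z-scored (possibly
#' log-transformed) discount rate.
#'
#' Defaults describe a population that engages both decision systems with
#' moderate heterogeneity: learning rates centred at 0.5 (logistic scale),
#' softmax weights of a few units on the \[0,1\] Q-value scale, mild
#' perseveration, discount rates with median near 1 per scaled year, and
#' choice noise `theta` giving crisp choices for value differences of tens
#' of dollars. See the methods vignette for the reasoning behind each value.
#'
#' @param mu_alpha,sigma_alpha learning-rate distribution (unconstrained
#'   logistic scale).
#' @param mu_mb,sigma_mb,mu_mf,sigma_mf,mu_beta2,sigma_beta2,mu_p,sigma_p
#'   softmax-weight distributions.
#' @param sigma_bias SD of the zero-mean side-bias distribution.
#' @param mu_k,sigma_k discount-rate distribution; interpreted on the natural
#'   scale (half-Gaussian, truncated at 0) when `group_dist = "normal"` and
#'   on the log scale when `"lognormal"`.
#' @param group_dist `"normal"` or `"lognormal"`.
#' @param mu_theta,sigma_theta ITC inverse-temperature distribution
#'   (half-Gaussian, 1/USD).
#' @param omega_mb,omega_mf coupling of the z-scored `f(k)` onto the
#'   model-based / model-free weights (`f` = identity for a normal group
#'   distribution, log for log-normal).
#' @return list of class `group_spec`.
#' @export
group_spec <- function(mu_alpha = 0, sigma_alpha = 1,
                       mu_mb = 2, sigma_mb = 1,
                       mu_mf = 2, sigma_mf = 1,
                       mu_beta2 = 3, sigma_beta2 = 1,
                       mu_p = 0.2, sigma_p = 0.3,
                       sigma_bias = 0.3,
                       mu_k = 1, sigma_k = 0.5,
                       group_dist = c("normal", "lognormal"),
                       mu_theta = 0.08, sigma_theta = 0.03,
                       omega_mb = 0, omega_mf = 0) {
  group_dist <- match.arg(group_dist)
  spec <- list(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
               mu_mb = mu_mb, sigma_mb = sigma_mb,
               mu_mf = mu_mf, sigma_mf = sigma_mf,
               mu_beta2 = mu_beta2, sigma_beta2 = sigma_beta2,
               mu_p = mu_p, sigma_p = sigma_p, sigma_bias = sigma_bias,
               mu_k = mu_k, sigma_k = sigma_k, group_dist = group_dist,
               mu_theta = mu_theta, sigma_theta = sigma_theta,
               omega_mb = omega_mb, omega_mf = omega_mf)
  sds <- spec[grep("^sigma_", names(spec))]
  stopifnot(all(unlist(sds) > 0))
  class(spec) <- "group_spec"
  spec
}

#' One step of the Gaussian payoff drift
#'
#' Perturbs each of the four terminal reward probabilities by independent
#' Gaussian noise with the study's drift SD and reflects the result into the
#' study's boundaries, so the walk never leaves them.
#'
#' @param p numeric vector of 4 reward probabilities.
#' @param config a [study_config()].
#' @return drifted probability vector, all components within
#'   `[drift_lo, drift_hi]`.
#' @export
step_payoff_drift <- function(p, config) {
  stopifnot(length(p) == 4, all(p >= config$drift_lo), all(p <= config$drift_hi))
  p <- p + stats::rnorm(4, 0, config$drift_sd)
  lo <- config$drift_lo; hi <- config$drift_hi
  for (i in seq_along(p)) {
    while (p[i] < lo || p[i] > hi) {
      if (p[i] > hi) p[i] <- 2 * hi - p[i]
      if (p[i] < lo) p[i] <- 2 * lo - p[i]
    }
  }
  p
}

#' Sample first-to-second-stage transitions
#'
#' The fixed transition structure of the task: action 0 leads to state A and
#' action 1 to state B with probability 0.7 (common), and to the opposite
#' state with probability 0.3 (rare).
#'
#' @param a1 vector of first-stage actions (0/1).
#' @return data.frame with `s2` ("A"/"B") and `transition` ("common"/"rare"),
#'   one row per action.
#' @export
sample_transition <- function(a1) {
  stopifnot(all(a1 %in% c(0, 1)))
  common <- stats::runif(length(a1)) < P_COMMON
  s2_idx <- ifelse(common, a1, 1 - a1)  # 0 -> A, 1 -> B
  data.frame(s2 = c("A", "B")[s2_idx + 1L],
             transition = ifelse(common, "common", "rare"),
             stringsAsFactors = FALSE)
}

#' Simulate one agent playing the two-step task
#'
#' The agent chooses by the hybrid model's own choice rules (first-stage
#' softmax over model-based + model-free values with perseveration and bias;
#' second-stage softmax) and learns by the same SARSA(lambda = 1) updates
#' used in the likelihood, while the environment transitions stochastically
#' and the four payoff probabilities drift every trial.
#'
#' @param params an [rl_params()] set.
#' @param config a [study_config()]; determines trial count, drift SD and
#'   boundaries.
#' @return a validated two-step trial data.frame of
#'   `config$n_twostep_trials` rows.
#' @export
simulate_twostep_session <- function(params, config = study_config(1)) {
  n <- config$n_twostep_trials
  alpha <- stats::plogis(params$alpha_raw)
  # payoff probabilities for (state A: a0, a1, state B: a0, a1)
  pay <- stats::runif(4, config$drift_lo, config$drift_hi)
  q <- q_init()
  prev_a1 <- NA
  out <- data.frame(trial = seq_len(n), a1 = NA_integer_,
                    transition = NA_character_, s2 = NA_character_,
                    a2 = NA_integer_, reward = NA_integer_)
  for (t in seq_len(n)) {
    p1 <- stage1_choice_prob(q, prev_a1, params)
    a1 <- as.integer(stats::runif(1) < p1[2L])
    tr <- sample_transition(a1)
    s2 <- match(tr$s2, c("A", "B"))          # 1 = A, 2 = B
    p2 <- stage2_choice_prob(q, s2, params$beta2)
    a2 <- as.integer(stats::runif(1) < p2[2L])
    pr <- pay[(s2 - 1L) * 2L + a2 + 1L]
    r <- as.integer(stats::runif(1) < pr)
    out$a1[t] <- a1; out$s2[t] <- tr$s2; out$transition[t] <- tr$transition
    out$a2[t] <- a2; out$reward[t] <- r
    q <- mf_learn(q, a1, s2, a2, r, alpha)
    q <- decay_unchosen(q, a1, s2, a2, alpha)
    q$count_diff <- update_transition_evidence(q$count_diff, a1, s2)
    prev_a1 <- a1
    pay <- step_payoff_drift(pay, config)
  }
  validate_twostep(out)
}

#' Initialize / advance the adaptive staircase
#'
#' Session-1 staircase over the immediate offer: the first "now" offer is
#' half the later amount ($500) with a $250 step. Choosing "later" raises
#' the next now offer by the current step, choosing "now" lowers it, and the
#' step halves after every trial ($250, $125, $62.50, ...), bisecting toward
#' the indifference point.
#'
#' @param state list with `now` (current offer), `step` (increment to apply
#'   after the current choice) and `trial` (1-based trial within the block).
#' @param choice `"now"` or `"later"`.
#' @return `staircase_init()`: the initial state; `staircase_next()`: the
#'   state for the following trial.
#' @export
staircase_init <- function() {
  list(now = 500, step = 250, trial = 1L)
}

#' @rdname staircase_init
#' @export
staircase_next <- function(state, choice) {
  stopifnot(choice %in% c("now", "later"))
  now <- state$now + if (choice == "later") state$step else -state$step
  list(now = now, step = state$step / 2, trial = state$trial + 1L)
}

#' Session-2 offer schedule around a session-1 reference point
#'
#' The second session probes the neighbourhood of the indifference estimate:
#' the reference is the now amount after the final session-1 update for the
#' delay, and three offers are placed above and three below it, in
#' consecutive bins of width `bin_width` with uniform jitter inside each
#' bin. Near the ceiling (reference above $970, three default bin widths
#' from $1,000) the above-bin width shrinks to `(1000 - reference)/3`, and
#' near the floor (below $30) the below-bin width shrinks to `reference/3`,
#' so all offers remain strictly inside (0, 1000).
#'
#' @param reference_now session-1 reference now amount, in (0, 1000).
#' @param bin_width default bin width in USD.
#' @return sorted numeric vector of 6 offers, 3 below and 3 above the
#'   reference.
#' @export
session2_offers <- function(reference_now, bin_width = 10) {
  if (reference_now <= 0 || reference_now >= 1000)
    stop("reference_now must lie strictly inside (0, 1000)")
  w_above <- if (reference_now > 1000 - 3 * bin_width)
    (1000 - reference_now) / 3 else bin_width
  w_below <- if (reference_now < 3 * bin_width)
    reference_now / 3 else bin_width
  u <- stats::runif(6)
  above <- reference_now + (0:2) * w_above + u[1:3] * w_above
  below <- reference_now - (0:2) * w_below - u[4:6] * w_below
  sort(c(below, above))
}

#' Simulate intertemporal choice sessions for one agent
#'
#' Session 1: the six delays in pseudo-random order, six staircase trials
#' each, with the agent's choices drawn from the discounting model's softmax
#' probabilities. For a study with two ITC sessions, a second session of 36
#' trials (six per delay, via [session2_offers()] around the final session-1
#' now amount for that delay) is appended in shuffled order.
#'
#' @param k,theta discounting parameters of the agent.
#' @param fn discount function, `"hyper"` or `"exp"`.
#' @param config a [study_config()]; `itc_sessions` selects 1 or 2 sessions.
#' @return a validated ITC trial data.frame (36 rows per session).
#' @export
simulate_itc_sessions <- function(k, theta, fn = c("hyper", "exp"),
                                  config = study_config(2)) {
  fn <- match.arg(fn)
  sched <- delay_schedule()
  order1 <- sample.int(6)
  rows <- list()
  refs <- numeric(6)                     # final updated now amount per delay
  for (d in order1) {
    D <- sched$frac[d]
    st <- staircase_init()
    for (i in 1:6) {
      pl <- choice_prob_later(st$now, 1000, D, k, theta, fn)
      choice <- if (stats::runif(1) < pl) "later" else "now"
      rows[[length(rows) + 1L]] <- data.frame(
        session = 1L, delay_label = sched$label[d], delay_frac = D,
        now_amount = st$now, later_amount = 1000, choice = choice,
        stringsAsFactors = FALSE)
      st <- staircase_next(st, choice)
    }
    refs[d] <- st$now
  }
  if (config$itc_sessions >= 2L) {
    offers <- lapply(1:6, function(d) {
      data.frame(session = 2L, delay_label = sched$label[d],
                 delay_frac = sched$frac[d],
                 now_amount = session2_offers(refs[d]), later_amount = 1000,
                 choice = NA_character_, stringsAsFactors = FALSE)
    })
    s2 <- do.call(rbind, offers)
    s2 <- s2[sample.int(nrow(s2)), , drop = FALSE]  # shuffled across delays
    pl <- choice_prob_later(s2$now_amount, 1000, s2$delay_frac, k, theta, fn)
    s2$choice <- ifelse(stats::runif(nrow(s2)) < pl, "later", "now")
    rows[[length(rows) + 1L]] <- s2
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_itc(out)
}

# draw n values from a half-Gaussian on [0, Inf) with location mu, scale sd
rhalfnorm <- function(n, mu, sd) {
  stats::qnorm(stats::runif(n, stats::pnorm(0, mu, sd), 1), mu, sd)
}

#' Generate a synthetic population with known ground truth
#'
#' Draws subject-level parameters from a [group_spec()], couples the
#' model-based and model-free weights to the z-scored (identity- or
#' log-transformed, matching the group distribution) discount rate with
#' slopes `omega_mb`/`omega_mf`, and simulates both tasks for every subject.
#' The z-scoring standardizes `f(k)` across the realized sample, mirroring
#' the convention used at inference.
#'
#' Each subject's tasks are simulated under an independent substream derived
#' from the master seed, so datasets are reproducible subject by subject.
#'
#' @param n number of subjects.
#' @param group a [group_spec()].
#' @param configs a single [study_config()] or a list of them; subjects are
#'   split across configs as evenly as possible, in order.
#' @param fn discount function used by the generating agents.
#' @param seed master seed (integer).
#' @return list with `datasets` (named list of [subject_dataset()]) and
#'   `truth` (data.frame of the generating subject-level parameters,
#'   including `z`, the standardized discount covariate).
#' @export
generate_population <- function(n, group = group_spec(),
                                configs = study_config(2),
                                fn = c("hyper", "exp"), seed = 1) {
  fn <- match.arg(fn)
  stopifnot(n >= 1)
  if (inherits(configs, "study_config")) configs <- list(configs)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  k <- if (group$group_dist == "lognormal") {
    stats::rlnorm(n, group$mu_k, group$sigma_k)
  } else {
    rhalfnorm(n, group$mu_k, group$sigma_k)
  }
  fk <- if (group$group_dist == "lognormal") log(k) else k
  z <- if (n >= 2 && stats::sd(fk) > 0) (fk - mean(fk)) / stats::sd(fk)
       else rep(0, n)
  theta <- rhalfnorm(n, group$mu_theta, group$sigma_theta)
  alpha_raw <- stats::rnorm(n, group$mu_alpha, group$sigma_alpha)
  beta_mb <- stats::rnorm(n, group$mu_mb + group$omega_mb * z, group$sigma_mb)
  beta_mf <- stats::rnorm(n, group$mu_mf + group$omega_mf * z, group$sigma_mf)
  beta2 <- stats::rnorm(n, group$mu_beta2, group$sigma_beta2)
  p <- stats::rnorm(n, group$mu_p, group$sigma_p)
  beta_bias <- stats::rnorm(n, 0, group$sigma_bias)
  # split subjects across configs evenly, in blocks
  sizes <- diff(round(seq(0, n, length.out = length(configs) + 1)))
  cfg_idx <- rep(seq_along(configs), times = sizes)
  ids <- sprintf("s%03d", seq_len(n))
  datasets <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    cfg <- configs[[cfg_idx[i]]]
    pars <- rl_params(alpha_raw[i], beta_mb[i], beta_mf[i], beta2[i], p[i],
                      beta_bias[i])
    ts <- simulate_twostep_session(pars, cfg)
    itc <- simulate_itc_sessions(k[i], theta[i], fn, cfg)
    datasets[[i]] <- subject_dataset(ids[i], cfg, twostep = ts, itc = itc)
  }
  names(datasets) <- ids
  truth <- data.frame(subject_id = ids,
                      study = vapply(cfg_idx, function(j) configs[[j]]$study_id, 1L),
                      alpha_raw = alpha_raw, alpha = stats::plogis(alpha_raw),
                      beta_mb = beta_mb, beta_mf = beta_mf, beta2 = beta2,
                      p = p, beta_bias = beta_bias, k = k, theta = theta,
                      z = z, stringsAsFactors = FALSE)
  list(datasets = datasets, truth = truth,
       settings = list(n = n, group = unclass(group), fn = fn, seed = seed))
}
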