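# Unit behaviour of the hybrid two-step likelihood components.

test_that("fresh learner starts at the 0.5 baseline with neutral evidence", {
  q <- q_init()
  expect_equal(q$Q, matrix(0.5, 3, 2))
  expect_identical(q$count_diff, 0L)
})

test_that("SARSA updates match hand algebra and the lambda=1 closed form", {
  # worked example: all values 0.5, reward 1, alpha 0.2 -> both chosen
  # values move to 0.6
  q <- q_init()
  q <- mf_learn(q, a1 = 0, s2 = 1, a2 = 1, reward = 1, alpha = 0.2)
  expect_equal(q$Q[2, 2], 0.6)
  expect_equal(q$Q[1, 1], 0.6)
  # alpha = 0 leaves everything untouched
  q0 <- mf_learn(q_init(), 1, 2, 0, 1, alpha = 0)
  expect_equal(q0$Q, matrix(0.5, 3, 2))
  expect_error(mf_learn(q_init(), 0, 1, 0, 1, alpha = 1.5), "alpha")
  # net stage-1 update collapses to (1 - alpha) Q1 + alpha r at lambda = 1,
  # for random states, against the explicit trace computation
  set.seed(11)
  for (rep in 1:200) {
    q <- q_init()
    q$Q[] <- runif(6)
    a1 <- sample(0:1, 1); s2 <- sample(1:2, 1); a2 <- sample(0:1, 1)
    r <- sample(0:1, 1); al <- runif(1)
    q1_old <- q$Q[1, a1 + 1]
    q2 <- mf_learn(q, a1, s2, a2, r, al)
    expect_equal(q2$Q[1, a1 + 1], (1 - al) * q1_old + al * r, tolerance = 1e-12)
  }
})

test_that("unchosen values decay toward baseline at rate alpha", {
  q <- q_init()
  q$Q[3, 1] <- 0.9
  q2 <- decay_unchosen(q, a1 = 0, s2 = 1, a2 = 0, alpha = 0.2)
  expect_equal(q2$Q[3, 1], 0.82)          # 0.9 + 0.2 (0.5 - 0.9)
  expect_equal(q2$Q[1, 1], 0.5)           # chosen pair untouched
  q3 <- decay_unchosen(q, 0, 1, 0, alpha = 1)
  expect_equal(q3$Q[3, 1], 0.5)           # full decay
  q4 <- decay_unchosen(q_init(), 0, 1, 0, alpha = 0.7)
  expect_equal(q4$Q, matrix(0.5, 3, 2))   # at baseline already
})

test_that("transition evidence tallies consistency with the canonical map", {
  cd <- 0L
  for (i in 1:10) cd <- update_transition_evidence(cd, 0L, 1L)
  expect_identical(cd, 10L)
  cd <- update_transition_evidence(cd, 0L, 2L)   # inconsistent
  expect_identical(cd, 9L)
  # brute-force recount oracle on a random trial list
  set.seed(3)
  a1 <- sample(0:1, 60, TRUE); s2 <- sample(1:2, 60, TRUE)
  cd <- 0L
  for (t in 1:60) cd <- update_transition_evidence(cd, a1[t], s2[t])
  brute <- sum(ifelse((a1 == 0 & s2 == 1) | (a1 == 1 & s2 == 2), 1, -1))
  expect_equal(cd, brute)
})

test_that("model-based values are the veridical-probability Bellman backup", {
  q <- q_init()
  q$Q[2, ] <- c(0.8, 0.1)   # state A, max 0.8
  q$Q[3, ] <- c(0.4, 0.2)   # state B, max 0.4
  expect_equal(mb_stage1_values(q), c(0.7 * 0.8 + 0.3 * 0.4,
                                      0.7 * 0.4 + 0.3 * 0.8))
  # flipped mapping when the evidence favours the opposite assignment
  q$count_diff <- -3L
  expect_equal(mb_stage1_values(q), c(0.7 * 0.4 + 0.3 * 0.8,
                                      0.7 * 0.8 + 0.3 * 0.4))
  # equal second-stage values are invariant: convex combination
  q2 <- q_init()
  q2$Q[2:3, ] <- 0.37
  expect_equal(mb_stage1_values(q2), c(0.37, 0.37))
})

test_that("choice rules are proper softmax with perseveration and bias", {
  q <- q_init()
  expect_equal(stage1_choice_prob(q, NA, rl_params(0, 0, 0, 0, 0, 0)),
               c(0.5, 0.5))
  # strongly negative bias pushes choice onto the first action
  p1 <- stage1_choice_prob(q, NA, rl_params(0, 0, 0, 0, 0, -50))
  expect_gt(p1[1], 1 - 1e-10)
  # perseveration favours the previous action
  pr <- stage1_choice_prob(q, 1, rl_params(0, 0, 0, 0, 2, 0))
  expect_gt(pr[2], pr[1])
  expect_equal(stage2_choice_prob(q, 1, 0), c(0.5, 0.5))
  expect_equal(stage2_choice_prob(q, 2, 7.3), c(0.5, 0.5))  # equal Q values
  # probabilities sum to one and log-odds follow beta2 (Q difference)
  set.seed(21)
  for (i in 1:100) {
    q$Q[] <- runif(6); q$count_diff <- sample(-3:3, 1)
    pars <- random_rl_params()
    v1 <- stage1_choice_prob(q, sample(c(NA, 0, 1), 1), pars)
    expect_equal(sum(v1), 1, tolerance = 1e-12)
    expect_true(all(v1 > 0))
    b2 <- rnorm(1, 0, 2)
    v2 <- stage2_choice_prob(q, 2, b2)
    expect_equal(log(v2[1] / v2[2]), b2 * (q$Q[3, 1] - q$Q[3, 2]),
                 tolerance = 1e-10)
  }
})

test_that("session log-likelihood equals the scalar oracle and honours limits", {
  # all-zero weights: both stages are coin flips
  set.seed(31)
  ts <- simulate_twostep_session(rl_params(0, 0, 0, 0, 0, 0),
                                 study_config(2, n_twostep_trials = 40))
  ll0 <- rl_session_loglik(ts, rl_params(0, 0, 0, 0, 0, 0))
  expect_equal(ll0, 2 * 40 * log(0.5), tolerance = 1e-12)
  # empty session
  expect_equal(rl_session_loglik(ts[0, ], rl_params()), 0)
  # oracle equivalence on random sessions, both engines
  for (i in 1:25) {
    pars <- random_rl_params()
    ts <- simulate_twostep_session(pars, study_config(1, n_twostep_trials = 30))
    m <- discountrl:::twostep_matrix(ts)
    o <- oracle_rl_loglik(m, pars$alpha_raw, pars$beta_mb, pars$beta_mf,
                          pars$beta2, pars$p, pars$beta_bias)
    expect_equal(rl_session_loglik(ts, pars), o, tolerance = 1e-10)
    expect_equal(rl_session_loglik(ts, pars, engine = "r"), o,
                 tolerance = 1e-10)
  }
})

test_that("likelihood prefers generating parameters over permuted weights", {
  set.seed(41)
  gen <- rl_params(0.4, 2.5, 0.3, 3, 0.2, 0)
  perm <- rl_params(0.4, 0.3, 2.5, 3, 0.2, 0)  # weights swapped
  d <- replicate(30, {
    ts <- simulate_twostep_session(gen, study_config(2, n_twostep_trials = 120))
    rl_session_loglik(ts, gen) - rl_session_loglik(ts, perm)
  })
  expect_gt(mean(d), 0)
})

test_that("stay-regression rows code previous-trial events as +/-1", {
  ts <- data.frame(trial = 1:3, a1 = c(0, 0, 1),
                   transition = c("common", "rare", "common"),
                   s2 = c("A", "B", "B"), a2 = c(0, 1, 0),
                   reward = c(1, 0, 1))
  rows <- build_stay_rows(ts, discount_z = 0.3)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$stay, c(1L, 0L))
  expect_equal(rows$reward, c(1, -1))     # prev rewarded, prev unrewarded
  expect_equal(rows$common, c(1, -1))     # prev common, prev rare
  expect_equal(rows$discount_z, c(0.3, 0.3))
  # a gap in trial indices (aborted trial) breaks the pair chain
  ts$trial <- c(1, 3, 4)
  rows2 <- build_stay_rows(ts)
  expect_equal(nrow(rows2), 1)
  expect_equal(build_stay_rows(ts[1, ]), build_stay_rows(ts[0, ]))
  # row count equals a brute-force count of adjacent pairs
  set.seed(5)
  tr <- sort(sample(1:60, 35))
  ts3 <- data.frame(trial = tr, a1 = sample(0:1, 35, TRUE),
                    transition = "common", s2 = "A", a2 = 0, reward = 1)
  ts3$s2 <- ifelse(ts3$a1 == 0, "A", "B")
  expect_equal(nrow(build_stay_rows(ts3)), sum(diff(tr) == 1))
})

test_that("per-session ML estimation orders subjects by their control weights", {
  # dispersed generating grid: recovery correlations are only meaningful
  # when the true spread exceeds the per-session measurement noise.
  # Model-free weights are well identified by 200 trials; model-based
  # weights are intrinsically noisy at this session length (the planning
  # regressor is a 0.4-weighted difference of drifting value maxima), so
  # only a clearly-positive ordering is required of them.
  set.seed(77)
  n <- 20
  tb <- runif(n, 0, 5); tmf <- runif(n, 0, 5)
  eb <- emf <- numeric(n)
  for (i in 1:n) {
    pars <- rl_params(rnorm(1, 0.5, 0.5), tb[i], tmf[i], rnorm(1, 3, 1),
                      rnorm(1, 0.2, 0.3), rnorm(1, 0, 0.3))
    ts <- simulate_twostep_session(pars, study_config(1, n_twostep_trials = 200))
    f <- rl_mle(ts)
    eb[i] <- f$params$beta_mb
    emf[i] <- f$params$beta_mf
  }
  expect_gt(cor(tmf, emf, method = "spearman"), 0.7)
  expect_gt(cor(tb, eb, method = "spearman"), 0.35)
})
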