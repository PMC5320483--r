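test_that("payoff drift reflects into the study boundaries", {
  cfg <- study_config(1)
  # zero-noise stream leaves the state unchanged
  cfg0 <- study_config(1, drift_sd = 0)
  p <- c(0.3, 0.5, 0.7, 0.44)
  expect_equal(step_payoff_drift(p, cfg0), p)
  # reflection arithmetic at the boundary: 0.8 + 0.03 reflects to 0.77
  expect_equal(2 * cfg$drift_hi - (0.8 + 0.03), 0.77)
  # long-run containment for all four walks
  set.seed(2)
  p <- rep(0.5, 4)
  lo <- 1; hi <- 0
  for (i in 1:10000) {
    p <- step_payoff_drift(p, cfg)
    lo <- min(lo, p); hi <- max(hi, p)
  }
  expect_gte(lo, cfg$drift_lo)
  expect_lte(hi, cfg$drift_hi)
})

test_that("transition sampler respects the fixed map at 0.7/0.3", {
  set.seed(4)
  tr <- sample_transition(rep(0L, 20000))
  expect_true(all(tr$s2[tr$transition == "common"] == "A"))
  expect_true(all(tr$s2[tr$transition == "rare"] == "B"))
  f <- mean(tr$transition == "common")
  expect_lt(abs(f - 0.7), 0.01)
  # matches an independent Bernoulli oracle drawing from the same stream
  set.seed(99)
  tr2 <- sample_transition(rep(1L, 500))
  set.seed(99)
  oracle_common <- runif(500) < 0.7
  expect_identical(tr2$transition == "common", unname(oracle_common))
  expect_identical(tr2$s2, ifelse(oracle_common, "B", "A"))
})

test_that("simulated two-step sessions have study-correct shape and chance behaviour at zero weights", {
  set.seed(6)
  ts <- simulate_twostep_session(rl_params(), study_config(1))
  expect_equal(nrow(ts), 201)
  expect_silent(validate_twostep(ts))
  ts2 <- simulate_twostep_session(rl_params(), study_config(2))
  expect_equal(nrow(ts2), 176)
  # flat agent chooses each first-stage action about half the time
  flat <- do.call(rbind, replicate(20, simulate_twostep_session(
    rl_params(0, 0, 0, 0, 0, 0), study_config(2)), simplify = FALSE))
  expect_lt(abs(mean(flat$a1) - 0.5), 0.04)
})

test_that("a model-based agent shows the transition-sensitive switch pattern", {
  # after a rewarded trial, switching is more likely following a rare than
  # a common transition (the planner knows the opposite action leads back)
  set.seed(8)
  rows <- do.call(rbind, replicate(40, build_stay_rows(
    simulate_twostep_session(rl_params(0, 5, 0, 5, 0, 0), study_config(1))),
    simplify = FALSE))
  sw_rr <- mean(1 - rows$stay[rows$reward == 1 & rows$common == -1])
  sw_rc <- mean(1 - rows$stay[rows$reward == 1 & rows$common == 1])
  expect_gt(sw_rr, sw_rc)
})

test_that("staircase follows the add/subtract-then-halve schedule", {
  st <- staircase_init()
  expect_equal(st$now, 500)
  expect_equal(st$step, 250)
  expect_equal(staircase_next(st, "later")$now, 750)
  expect_equal(staircase_next(st, "now")$now, 250)
  st2 <- staircase_next(st, "later")
  expect_equal(st2$step, 125)
  st3 <- staircase_next(st2, "now")
  expect_equal(st3$step, 62.5)
  expect_equal(st3$now, 625)
  # six trials of bisection bracket a deterministic agent's indifference
  # point within the final step size
  set.seed(10)
  for (rep in 1:20) {
    k <- exp(runif(1, log(0.2), log(4)))
    D <- sample(delay_schedule()$frac, 1)
    ip <- 1000 / (1 + k * D)
    st <- staircase_init()
    for (i in 1:6) {
      choice <- if (ip > st$now) "later" else "now"
      st <- staircase_next(st, choice)
    }
    expect_lt(abs(st$now - ip), 1000 / 2^6)
  }
})

test_that("session-2 offers bracket the reference in jittered bins", {
  set.seed(12)
  off <- session2_offers(500)
  expect_length(off, 6)
  expect_false(is.unsorted(off))
  expect_equal(sum(off > 500), 3)
  expect_equal(sum(off < 500), 3)
  expect_true(all(off > 470 & off < 530))
  # ceiling: bin width shrinks to (1000 - ref)/3 so offers stay below $1,000
  for (i in 1:50) {
    hi <- session2_offers(985)
    expect_true(all(hi < 1000 & hi > 0))
    lo <- session2_offers(12)
    expect_true(all(lo > 0 & lo < 1000))
  }
  expect_error(session2_offers(1000), "inside")
  expect_error(session2_offers(0), "inside")
})

test_that("simulated ITC sessions have the blocked staircase structure", {
  set.seed(14)
  itc <- simulate_itc_sessions(1, 0.08, "hyper", study_config(2))
  expect_equal(nrow(itc), 36)
  expect_true(all(itc$session == 1))
  counts <- table(itc$delay_label)
  expect_true(all(counts == 6))
  # every block opens at half the later amount
  first <- itc[!duplicated(itc$delay_label), ]
  expect_true(all(first$now_amount == 500))
  # study 1 appends a 36-trial second session
  itc2 <- simulate_itc_sessions(1, 0.08, "hyper", study_config(1))
  expect_equal(table(itc2$session), table(factor(rep(c(1, 2), each = 36))),
               ignore_attr = TRUE)
  expect_silent(validate_itc(itc2))
})

test_that("population generation is seed-reproducible with faithful truth table", {
  g <- group_spec(omega_mb = 0.5, sigma_mb = 0.5)
  p1 <- generate_population(6, g, study_config(2, n_twostep_trials = 15), seed = 33)
  p2 <- generate_population(6, g, study_config(2, n_twostep_trials = 15), seed = 33)
  expect_identical(p1$datasets, p2$datasets)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_population(6, g, study_config(2, n_twostep_trials = 15), seed = 34)
  expect_false(identical(p1$datasets, p3$datasets))
  # z column is the standardized f(k) of the realized sample
  expect_equal(mean(p1$truth$z), 0, tolerance = 1e-12)
  expect_equal(sd(p1$truth$z), 1, tolerance = 1e-12)
})

test_that("coupling in the generator induces (only) the requested correlation", {
  g0 <- group_spec(omega_mb = 0, omega_mf = 0)
  p0 <- generate_population(500, g0, study_config(2, n_twostep_trials = 2), seed = 55)
  expect_lt(abs(cor(p0$truth$z, p0$truth$beta_mb)), 0.1)
  g1 <- group_spec(omega_mb = 0.5, sigma_mb = 0.2)
  p1 <- generate_population(500, g1, study_config(2, n_twostep_trials = 2), seed = 56)
  expect_gt(cor(p1$truth$z, p1$truth$beta_mb), 0.5)
  # lognormal group distribution yields positive k and log-scale covariate
  g2 <- group_spec(group_dist = "lognormal", mu_k = 0, sigma_k = 1)
  p2 <- generate_population(200, g2, study_config(2, n_twostep_trials = 2), seed = 57)
  expect_true(all(p2$truth$k > 0))
  expect_equal(p2$truth$z, zscore_covariate(log(p2$truth$k)), tolerance = 1e-12)
})
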