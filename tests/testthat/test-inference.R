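make_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      pop <- make_cohort(n = 6, seed = 81, n_trials = 25)
      model <- build_joint_model(model_config("rl", "hyper", "normal",
                                              "combined"), pop$datasets)
      fit <<- fit_model(model, n_chains = 3, n_iter = 400, n_warmup = 200,
                        seed = 9)
    }
    fit
  }
})

test_that("fits have the promised draw geometry and are seed-reproducible", {
  fit <- make_fit()
  expect_equal(dim(fit$draws)[1], 200)   # retained iterations per chain
  expect_equal(dim(fit$draws)[3], 3)
  expect_equal(fit$meta$n_retained, 3 * (400 - 200))
  expect_true(all(c("omega_mb", "sigma_mb", "mu_theta", "k[1]", "theta[6]")
                  %in% fit$par_names))
  # natural-scale positivity of transformed parameters
  expect_true(all(extract_par(fit, "sigma_mb") > 0))
  expect_true(all(extract_par(fit, "k[3]") > 0))
  pop <- make_cohort(n = 6, seed = 81, n_trials = 25)
  model <- build_joint_model(model_config("rl", "hyper", "normal",
                                          "combined"), pop$datasets)
  fit2 <- fit_model(model, n_chains = 3, n_iter = 400, n_warmup = 200,
                    seed = 9)
  expect_identical(fit$draws, fit2$draws)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(91)
  # well-mixed: iid draws in every chain
  good <- matrix(rnorm(4 * 5000), ncol = 4)
  expect_lt(rhat(good), 1.01)
  # chains identical sequences: statistic stays at 1
  same <- matrix(rep(rnorm(5000), 4), ncol = 4)
  expect_lt(rhat(same), 1.005)
  # chains at different levels: between-chain variance dominates; check
  # against the textbook formula computed directly
  bad <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  r <- rhat(bad, split = FALSE)
  expect_gt(r, 5)
  n <- 1000
  W <- mean(apply(bad, 2, var))
  B <- n * var(colMeans(bad))
  expect_equal(r, sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)
  # invariant under a common affine transform
  expect_equal(rhat(3 * bad - 7), rhat(bad), tolerance = 1e-10)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  # non-stationarity is caught by the split variant only
  drift <- matrix(c(seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.05),
                    seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.05)),
                  ncol = 2)
  expect_gt(rhat(drift, split = TRUE), rhat(drift, split = FALSE))
})

test_that("posterior summaries use linear-interpolation percentiles", {
  fit <- make_fit()
  # convention check on a known sequence
  x <- 1:100
  expect_equal(unname(quantile(x, c(0.025, 0.5, 0.975), type = 7)),
               c(3.475, 50.5, 97.525))
  s <- summarize_draws(fit, c("mu_mf", "omega_mb"))
  d <- extract_par(fit, "mu_mf")
  expect_equal(s$median[1], unname(quantile(d, 0.5, type = 7)))
  expect_equal(s$ci_low[1], unname(quantile(d, 0.025, type = 7)))
  expect_equal(s$ci_high[1], unname(quantile(d, 0.975, type = 7)))
  expect_true(all(s$ci_low <= s$median & s$median <= s$ci_high))
  # constant draws collapse the interval
  expect_equal(unname(discountrl:::.summ_one(rep(2.5, 50))), rep(2.5, 3))
})

test_that("differential effect summarizes the draw-wise coupling difference", {
  fit <- make_fit()
  d <- extract_par(fit, "omega_mb") - extract_par(fit, "omega_mf")
  de <- differential_effect(fit)
  expect_equal(de$median, unname(quantile(d, 0.5, type = 7)))
  expect_equal(de$ci_low, unname(quantile(d, 0.025, type = 7)))
  expect_equal(de$ci_high, unname(quantile(d, 0.975, type = 7)))
})

test_that("engagement filter applies the interval rule per subject", {
  ci <- rbind(
    data.frame(subject_id = "a", param = c("beta_mb", "beta_mf", "beta2"),
               ci_low = c(-1, 0.5, -2), ci_high = c(1, 1.2, 2)),
    data.frame(subject_id = "b", param = c("beta_mb", "beta_mf", "beta2"),
               ci_low = c(-1, -1, -1), ci_high = c(1, 1, 1)),
    data.frame(subject_id = "c", param = c("beta_mb", "beta_mf", "beta2"),
               ci_low = c(-3, -2, -1.5), ci_high = c(-0.5, 2, 2)))
  res <- engagement_filter(ci)
  expect_setequal(res$retained, c("a", "c"))   # b spans 0 on all three
  expect_equal(res$n_total, 3)
  lit <- engagement_filter(ci, literal = TRUE)
  expect_setequal(lit$retained, c("a", "b", "c"))
  # brute-force re-evaluation of the rule on the stored intervals
  brute <- unique(ci$subject_id[ci$ci_low > 0 | ci$ci_high < 0])
  expect_setequal(res$retained, brute)
  expect_error(engagement_filter(ci[ci$param != "beta2", ]), "beta2")
})

test_that("subject-level intervals line up with their draws", {
  fit <- make_fit()
  tab <- subject_intervals(fit)
  expect_equal(nrow(tab), 6 * 3)
  d <- extract_par(fit, "beta_mf[2]")
  row <- tab[tab$subject_id == fit$meta$subject_ids[2] &
               tab$param == "beta_mf", ]
  expect_equal(row$median, unname(quantile(d, 0.5, type = 7)))
  expect_equal(row$ci_low, unname(quantile(d, 0.025, type = 7)))
})
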