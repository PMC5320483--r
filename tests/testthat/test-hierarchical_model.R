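test_that("z-scoring standardizes and is affine-invariant", {
  expect_equal(zscore_covariate(c(1, 3)), c(-sqrt(2) / 2, sqrt(2) / 2))
  set.seed(61)
  x <- rnorm(40, 3, 2)
  z <- zscore_covariate(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_covariate(5 * x - 2), z, tolerance = 1e-10)
  expect_error(zscore_covariate(rep(2, 5)), "zero variance")
  expect_error(zscore_covariate(3), "at least 2")
})

test_that("coupled subject means shift by omega times the covariate", {
  g <- group_spec(mu_mb = 2, omega_mb = 0.3, mu_mf = 1, omega_mf = -0.2)
  z <- c(-1, 0, 1)
  m <- subject_weight_means(g, z)
  expect_equal(m$beta_mb, c(1.7, 2, 2.3))
  expect_equal(m$beta_mf, c(1.2, 1, 0.8))
  # mean of subject means recovers the group mean because mean(z) = 0
  set.seed(62)
  z2 <- zscore_covariate(rnorm(30))
  expect_equal(mean(subject_weight_means(g, z2)$beta_mb), g$mu_mb,
               tolerance = 1e-10)
  g0 <- group_spec(omega_mb = 1e-12)
  expect_equal(subject_weight_means(g0, z2)$beta_mb, rep(g0$mu_mb, 30),
               tolerance = 1e-9)
})

test_that("joint density is finite for all 8 variants and matches the scalar oracle", {
  pop <- make_cohort(n = 4, seed = 63, n_trials = 20,
                     configs = study_config(1, n_twostep_trials = 20))
  variants <- model_variants()
  for (v in seq_len(nrow(variants))) {
    cfg <- model_config(variants$twostep_form[v], variants$discount_fn[v],
                        variants$group_dist[v], "combined")
    model <- build_joint_model(cfg, pop$datasets)
    set.seed(100 + v)
    th <- discountrl:::init_state(model) + rnorm(model$n_par, 0, 0.2)
    ld <- joint_log_density(model, th)
    expect_true(is.finite(ld))
    expect_equal(ld, oracle_joint_logdensity(model, th), tolerance = 1e-8)
  }
})

test_that("density decomposes: dropping the coupling changes only its prior terms", {
  pop <- make_cohort(n = 5, seed = 64, n_trials = 20)
  model <- build_joint_model(model_config("rl", "hyper", "normal", "combined"),
                             pop$datasets)
  set.seed(65)
  th <- discountrl:::init_state(model) + rnorm(model$n_par, 0, 0.1)
  names(th) <- model$par_names
  th0 <- th
  th0[c("omega_mb", "omega_mf")] <- 0
  # with omega = 0 the coupled prior means lose their z shift; rebuilding
  # the difference from the oracle's own terms must match the density change
  expect_equal(joint_log_density(model, th) - joint_log_density(model, th0),
               oracle_joint_logdensity(model, th) -
                 oracle_joint_logdensity(model, th0),
               tolerance = 1e-8)
})

test_that("partitions filter subjects by study and validate inputs", {
  pop <- make_cohort(n = 6, seed = 66, n_trials = 15,
                     configs = list(study_config(1, n_twostep_trials = 15),
                                    study_config(2, n_twostep_trials = 15)))
  m1 <- build_joint_model(model_config(partition = "study1"), pop$datasets)
  m2 <- build_joint_model(model_config(partition = "study2"), pop$datasets)
  mc <- build_joint_model(model_config(partition = "combined"), pop$datasets)
  expect_equal(m1$n_subjects + m2$n_subjects, mc$n_subjects)
  expect_true(all(pop$truth$study[match(m1$subject_ids,
                                        pop$truth$subject_id)] == 1))
  # a partition with too few subjects errors
  one <- pop$datasets[pop$truth$subject_id[pop$truth$study == 1][1]]
  expect_error(build_joint_model(model_config(partition = "study2"), one),
               "fewer than 2")
})

test_that("regression form drops sparse two-step subjects but keeps their ITC block", {
  pop <- make_cohort(n = 4, seed = 67, n_trials = 20)
  # subject 2 has a single two-step trial: no usable consecutive pairs
  pop$datasets[[2]]$twostep <- pop$datasets[[2]]$twostep[1, ]
  model <- build_joint_model(model_config("regression", "hyper", "normal",
                                          "combined"), pop$datasets)
  expect_equal(nrow(model$stay_list[[2]]), 0)
  expect_gt(nrow(model$stay_list[[1]]), 0)
  expect_gt(nrow(model$itc_list[[2]]), 0)
  # density still finite: the dropped block contributes zero likelihood
  set.seed(68)
  th <- discountrl:::init_state(model) + rnorm(model$n_par, 0, 0.1)
  expect_true(is.finite(joint_log_density(model, th)))
  expect_equal(joint_log_density(model, th),
               oracle_joint_logdensity(model, th), tolerance = 1e-8)
})
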