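# Assembly of the joint hierarchical model: per-subject two-step likelihood
# (stay regression or hybrid RL) + per-subject discounting likelihood +
# group-level priors + the coupling of the z-scored discount rate onto the
# decision-system weights. Eight variants (2 two-step forms x 2 discount
# functions x 2 group distributions of k) x 3 data partitions.

#' Model variant and data partition
#'
#' @param twostep_form `"rl"` (hybrid reinforcement-learning likelihood) or
#'   `"regression"` (consecutive-trial stay regression).
#' @param discount_fn `"hyper"` or `"exp"`.
#' @param group_dist group-level distribution of the discount rate:
#'   `"normal"` (half-Gaussian on \[0, Inf), z-score of k itself) or
#'   `"lognormal"` (z-score of log k).
#' @param partition `"combined"`, `"study1"` or `"study2"`.
#' @return list of class `model_config`.
#' @export
model_config <- function(twostep_form = c("rl", "regression"),
                         discount_fn = c("hyper", "exp"),
                         group_dist = c("normal", "lognormal"),
                         partition = c("combined", "study1", "study2")) {
  cfg <- list(twostep_form = match.arg(twostep_form),
              discount_fn = match.arg(discount_fn),
              group_dist = match.arg(group_dist),
              partition = match.arg(partition))
  class(cfg) <- "model_config"
  cfg
}

#' Hyperprior constants of the hierarchical model
#'
#' Group-level means carry broad Gaussian hyperpriors: N(0, 2^2) for the
#' regression coefficients and the discount-rate mean, N(0, 10^2) for the
#' softmax-weight means and theta, and N(0, 5^2) for the group learning
#' rate. Group-level SDs carry half-Cauchy(0, 2.5) priors. The coupling
#' slopes (omega) carry N(0, 2^2), matching the group-level regression
#' coefficients, and the per-subject side bias an independent N(0, 10^2).
#'
#' @param coef_mean_sd,weight_mean_sd,alpha_mean_sd,k_mean_sd,theta_mean_sd
#'   SDs of the zero-mean Gaussian hyperpriors on the group means.
#' @param sigma_scale scale of the half-Cauchy prior on group SDs.
#' @param omega_sd SD of the prior on the coupling coefficients.
#' @param bias_sd SD of the independent side-bias prior.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(coef_mean_sd = 2, weight_mean_sd = 10,
                       alpha_mean_sd = 5, k_mean_sd = 2, theta_mean_sd = 10,
                       sigma_scale = 2.5, omega_sd = 2, bias_sd = 10) {
  pr <- list(coef_mean_sd = coef_mean_sd, weight_mean_sd = weight_mean_sd,
             alpha_mean_sd = alpha_mean_sd, k_mean_sd = k_mean_sd,
             theta_mean_sd = theta_mean_sd, sigma_scale = sigma_scale,
             omega_sd = omega_sd, bias_sd = bias_sd)
  stopifnot(all(unlist(pr) > 0))
  class(pr) <- "prior_spec"
  pr
}

.prior_vector <- function(pr) {
  c(pr$coef_mean_sd, pr$weight_mean_sd, pr$alpha_mean_sd, pr$k_mean_sd,
    pr$theta_mean_sd, pr$sigma_scale, pr$omega_sd, pr$bias_sd)
}

#' Z-score a discount covariate
#'
#' Standardizes the per-subject (possibly log-transformed) discount rates to
#' sample mean 0 and sample SD 1 (denominator n - 1). Inside the model this
#' standardization is recomputed for every parameter state, i.e. per MCMC
#' draw.
#'
#' @param values numeric vector (length >= 2, finite, non-constant).
#' @return standardized vector.
#' @export
zscore_covariate <- function(values) {
  if (length(values) < 2) stop("need at least 2 subjects to z-score")
  if (any(!is.finite(values))) stop("non-finite covariate values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate covariate: zero variance")
  (values - mean(values)) / s
}

#' Coupled per-subject means of the decision-system weights
#'
#' The group means of the model-based and model-free weights are shifted per
#' subject by the coupling slopes times the standardized discount covariate:
#' `E[beta_mb_i] = mu_mb + omega_mb * z_i` (and likewise model-free).
#' Because `mean(z) = 0`, the average subject mean equals the group mean.
#'
#' @param group a [group_spec()] or any list with `mu_mb`, `omega_mb`,
#'   `mu_mf`, `omega_mf`.
#' @param z standardized discount covariate, one entry per subject.
#' @return list with numeric vectors `beta_mb` and `beta_mf`.
#' @export
subject_weight_means <- function(group, z) {
  list(beta_mb = group$mu_mb + group$omega_mb * z,
       beta_mf = group$mu_mf + group$omega_mf * z)
}

.partition_data <- function(data, partition) {
  if (partition == "combined") return(data)
  want <- if (partition == "study1") 1L else 2L
  keep <- vapply(data, function(d) d$study$study_id == want, logical(1))
  data[keep]
}

# half-Gaussian group locations (theta always, k under the normal group
# distribution) are sampled on the log scale, constraining them positive
.sampler_names <- function(form, gdist, ids) {
  mu_k_name <- if (gdist == "lognormal") "mu_k" else "log_mu_k"
  if (form == "rl") {
    grp <- c("mu_alpha", "log_sigma_alpha", "mu_mb", "log_sigma_mb",
             "omega_mb", "mu_mf", "log_sigma_mf", "omega_mf", "mu_beta2",
             "log_sigma_beta2", "mu_p", "log_sigma_p", mu_k_name,
             "log_sigma_k", "log_mu_theta", "log_sigma_theta")
    per <- c("alpha_raw", "beta_mb", "beta_mf", "beta2", "p", "beta_bias",
             "log_k", "log_theta")
  } else {
    grp <- c("mu_stay", "log_sigma_stay", "mu_reward", "log_sigma_reward",
             "mu_common", "log_sigma_common", "mu_rc", "log_sigma_rc",
             "omega_stay", "omega_mf", "omega_common", "omega_mb",
             mu_k_name, "log_sigma_k", "log_mu_theta", "log_sigma_theta")
    per <- c("b_stay", "b_reward", "b_common", "b_rc", "log_k", "log_theta")
  }
  subj <- as.vector(vapply(seq_along(ids),
                           function(i) paste0(per, "[", i, "]"),
                           character(length(per))))
  c(grp, subj)
}

#' Build a joint hierarchical model
#'
#' Packs a data partition into the likelihood-ready representation for one of
#' the eight model variants: per-subject two-step trial matrices (RL form) or
#' stay-regression designs (regression form; subjects with fewer than two
#' usable consecutive-trial pairs keep only their ITC likelihood), per-subject
#' ITC matrices, the variant flags and the hyperprior constants.
#'
#' @param config a [model_config()].
#' @param data named list of [subject_dataset()] covering the partition.
#' @param priors a [prior_spec()].
#' @return list of class `joint_model` with the data blocks, the sampler
#'   parameter names (`par_names`, group block first) and bookkeeping used by
#'   [fit_model()] and [joint_log_density()].
#' @export
build_joint_model <- function(config, data, priors = prior_spec()) {
  stopifnot(inherits(config, "model_config"), inherits(priors, "prior_spec"))
  data <- .partition_data(data, config$partition)
  if (length(data) < 2)
    stop("partition '", config$partition, "' has fewer than 2 subjects")
  if (any(vapply(data, function(d) is.null(d$itc), logical(1))))
    stop("every subject needs ITC trials for the joint model")
  ids <- names(data)
  form <- config$twostep_form
  ts_list <- lapply(data, function(d) {
    if (form != "rl" || is.null(d$twostep))
      return(matrix(integer(0), 0, 4))
    twostep_matrix(d$twostep)
  })
  stay_list <- lapply(data, function(d) {
    if (form != "regression") return(matrix(numeric(0), 0, 3))
    rows <- build_stay_rows(d$twostep)
    if (nrow(rows) < 2) return(matrix(numeric(0), 0, 3))  # drop two-step part
    cbind(rows$stay, rows$reward, rows$common)
  })
  itc_list <- lapply(data, function(d) itc_matrix(d$itc))
  par_names <- .sampler_names(form, config$group_dist, ids)
  model <- list(config = config, priors = priors, subject_ids = ids,
                n_subjects = length(ids),
                ts_list = unname(ts_list), stay_list = unname(stay_list),
                itc_list = unname(itc_list),
                form_int = as.integer(form == "rl"),
                fn_int = as.integer(config$discount_fn == "hyper"),
                gdist_int = as.integer(config$group_dist == "lognormal"),
                prior_c = .prior_vector(priors),
                par_names = par_names, n_par = length(par_names))
  class(model) <- "joint_model"
  model
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("joint model: %s + %s discounting, %s group k, partition %s\n",
              x$config$twostep_form, x$config$discount_fn,
              x$config$group_dist, x$config$partition))
  cat(sprintf("  %d subjects, %d parameters\n", x$n_subjects, x$n_par))
  invisible(x)
}

#' Joint posterior log-density
#'
#' Evaluates the full unnormalized posterior (sum of the per-subject two-step
#' and ITC log-likelihoods plus all prior terms) at a parameter state on the
#' sampler scale (group SDs as `log_sigma_*`, subject-level discount rate and
#' inverse temperature as `log_k`/`log_theta`; see `model$par_names`).
#' Includes the log-Jacobians of those log transformations, so the density is
#' with respect to the sampled coordinates.
#'
#' @param model a [build_joint_model()] result.
#' @param state numeric vector of length `model$n_par`, in `par_names` order.
#' @return scalar log-density (`-Inf` for degenerate states).
#' @export
joint_log_density <- function(model, state) {
  stopifnot(inherits(model, "joint_model"), length(state) == model$n_par)
  cpp_joint_logdensity(model$ts_list, model$stay_list, model$itc_list,
                       model$form_int, model$fn_int, model$gdist_int,
                       model$prior_c, as.numeric(state))
}

# default starting point on the sampler scale; fit_model() adds per-chain
# jitter for overdispersed initialization
init_state <- function(model) {
  lk0 <- if (model$gdist_int == 1) 0 else log(0.5)
  mu_k0 <- if (model$gdist_int == 1) 0 else log(0.5)
  if (model$form_int == 1) {
    grp <- c(0, 0, 1, 0, 0, 1, 0, 0, 1, 0, 0, log(0.5),
             mu_k0, log(0.5), log(0.05), log(0.05))
    per <- c(0, 1, 1, 1, 0, 0, lk0, log(0.05))
  } else {
    grp <- c(0.5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
             mu_k0, log(0.5), log(0.05), log(0.05))
    per <- c(0.5, 0, 0, 0, lk0, log(0.05))
  }
  stats::setNames(c(grp, rep(per, model$n_subjects)), model$par_names)
}
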