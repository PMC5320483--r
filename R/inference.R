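# Posterior sampling and diagnostics. Chains are adaptive
# Metropolis-within-Gibbs: every coordinate gets a Gaussian random-walk
# proposal whose scale adapts during warmup toward a 0.44 acceptance rate
# (the optimal rate for one-dimensional updates), then stays fixed. Chains
# run sequentially, each under its own seeded RNG stream, so fits are
# reproducible from (seed, n_chains).

#' Fit a joint hierarchical model by MCMC
#'
#' Runs independent adaptive Metropolis-within-Gibbs chains over the joint
#' posterior of a [build_joint_model()] model. Defaults mirror the reference
#' sampling configuration: 8 chains of 4,000 iterations (10,000 for the
#' regression form) with the first 1,000 discarded as warmup, retaining
#' `n_chains * (n_iter - n_warmup)` draws.
#'
#' @param model a `joint_model`.
#' @param n_chains number of chains.
#' @param n_iter iterations per chain (default 4,000 for the RL form,
#'   10,000 for the regression form).
#' @param n_warmup warmup iterations discarded from each chain (adaptation
#'   happens only here).
#' @param seed integer seed; chain c uses an RNG stream derived from it.
#' @param jitter SD of the Gaussian jitter overdispersing each chain's
#'   starting point around the default initialization.
#' @param adapt_interval,target_accept proposal-adaptation settings.
#' @return object of class `posterior_draws`: `$draws` is a 3-d array
#'   (retained iteration x parameter x chain) on the natural scale (group
#'   SDs as `sigma_*`, discount parameters as `k[i]`, `theta[i]`), `$meta`
#'   records the sampling configuration.
#' @export
fit_model <- function(model, n_chains = 8, n_iter = NULL, n_warmup = 1000,
                      seed = 1, jitter = 0.05, adapt_interval = 50,
                      target_accept = 0.44) {
  stopifnot(inherits(model, "joint_model"))
  if (is.null(n_iter))
    n_iter <- if (model$config$twostep_form == "rl") 4000 else 10000
  stopifnot(n_iter > n_warmup, n_chains >= 1)
  base_init <- init_state(model)
  keep <- (n_warmup + 1):n_iter
  nat_names <- sub("^log_", "", model$par_names)
  log_cols <- grep("^log_", model$par_names)
  draws <- array(NA_real_,
                 dim = c(length(keep), model$n_par, n_chains),
                 dimnames = list(NULL, nat_names, paste0("chain", 1:n_chains)))
  accept <- matrix(NA_real_, model$n_par, n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    init <- base_init + stats::rnorm(model$n_par, 0, jitter)
    res <- cpp_run_chain(model$ts_list, model$stay_list, model$itc_list,
                         model$form_int, model$fn_int, model$gdist_int,
                         model$prior_c, init, as.integer(n_iter),
                         as.integer(n_warmup), -1.0,
                         as.integer(adapt_interval), target_accept)
    d <- res$draws[keep, , drop = FALSE]
    if (length(log_cols)) d[, log_cols] <- exp(d[, log_cols])
    draws[, , ch] <- d
    accept[, ch] <- res$accept
  }
  structure(list(
    draws = draws,
    par_names = nat_names,
    meta = list(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
                n_retained = n_chains * (n_iter - n_warmup), seed = seed,
                config = model$config, subject_ids = model$subject_ids,
                mean_accept = rowMeans(accept))),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior draws: %d chains x %d retained iterations, %d parameters (%d total draws)\n",
              x$meta$n_chains, dim(x$draws)[1], dim(x$draws)[2],
              x$meta$n_retained))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param fit a `posterior_draws` object.
#' @param par parameter name (natural scale, e.g. `"omega_mb"` or
#'   `"beta_mb[3]"`).
#' @param pooled pool chains into one vector (default) or keep an
#'   iteration x chain matrix.
#' @return numeric vector or matrix.
#' @export
extract_par <- function(fit, par, pooled = TRUE) {
  if (!par %in% fit$par_names) stop("unknown parameter: ", par)
  m <- fit$draws[, par, ]
  if (is.null(dim(m))) m <- matrix(m, ncol = dim(fit$draws)[3])
  if (pooled) as.vector(m) else m
}

.rhat_matrix <- function(m, split = TRUE) {
  if (ncol(m) < 2) stop("R-hat needs at least 2 chains")
  if (split) {
    n2 <- floor(nrow(m) / 2)
    m <- cbind(m[seq_len(n2), , drop = FALSE],
               m[(nrow(m) - n2 + 1):nrow(m), , drop = FALSE])
  }
  if (ncol(m) < 2) stop("R-hat needs at least 2 chains")
  if (nrow(m) < 2) stop("R-hat needs at least 2 draws per chain")
  W <- mean(apply(m, 2, stats::var))
  if (W == 0) return(1)  # constant draws: nothing to diagnose
  n <- nrow(m)
  B <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Potential scale reduction (R-hat)
#'
#' Between/within-chain variance diagnostic. The default is the split form
#' (each chain halved before comparison), which also detects
#' non-stationarity within chains; `split = FALSE` gives the classic
#' statistic. A fit is conventionally accepted when R-hat < 1.1 for all
#' monitored parameters.
#'
#' @param fit a `posterior_draws` object, or an iteration x chain matrix.
#' @param pars parameters to compute (default all).
#' @param split use split chains (default `TRUE`).
#' @return named numeric vector of R-hat values.
#' @export
rhat <- function(fit, pars = NULL, split = TRUE) {
  if (is.matrix(fit)) return(.rhat_matrix(fit, split))
  stopifnot(inherits(fit, "posterior_draws"))
  if (is.null(pars)) pars <- fit$par_names
  vapply(pars, function(p) .rhat_matrix(extract_par(fit, p, pooled = FALSE),
                                        split), numeric(1))
}

#' Convergence gate on the group-level parameters
#'
#' Computes both the split and the classic R-hat for every group-level
#' (non-subject-indexed) parameter and applies the threshold to the stricter
#' (larger) of the two.
#'
#' @param fit a `posterior_draws` object.
#' @param threshold flag parameters with R-hat at or above this (default 1.1).
#' @return list with `ok` (logical), `rhat` (named vector, stricter variant)
#'   and `flagged` (names failing the gate).
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  group_pars <- grep("\\[", fit$par_names, invert = TRUE, value = TRUE)
  r <- pmax(rhat(fit, group_pars, split = TRUE),
            rhat(fit, group_pars, split = FALSE))
  list(ok = all(r < threshold), rhat = r, flagged = names(r)[r >= threshold])
}

.summ_one <- function(x, prob = 0.95) {
  a <- (1 - prob) / 2
  q <- stats::quantile(x, c(0.5, a, 1 - a), names = FALSE, type = 7)
  c(median = q[1], ci_low = q[2], ci_high = q[3])
}

#' Posterior summaries: median and central credible interval
#'
#' Equal-tailed interval from linear-interpolation (type 7) percentiles, so
#' summaries are bit-reproducible given the draws.
#'
#' @param fit a `posterior_draws` object.
#' @param pars parameters to summarize (default: the group-level block).
#' @param prob interval mass (default 0.95).
#' @return data.frame with `param`, `median`, `ci_low`, `ci_high`, `rhat`
#'   (split form).
#' @export
summarize_draws <- function(fit, pars = NULL, prob = 0.95) {
  if (is.null(pars))
    pars <- grep("\\[", fit$par_names, invert = TRUE, value = TRUE)
  s <- t(vapply(pars, function(p) .summ_one(extract_par(fit, p), prob),
                numeric(3)))
  data.frame(param = pars, median = s[, 1], ci_low = s[, 2], ci_high = s[, 3],
             rhat = rhat(fit, pars), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential effect of discount rate on model-based vs model-free control
#'
#' Summary of the draw-wise difference `omega_mb - omega_mf`, the specific
#' influence of discount rate on model-based control over and above its
#' effect on model-free control.
#'
#' @param fit a `posterior_draws` object containing `omega_mb` and
#'   `omega_mf`.
#' @param prob interval mass.
#' @return one-row data.frame (`param = "omega_diff"`).
#' @export
differential_effect <- function(fit, prob = 0.95) {
  d <- extract_par(fit, "omega_mb") - extract_par(fit, "omega_mf")
  s <- .summ_one(d, prob)
  data.frame(param = "omega_diff", median = s[1], ci_low = s[2],
             ci_high = s[3], row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subject credible intervals of the decision-system weights
#'
#' Builds the table consumed by [engagement_filter()]: for each subject of an
#' RL-form fit, the posterior median and 95% CI of `beta_mb`, `beta_mf` and
#' `beta2`.
#'
#' @param fit a `posterior_draws` object from an RL-form model.
#' @param params subject-level parameters to tabulate.
#' @param prob interval mass.
#' @return data.frame with `subject_id`, `param`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
subject_intervals <- function(fit, params = c("beta_mb", "beta_mf", "beta2"),
                              prob = 0.95) {
  ids <- fit$meta$subject_ids
  rows <- lapply(seq_along(ids), function(i) {
    do.call(rbind, lapply(params, function(p) {
      nm <- sprintf("%s[%d]", p, i)
      s <- .summ_one(extract_par(fit, nm), prob)
      data.frame(subject_id = ids[i], param = p, median = s[1],
                 ci_low = s[2], ci_high = s[3], stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Task-engagement filter on subject-level intervals
#'
#' Screens out subjects whose two-step behaviour is indistinguishable from
#' disengagement. The default rule retains a subject when at least one of the
#' three decision-weight CIs (`beta_mb`, `beta_mf`, `beta2`) excludes 0 —
#' i.e. the subject demonstrably used some decision system at some stage.
#' `literal = TRUE` applies the opposite published wording (retain when at
#' least one CI includes 0); both rules are reported by their name so
#' analyses can state which was used.
#'
#' @param ci_table output of [subject_intervals()] (columns `subject_id`,
#'   `param`, `ci_low`, `ci_high` over the three weights).
#' @param literal apply the literal "includes 0" wording instead of the
#'   engagement-intent rule.
#' @return list with `retained` (subject ids), `n_retained`, `n_total` and
#'   `rule`.
#' @export
engagement_filter <- function(ci_table, literal = FALSE) {
  need <- c("beta_mb", "beta_mf", "beta2")
  if (!all(need %in% ci_table$param))
    stop("ci_table must cover beta_mb, beta_mf and beta2")
  ci_table <- ci_table[ci_table$param %in% need, , drop = FALSE]
  excl0 <- ci_table$ci_low > 0 | ci_table$ci_high < 0
  keep_by <- tapply(if (literal) !excl0 else excl0, ci_table$subject_id, any)
  retained <- names(keep_by)[keep_by]
  list(retained = retained, n_retained = length(retained),
       n_total = length(keep_by),
       rule = if (literal) "literal: some CI includes 0"
              else "engagement: some CI excludes 0")
}
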