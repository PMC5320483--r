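# Exponential and hyperbolic discounting likelihoods for the intertemporal
# choice task. Utilities are kept in raw dollars, so the softmax inverse
# temperature theta has units 1/USD. The delay D is scaled to the maximum
# available (one year), so the discount rate k is per scaled year.

#' Discounted value of a delayed amount
#'
#' Exponential discounting `A * exp(-k * D)` or hyperbolic discounting
#' `A / (1 + k * D)`, with `D` the delay as a fraction of one year.
#'
#' @param A amount (USD), positive.
#' @param D delay in scaled years, in \[0, 1\].
#' @param k discount rate, non-negative.
#' @param fn `"hyper"` or `"exp"`.
#' @return discounted value, vectorized over the inputs.
#' @export
discounted_value <- function(A, D, k, fn = c("hyper", "exp")) {
  fn <- match.arg(fn)
  if (any(A <= 0)) stop("amount A must be positive")
  if (any(k < 0)) stop("discount rate k must be non-negative")
  if (any(D < 0 | D > 1)) stop("scaled delay D must be in [0, 1]")
  if (fn == "hyper") A / (1 + k * D) else A * exp(-k * D)
}

#' Probability of choosing the later option
#'
#' Softmax (logistic) choice between the immediate amount, valued at face
#' value (its delay is 0), and the discounted later amount:
#' `P(later) = logistic(theta * (discounted_value(later, D, k) - now))`.
#'
#' @param now immediate amount (USD).
#' @param later delayed amount (USD), $1,000 in the task.
#' @param D scaled delay of the later option.
#' @param k discount rate.
#' @param theta inverse temperature (1/USD), non-negative.
#' @param fn discount function, `"hyper"` or `"exp"`.
#' @return probability in (0, 1), vectorized.
#' @export
choice_prob_later <- function(now, later, D, k, theta, fn = c("hyper", "exp")) {
  fn <- match.arg(fn)
  if (any(theta < 0)) stop("theta must be non-negative")
  stats::plogis(theta * (discounted_value(later, D, k, fn) - now))
}

# internal ITC matrix: columns D, now, later, choice (1 = later, 0 = now)
itc_matrix <- function(trials) {
  if (is.matrix(trials)) return(trials)
  cbind(D = trials$delay_frac, now = trials$now_amount,
        later = trials$later_amount,
        choice = as.numeric(trials$choice == "later"))
}

#' Log-likelihood of an intertemporal choice session
#'
#' Sum of log choice probabilities of the observed now/later choices under a
#' two-parameter discounting model.
#'
#' @param trials validated ITC table (data.frame) or internal matrix with
#'   columns `D`, `now`, `later`, `choice` (1 = later).
#' @param k,theta model parameters (both non-negative).
#' @param fn discount function.
#' @param engine `"cpp"` (compiled, used by the sampler) or `"r"` (scalar
#'   per-trial reference).
#' @return scalar log-likelihood (0 for an empty session).
#' @export
itc_session_loglik <- function(trials, k, theta, fn = c("hyper", "exp"),
                               engine = c("cpp", "r")) {
  fn <- match.arg(fn)
  engine <- match.arg(engine)
  m <- itc_matrix(trials)
  if (nrow(m) == 0) return(0)
  if (engine == "cpp") {
    return(cpp_itc_loglik(m, k, theta, as.integer(fn == "hyper")))
  }
  ll <- 0
  for (t in seq_len(nrow(m))) {
    pl <- choice_prob_later(m[t, 2L], m[t, 3L], m[t, 1L], k, theta, fn)
    ll <- ll + if (m[t, 4L] == 1) log(pl) else log(1 - pl)
  }
  unname(ll)
}

#' Maximum-likelihood fit of a discounting model to one session
#'
#' Numerical maximization of [itc_session_loglik()] over `(log k, log theta)`,
#' used by the parameter-recovery diagnostics.
#'
#' @param trials ITC trial table.
#' @param fn discount function.
#' @param start start values on the log scale, `c(log_k, log_theta)`.
#' @return list with `k`, `theta` and `loglik`.
#' @export
itc_mle <- function(trials, fn = c("hyper", "exp"),
                    start = c(0, log(0.05))) {
  fn <- match.arg(fn)
  m <- itc_matrix(trials)
  obj <- function(x) -cpp_itc_loglik(m, exp(x[1]), exp(x[2]),
                                     as.integer(fn == "hyper"))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000))
  list(k = exp(fit$par[1]), theta = exp(fit$par[2]), loglik = -fit$value)
}
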