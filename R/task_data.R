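# Trial-level data model shared by the simulators, the likelihoods and the
# hierarchical models. Two tasks: the two-step sequential decision task and
# the adaptive intertemporal choice (ITC) task.

DELAY_LABELS <- c("1 day", "1 week", "1 month", "3 months", "6 months", "1 year")
DELAY_DAYS <- c(1, 7, 30, 91, 182, 365)

#' Delay schedule of the intertemporal choice task
#'
#' The six delays used in the ITC task, with the calendar-day convention used
#' to scale each delay to the maximum available (one year): 1 week = 7/365,
#' 1 month = 30/365, 3 months = 91/365, 6 months = 182/365, 1 year = 1.
#'
#' @return A data.frame with columns `label`, `days` and `frac` (delay as a
#'   fraction of one year, the `D` entering the discount functions).
#' @export
delay_schedule <- function() {
  data.frame(label = DELAY_LABELS, days = DELAY_DAYS,
             frac = DELAY_DAYS / 365, stringsAsFactors = FALSE)
}

#' Study configuration for the two-step and ITC tasks
#'
#' The two studies shared the same task structure and differed only in a few
#' parameters: trials per participant (201 vs 176), the payoff drift standard
#' deviation (0.025 vs 0.05), the reflecting boundaries of the drift
#' (0.2/0.8 vs 0.25/0.75) and the number of ITC sessions (2 vs 1).
#'
#' @param study Study id, 1 or 2.
#' @param n_twostep_trials,drift_sd,drift_lo,drift_hi,itc_sessions Optional
#'   overrides of the study defaults (e.g. a shorter session for simulation
#'   studies).
#' @return A list of class `study_config`.
#' @export
study_config <- function(study = 1, n_twostep_trials = NULL, drift_sd = NULL,
                         drift_lo = NULL, drift_hi = NULL, itc_sessions = NULL) {
  stopifnot(study %in% c(1, 2))
  cfg <- if (study == 1) {
    list(study_id = 1L, n_twostep_trials = 201L, drift_sd = 0.025,
         drift_lo = 0.2, drift_hi = 0.8, itc_sessions = 2L)
  } else {
    list(study_id = 2L, n_twostep_trials = 176L, drift_sd = 0.05,
         drift_lo = 0.25, drift_hi = 0.75, itc_sessions = 1L)
  }
  if (!is.null(n_twostep_trials)) cfg$n_twostep_trials <- as.integer(n_twostep_trials)
  if (!is.null(drift_sd)) cfg$drift_sd <- drift_sd
  if (!is.null(drift_lo)) cfg$drift_lo <- drift_lo
  if (!is.null(drift_hi)) cfg$drift_hi <- drift_hi
  if (!is.null(itc_sessions)) cfg$itc_sessions <- as.integer(itc_sessions)
  stopifnot(cfg$drift_lo > 0, cfg$drift_hi < 1, cfg$drift_lo < cfg$drift_hi)
  class(cfg) <- "study_config"
  cfg
}

# transition consistent with the fixed map: action 0 commonly -> state A,
# action 1 commonly -> state B
.expected_transition <- function(a1, s2) {
  ifelse((a1 == 0 & s2 == "A") | (a1 == 1 & s2 == "B"), "common", "rare")
}

#' Validate a two-step trial table
#'
#' Checks the invariants of the two-step trial representation: actions in
#' {0,1}, second-stage state in {A,B}, binary reward, and transition labels
#' consistent with the fixed transition map (action 0 commonly leads to state
#' A, action 1 to state B).
#'
#' @param df data.frame with columns `trial`, `a1`, `transition`, `s2`, `a2`,
#'   `reward`.
#' @return `df`, ordered by trial, invisibly valid; errors name the offending
#'   field and row.
#' @export
validate_twostep <- function(df) {
  need <- c("trial", "a1", "transition", "s2", "a2", "reward")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("twostep table missing columns: ", paste(miss, collapse = ", "))
  df <- df[order(df$trial), , drop = FALSE]
  chk <- function(ok, field) {
    if (any(!ok)) stop(sprintf("invalid %s at row %d", field, which(!ok)[1]), call. = FALSE)
  }
  chk(df$trial >= 1 & df$trial == floor(df$trial), "trial")
  chk(!duplicated(df$trial), "trial (duplicate index)")
  chk(df$a1 %in% c(0, 1), "a1")
  chk(df$a2 %in% c(0, 1), "a2")
  chk(df$s2 %in% c("A", "B"), "s2")
  chk(df$reward %in% c(0, 1), "reward")
  chk(df$transition == .expected_transition(df$a1, df$s2), "transition")
  df
}

#' Validate an intertemporal choice trial table
#'
#' Enforces the ITC invariants: the later amount is exactly $1,000, the now
#' amount lies strictly between 0 and the later amount, the delay fraction is
#' in (0, 1], and choices are "now" or "later".
#'
#' @param df data.frame with columns `session`, `delay_label`, `delay_frac`,
#'   `now_amount`, `later_amount`, `choice`.
#' @return `df`, validated; errors name the offending field and row.
#' @export
validate_itc <- function(df) {
  need <- c("session", "delay_label", "delay_frac", "now_amount",
            "later_amount", "choice")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("itc table missing columns: ", paste(miss, collapse = ", "))
  chk <- function(ok, field) {
    if (any(!ok)) stop(sprintf("invalid %s at row %d", field, which(!ok)[1]), call. = FALSE)
  }
  chk(df$session %in% c(1, 2), "session")
  chk(df$delay_label %in% DELAY_LABELS, "delay_label")
  chk(df$delay_frac > 0 & df$delay_frac <= 1, "delay_frac")
  chk(abs(df$later_amount - 1000) < 1e-9, "later_amount")
  chk(df$now_amount > 0 & df$now_amount < df$later_amount, "now_amount")
  chk(df$choice %in% c("now", "later"), "choice")
  df
}

#' Construct a per-subject dataset
#'
#' Bundles a subject's two-step and ITC trial tables with the study
#' configuration they were collected (or simulated) under. Either task table
#' may be `NULL` when only one task has been loaded.
#'
#' @param subject_id character scalar.
#' @param study a `study_config` or a study id (1/2).
#' @param twostep,itc validated trial tables (or `NULL`).
#' @return list of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, study = 1, twostep = NULL, itc = NULL) {
  if (!inherits(study, "study_config")) study <- study_config(study)
  if (!is.null(twostep)) twostep <- validate_twostep(twostep)
  if (!is.null(itc)) itc <- validate_itc(itc)
  structure(list(subject_id = as.character(subject_id), study = study,
                 twostep = twostep, itc = itc),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject %s (study %d): %s two-step trials, %s ITC trials\n",
              x$subject_id, x$study$study_id,
              if (is.null(x$twostep)) 0L else nrow(x$twostep),
              if (is.null(x$itc)) 0L else nrow(x$itc)))
  invisible(x)
}

.twostep_cols <- c("subject_id", "study", "trial", "a1", "transition", "s2",
                   "a2", "reward")
.itc_cols <- c("subject_id", "study", "session", "delay_label", "delay_frac",
               "now_amount", "later_amount", "choice")

#' Read trial tables from CSV
#'
#' Reads a flat per-trial CSV for one of the two tasks and splits it into
#' validated per-subject datasets. Two-step files carry columns
#' `subject_id, study, trial, a1, transition, s2, a2, reward`; ITC files carry
#' `subject_id, study, session, delay_label, delay_frac, now_amount,
#' later_amount, choice`.
#'
#' @param path CSV file path.
#' @param task `"twostep"` or `"itc"`.
#' @return Named list of `subject_dataset` objects (the slot for the other
#'   task is `NULL`); use [merge_datasets()] to combine the two tasks.
#' @export
read_trials <- function(path, task = c("twostep", "itc")) {
  task <- match.arg(task)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (task == "twostep") .twostep_cols else .itc_cols
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("%s: missing columns %s", path,
                                 paste(miss, collapse = ", ")))
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  out <- lapply(split(df, df$subject_id), function(d) {
    study <- unique(d$study)
    if (length(study) != 1) stop("subject ", d$subject_id[1],
                                 ": inconsistent study ids")
    tab <- d[setdiff(names(d), c("subject_id", "study"))]
    rownames(tab) <- NULL
    if (task == "twostep") {
      subject_dataset(d$subject_id[1], study, twostep = tab)
    } else {
      subject_dataset(d$subject_id[1], study, itc = tab)
    }
  })
  out[order(names(out))]
}

#' Write per-subject datasets to CSV
#'
#' Inverse of [read_trials()]: emits one flat CSV for the chosen task.
#' Subjects lacking that task are skipped; an empty dataset list yields a
#' header-only file. `read_trials(write_trials(x))` reproduces `x` exactly.
#'
#' @param datasets list of `subject_dataset`.
#' @param path output CSV path.
#' @param task `"twostep"` or `"itc"`.
#' @export
write_trials <- function(datasets, path, task = c("twostep", "itc")) {
  task <- match.arg(task)
  rows <- lapply(datasets, function(d) {
    tab <- d[[task]]
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    cbind(data.frame(subject_id = d$subject_id, study = d$study$study_id,
                     stringsAsFactors = FALSE), tab)
  })
  rows <- Filter(Negate(is.null), rows)
  cols <- if (task == "twostep") .twostep_cols else .itc_cols
  if (length(rows) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  out <- do.call(rbind, rows)[, cols]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Merge task tables of matching subjects
#'
#' Combines two lists of datasets (typically one read from a two-step CSV and
#' one from an ITC CSV) into single datasets carrying both tasks.
#'
#' @param a,b named lists of `subject_dataset`.
#' @return Named list of merged datasets over the union of subjects.
#' @export
merge_datasets <- function(a, b) {
  ids <- sort(union(names(a), names(b)))
  out <- lapply(ids, function(id) {
    x <- a[[id]]; y <- b[[id]]
    if (is.null(x)) return(y)
    if (is.null(y)) return(x)
    if (x$study$study_id != y$study$study_id)
      stop("subject ", id, ": study mismatch between tasks")
    x$twostep <- if (is.null(x$twostep)) y$twostep else x$twostep
    x$itc <- if (is.null(x$itc)) y$itc else x$itc
    x
  })
  names(out) <- ids
  out
}
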