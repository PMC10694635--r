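#' subvaltest: one-step value-difference tests for treatment-benefit subgroups
#'
#' Implements a test of the null hypothesis that no subgroup of patients
#' benefits from an active treatment relative to control. The test statistic
#' is built from per-patient value-difference scores comparing an estimated
#' optimal treatment regime against the give-everyone-control regime, combined
#' across sequential data chunks so that inference remains valid at the
#' exceptional law (a positive fraction of patients with exactly zero
#' conditional treatment effect). Both uncensored continuous outcomes and
#' right-censored time-to-event outcomes (on the restricted-mean-survival-time
#' scale) are supported.
#'
#' @section Main entry points:
#' * [one_step_test()] runs the sequential test on a validated trial dataset.
#' * [validate_uncensored()] / [validate_survival()] build trial containers
#'   from raw tables.
#' * [gen_model1()] / [gen_aft()] generate the benchmark simulation designs
#'   and [monte_carlo()] summarises operating characteristics over replicates.
#'
#' @keywords internal
#' @aliases subvaltest-package
"_PACKAGE"

# ---- containers -------------------------------------------------------------

#' Construct an uncensored trial dataset
#'
#' Bundles covariates, a binary treatment indicator and a continuous outcome
#' (larger values preferred) into a validated container used by all downstream
#' routines.
#'
#' @param X Numeric covariate matrix (n x p) or data frame of numeric columns.
#' @param A Integer/numeric treatment indicator in {0, 1}; both arms required.
#' @param Y Numeric outcome vector, larger values preferred.
#' @param known_pi Optional known randomization probability P(A = 1) in (0, 1).
#' @return An object of class `"uncensored_trial"`: a list with elements
#'   `X`, `A`, `Y`, `n`, `p`, `known_pi`.
#' @examples
#' d <- uncensored_trial(matrix(rnorm(20), 10), rep(0:1, 5), rnorm(10))
#' d$n
#' @export
uncensored_trial <- function(X, A, Y, known_pi = NULL) {
  X <- as_covariate_matrix(X)
  A <- check_treatment(A, nrow(X))
  Y <- as.numeric(Y)
  if (length(Y) != nrow(X)) stop("Y length does not match X rows")
  if (!all(is.finite(Y))) stop("Y contains missing or non-finite values")
  check_known_pi(known_pi)
  structure(
    list(X = X, A = A, Y = Y, n = nrow(X), p = ncol(X), known_pi = known_pi),
    class = c("uncensored_trial", "trial_data")
  )
}

#' Construct a right-censored survival trial dataset
#'
#' Bundles covariates, treatment, the observed time `U = min(T, C)` and the
#' event indicator `Delta = 1(T <= C)` together with the restriction time `L`
#' used for restricted-mean-survival-time comparisons. The truncated time
#' `UL = min(U, L)` and its event indicator
#' `DeltaL = Delta + (1 - Delta) * 1(U >= L)` are derived and stored: a subject
#' censored at or after `L` is fully observed on the truncated scale.
#'
#' @inheritParams uncensored_trial
#' @param U Nonnegative observed time vector.
#' @param Delta Event indicator in {0, 1} (1 = event, 0 = censored).
#' @param L Positive restriction time; some subjects must satisfy `U >= L`
#'   (empirical positivity of `P(U >= L)`).
#' @return An object of class `"survival_trial"`: list with `X`, `A`, `U`,
#'   `Delta`, `L`, derived `UL`, `DeltaL`, plus `n`, `p`, `known_pi`.
#' @examples
#' d <- survival_trial(matrix(rnorm(20), 10), rep(0:1, 5),
#'                     U = rexp(10, 0.02), Delta = rbinom(10, 1, 0.8), L = 5)
#' cbind(d$UL, d$DeltaL)
#' @export
survival_trial <- function(X, A, U, Delta, L, known_pi = NULL) {
  X <- as_covariate_matrix(X)
  A <- check_treatment(A, nrow(X))
  U <- as.numeric(U)
  Delta <- as.numeric(Delta)
  if (length(U) != nrow(X) || length(Delta) != nrow(X))
    stop("U/Delta length does not match X rows")
  if (!all(is.finite(U)) || any(U < 0)) stop("U must be nonnegative and finite")
  if (!all(Delta %in% c(0, 1))) stop("Delta must be coded 0/1 (1 = event)")
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("L must be a single positive number")
  if (!any(U >= L))
    stop("L violates positivity: no subject has U >= L")
  check_known_pi(known_pi)
  UL <- pmin(U, L)
  DeltaL <- Delta + (1 - Delta) * as.numeric(U >= L)
  structure(
    list(X = X, A = A, U = U, Delta = Delta, L = L, UL = UL, DeltaL = DeltaL,
         n = nrow(X), p = ncol(X), known_pi = known_pi),
    class = c("survival_trial", "trial_data")
  )
}

as_covariate_matrix <- function(X) {
  if (is.data.frame(X)) {
    ok <- vapply(X, is.numeric, logical(1))
    if (!all(ok))
      stop("all covariates must be numeric; pre-encode categorical columns")
    X <- as.matrix(X)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("covariates contain missing or non-finite values")
  X
}

check_treatment <- function(A, n) {
  A <- as.numeric(A)
  if (length(A) != n) stop("A length does not match X rows")
  if (!all(A %in% c(0, 1)))
    stop("treatment indicator must be coded 0/1; found other values")
  if (length(unique(A)) < 2L)
    stop("degenerate treatment assignment: only one arm present")
  A
}

check_known_pi <- function(known_pi) {
  if (!is.null(known_pi) &&
      (!is.numeric(known_pi) || length(known_pi) != 1L ||
       known_pi <= 0 || known_pi >= 1))
    stop("known_pi must be a single probability in (0, 1)")
  invisible(NULL)
}

#' @export
print.uncensored_trial <- function(x, ...) {
  cat("Uncensored trial data: n =", x$n, ", p =", x$p,
      ", treated =", sum(x$A), "\n")
  if (!is.null(x$known_pi)) cat("Known randomization probability:", x$known_pi, "\n")
  invisible(x)
}

#' @export
print.survival_trial <- function(x, ...) {
  cat("Survival trial data: n =", x$n, ", p =", x$p,
      ", treated =", sum(x$A), "\n")
  cat("Restriction time L =", x$L,
      sprintf("; observed by L: %.1f%%", 100 * mean(x$DeltaL == 1)),
      sprintf("; censored before L: %.1f%%\n", 100 * mean(x$DeltaL == 0)))
  invisible(x)
}

# ---- raw-table validation ---------------------------------------------------

#' Validate a raw table as uncensored trial data
#'
#' Checks column presence, drops rows with any missing value in the used
#' columns (the count is reported via a message and attached as attribute
#' `"n_excluded"`), and returns a typed container.
#'
#' @param raw_table A data frame (e.g. from [utils::read.csv()]).
#' @param config Named list of configuration keys: `treatment_col` (default
#'   `"A"`), `outcome_col` (default `"Y"`), `covariate_cols` (default: all
#'   remaining numeric columns), `known_pi` (optional).
#' @return An [uncensored_trial()] container with attribute `n_excluded`.
#' @export
validate_uncensored <- function(raw_table, config = list()) {
  tcol <- config$treatment_col %||% "A"
  ycol <- config$outcome_col %||% "Y"
  need <- c(tcol, ycol)
  miss <- setdiff(need, names(raw_table))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  xcols <- config$covariate_cols %||% setdiff(names(raw_table), need)
  if (length(xcols) < 1L) stop("at least one covariate column is required")
  used <- raw_table[, c(tcol, ycol, xcols), drop = FALSE]
  keep <- stats::complete.cases(used)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(n_excluded, " row(s) with missing values excluded")
  used <- used[keep, , drop = FALSE]
  out <- uncensored_trial(used[, xcols, drop = FALSE], used[[tcol]],
                          used[[ycol]], known_pi = config$known_pi)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Validate a raw table as survival trial data
#'
#' @inheritParams validate_uncensored
#' @param config Named list: `treatment_col` (default `"A"`), `time_col`
#'   (default `"U"`), `status_col` (default `"Delta"`, convention 1 = event,
#'   0 = censored), `covariate_cols`, `known_pi`, and either `L` or
#'   `target_observed_frac` (forwarded to [choose_L()]).
#' @return A [survival_trial()] container with attribute `n_excluded`.
#' @export
validate_survival <- function(raw_table, config = list()) {
  tcol <- config$treatment_col %||% "A"
  ucol <- config$time_col %||% "U"
  dcol <- config$status_col %||% "Delta"
  need <- c(tcol, ucol, dcol)
  miss <- setdiff(need, names(raw_table))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  xcols <- config$covariate_cols %||% setdiff(names(raw_table), need)
  if (length(xcols) < 1L) stop("at least one covariate column is required")
  used <- raw_table[, c(need, xcols), drop = FALSE]
  keep <- stats::complete.cases(used)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(n_excluded, " row(s) with missing values excluded")
  used <- used[keep, , drop = FALSE]
  if (!is.null(config$L) && !is.null(config$target_observed_frac))
    stop("supply either L or target_observed_frac, not both")
  L <- config$L %||% choose_L(used[[ucol]],
                              config$target_observed_frac %||% 0.85)
  out <- survival_trial(used[, xcols, drop = FALSE], used[[tcol]],
                        used[[ucol]], used[[dcol]], L = L,
                        known_pi = config$known_pi)
  attr(out, "n_excluded") <- n_excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- CSV round trip ---------------------------------------------------------

#' Write trial data to CSV at full double precision
#'
#' Writes the container columns (covariates plus `A` and `Y`, or `A`, `U`,
#' `Delta`) with `%.17g` formatting so that a write/read round trip reproduces
#' the arrays exactly.
#'
#' @param data A `trial_data` container.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  df <- as.data.frame(data$X)
  df$A <- data$A
  if (inherits(data, "survival_trial")) {
    df$U <- data$U
    df$Delta <- data$Delta
  } else {
    df$Y <- data$Y
  }
  fmt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  fmt <- rbind(names(df), fmt)
  writeLines(apply(fmt, 1L, paste, collapse = ","), path)
  invisible(path)
}

#' Read trial data written by [write_trial_csv()]
#'
#' @param path CSV path.
#' @param type `"continuous"` or `"survival"`.
#' @param config Passed to [validate_uncensored()] / [validate_survival()];
#'   for survival data supply `L` (or `target_observed_frac`).
#' @return A `trial_data` container.
#' @export
read_trial_csv <- function(path, type = c("continuous", "survival"),
                           config = list()) {
  type <- match.arg(type)
  raw <- utils::read.csv(path)
  if (type == "continuous") validate_uncensored(raw, config)
  else validate_survival(raw, config)
}
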