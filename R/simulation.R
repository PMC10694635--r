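# Benchmark simulation designs and the Monte Carlo harness.
#
# Covariates in every design: X1, X2, X3 iid N(0, 1); X4, X5 iid
# Bernoulli(0.5). "N(0, 0.25)" noise is parameterized as variance 0.25
# (SD 0.5).

expit <- function(x) 1 / (1 + exp(-x))

sim_covariates <- function(n, extra_noise = 0L) {
  X <- cbind(X1 = stats::rnorm(n), X2 = stats::rnorm(n), X3 = stats::rnorm(n),
             X4 = stats::rbinom(n, 1, 0.5), X5 = stats::rbinom(n, 1, 0.5))
  if (extra_noise > 0L) {
    N <- matrix(stats::rnorm(n * extra_noise), n,
                dimnames = list(NULL, paste0("N", seq_len(extra_noise))))
    X <- cbind(X, N)
  }
  X
}

draw_treatment <- function(X, pi_mode, pi, allocation) {
  n <- nrow(X)
  if (pi_mode == "observational") {
    p <- expit(-0.3 + 0.2 * X[, "X1"] + 0.6 * X[, "X5"])
    A <- stats::rbinom(n, 1, p)
  } else if (allocation == "exact") {
    n1 <- round(n * pi)
    A <- sample(rep(c(1, 0), c(n1, n - n1)))
  } else {
    A <- stats::rbinom(n, 1, pi)
  }
  if (length(unique(A)) < 2L) A[sample.int(n, 1)] <- 1 - A[1]
  A
}

#' Generate uncensored benchmark data (Model 1)
#'
#' `Y = C0(X) + A * tau(X) + eps`, with
#' `C0(X) = 3.18 + 0.2 X1 + X2 + 0.5 X3`,
#' `tau(X) = c * 1(X4 - X2^2 / 2 > 0)` and `eps ~ N(0, 0.25)` (variance).
#' Under scheme 2, 20 additional iid N(0, 1) noise covariates are appended.
#' About 57.9% of the population has exactly zero treatment effect
#' (`1 - 0.5 P(chi^2_1 < 2)`), so `c = 0` puts the design at the exceptional
#' law; `c > 0` creates a benefiting subgroup.
#'
#' @param n Sample size.
#' @param c Subgroup effect size (`c <= 0`: null true; `c > 0`: alternative).
#' @param scheme 1 (five covariates) or 2 (adds 20 noise covariates).
#' @param pi Randomization probability (randomized mode).
#' @param pi_mode `"randomized"` or `"observational"` (logistic propensity
#'   `expit(-0.3 + 0.2 X1 + 0.6 X5)`).
#' @param allocation `"bernoulli"` draws, or `"exact"` fixing the treated
#'   count at `round(n * pi)` (used with SAP-match chunking).
#' @return An [uncensored_trial()] with attribute `"truth"` (functions
#'   `pi_fun`, `c0_fun`, `tau_fun`) for oracle-nuisance studies.
#' @export
gen_model1 <- function(n, c, scheme = 1, pi = 0.5,
                       pi_mode = c("randomized", "observational"),
                       allocation = c("bernoulli", "exact")) {
  pi_mode <- match.arg(pi_mode)
  allocation <- match.arg(allocation)
  X <- sim_covariates(n, extra_noise = if (scheme == 2) 20L else 0L)
  c0_fun <- function(X) 3.18 + 0.2 * X[, "X1"] + X[, "X2"] + 0.5 * X[, "X3"]
  tau_fun <- function(X) c * as.numeric(X[, "X4"] - 0.5 * X[, "X2"]^2 > 0)
  A <- draw_treatment(X, pi_mode, pi, allocation)
  Y <- c0_fun(X) + A * tau_fun(X) + stats::rnorm(n, 0, 0.5)
  out <- uncensored_trial(X, A, Y,
                          known_pi = if (pi_mode == "randomized") pi else NULL)
  attr(out, "truth") <- list(
    pi_fun = if (pi_mode == "randomized") function(X) rep(pi, nrow(rbind(X)))
             else function(X) expit(-0.3 + 0.2 * X[, "X1"] + 0.6 * X[, "X5"]),
    c0_fun = c0_fun, tau_fun = tau_fun)
  out
}

aft_linpred <- function(X) {
  1.75 + 0.5 * X[, "X1"] + X[, "X1"]^2 + 0.3 * X[, "X2"] +
    0.2 * X[, "X3"] + 0.3 * X[, "X4"] + 0.6 * X[, "X5"]
}

#' Generate right-censored benchmark data (AFT models)
#'
#' Accelerated failure time model
#' `log T = 1.75 + 0.5 X1 + X1^2 + 0.3 X2 + 0.2 X3 + 0.3 X4 + 0.6 X5
#'          + c * A * 1(X2 + 3 X4 > 0) + e`,
#' with `e ~ N(0, 0.25)` (error model 1, non-proportional hazards) or
#' `e = log Z`, `Z ~ Exp(1)` (error model 2, proportional hazards).
#' Approximately 25% of the population has exactly zero effect
#' (`P(X2 + 3 X4 <= 0)`). Censoring: (a) `U(0, 50)`, (b) `U(0, 100)`,
#' (c) exponential with rate `exp(cens_intercept + 0.1 X1 + 0.2 A)`, or none.
#' The model-(c) intercept is a calibration parameter; its default makes
#' censoring by `L` heavier than under model (b).
#'
#' @inheritParams gen_model1
#' @param error_model `"normal"` (model 1) or `"exponential"` (model 2).
#' @param censoring `"a"`, `"b"`, `"c"` or `"none"`.
#' @param L Restriction time. Defaults: 42 under censoring (b), 33 under
#'   (c), otherwise the 0.85 empirical quantile of `U` via [choose_L()].
#' @param cens_intercept Intercept of the model-(c) log censoring rate.
#' @return A [survival_trial()] with attribute `"truth"` (functions `pi_fun`,
#'   `surv_fun(t, X, a)`, `cumhaz_c_fun(t, X, a)` and `effect_ind(X)`).
#' @export
gen_aft <- function(n, c, error_model = c("normal", "exponential"),
                    censoring = c("a", "b", "c", "none"),
                    pi = 0.5, pi_mode = c("randomized", "observational"),
                    allocation = c("bernoulli", "exact"),
                    L = NULL, cens_intercept = -4) {
  error_model <- match.arg(error_model)
  censoring <- match.arg(censoring)
  pi_mode <- match.arg(pi_mode)
  allocation <- match.arg(allocation)
  X <- sim_covariates(n)
  A <- draw_treatment(X, pi_mode, pi, allocation)
  eff <- as.numeric(X[, "X2"] + 3 * X[, "X4"] > 0)
  mu <- aft_linpred(X) + c * A * eff
  e <- if (error_model == "normal") stats::rnorm(n, 0, 0.5)
       else log(stats::rexp(n))
  T_time <- exp(mu + e)
  Cens <- switch(censoring,
    a = stats::runif(n, 0, 50),
    b = stats::runif(n, 0, 100),
    c = stats::rexp(n, exp(cens_intercept + 0.1 * X[, "X1"] + 0.2 * A)),
    none = rep(Inf, n))
  U <- pmin(T_time, Cens)
  Delta <- as.numeric(T_time <= Cens)
  if (is.null(L))
    L <- switch(censoring, b = 42, c = 33, choose_L(U, 0.85))
  out <- survival_trial(X, A, U, Delta, L = L,
                        known_pi = if (pi_mode == "randomized") pi else NULL)
  surv_fun <- function(t, X, a) {
    X <- rbind(X)
    m <- aft_linpred(X) + c * a * as.numeric(X[, "X2"] + 3 * X[, "X4"] > 0)
    if (error_model == "normal") {
      stats::pnorm((log(t) - m) / 0.5, lower.tail = FALSE)
    } else {
      exp(-t * exp(-m))
    }
  }
  cumhaz_c_fun <- switch(censoring,
    a = function(t, X, a) rep(-log(pmax(1 - pmin(t, 50 * 0.999) / 50, 1e-12)),
                              nrow(rbind(X))),
    b = function(t, X, a) rep(-log(pmax(1 - pmin(t, 100 * 0.999) / 100, 1e-12)),
                              nrow(rbind(X))),
    c = function(t, X, a)
      t * exp(cens_intercept + 0.1 * rbind(X)[, "X1"] + 0.2 * a),
    none = function(t, X, a) rep(0, nrow(rbind(X))))
  attr(out, "truth") <- list(
    pi_fun = if (pi_mode == "randomized") function(X) rep(pi, nrow(rbind(X)))
             else function(X) expit(-0.3 + 0.2 * rbind(X)[, "X1"] +
                                      0.6 * rbind(X)[, "X5"]),
    surv_fun = surv_fun, cumhaz_c_fun = cumhaz_c_fun,
    effect_ind = function(X) as.numeric(rbind(X)[, "X2"] + 3 * rbind(X)[, "X4"] > 0))
  out
}

#' Oracle nuisance spec from a generated design
#'
#' Reads the `"truth"` attribute attached by [gen_model1()] / [gen_aft()] and
#' wraps it via [oracle_nuisance()].
#'
#' @param data Trial data carrying a `"truth"` attribute.
#' @param grid_size Discretization grid for survival designs.
#' @return A `nuisance_spec`.
#' @export
oracle_from_design <- function(data, grid_size = 400) {
  tr <- attr(data, "truth")
  if (is.null(tr)) stop("data carry no truth attribute")
  oracle_nuisance(pi_fun = tr$pi_fun, c0_fun = tr$c0_fun,
                  tau_fun = tr$tau_fun, surv_fun = tr$surv_fun,
                  cumhaz_fun = tr$cumhaz_c_fun, grid_size = grid_size)
}

#' Choose the RMST restriction time from the observed-time distribution
#'
#' Returns the empirical quantile of `U` at `target_observed_frac`, so that
#' approximately that fraction of subjects is observed (event or follow-up)
#' by `L`; keeping `Kc(L)` away from zero stabilizes the inverse weights.
#'
#' @param U Observed times.
#' @param target_observed_frac Target fraction observed by `L` (default 0.85).
#' @return The chosen `L`.
#' @export
choose_L <- function(U, target_observed_frac = 0.85) {
  if (target_observed_frac <= 0 || target_observed_frac >= 1)
    stop("target_observed_frac must be in (0, 1)")
  if (length(unique(U)) == 1L) {
    warning("degenerate observed times; returning their common value")
    return(U[1])
  }
  stats::quantile(U, target_observed_frac, type = 1, names = FALSE)
}

#' Monte Carlo estimate of the zero-effect fraction of a design
#'
#' @param family `"model1_scheme1"`, `"model1_scheme2"`, `"aft"`, or
#'   `"custom"` with `indicator_fun`.
#' @param n_mc Number of Monte Carlo covariate draws (>= 1000).
#' @param indicator_fun For `family = "custom"`: function of the covariate
#'   matrix returning the has-effect indicator.
#' @return Estimated `P(tau(X) = 0)` with attribute `"mc_se"`.
#' @export
zero_effect_fraction <- function(family = c("model1_scheme1",
                                            "model1_scheme2", "aft",
                                            "custom"),
                                 n_mc = 10000, indicator_fun = NULL) {
  family <- match.arg(family)
  if (n_mc < 1000) stop("n_mc must be at least 1000")
  X <- sim_covariates(n_mc)
  has_effect <- switch(family,
    model1_scheme1 = ,
    model1_scheme2 = X[, "X4"] - 0.5 * X[, "X2"]^2 > 0,
    aft = X[, "X2"] + 3 * X[, "X4"] > 0,
    custom = {
      if (is.null(indicator_fun)) stop("indicator_fun required")
      indicator_fun(X) > 0
    })
  p0 <- mean(!has_effect)
  structure(p0, mc_se = sqrt(p0 * (1 - p0) / n_mc))
}

#' Monte Carlo operating characteristics of the one-step test
#'
#' Runs [one_step_test()] on `n_reps` independently generated datasets and
#' summarises, per estimator, the mean and SD of the statistic and the
#' rejection rate, with Monte Carlo standard errors. Per-replicate seeds are
#' derived from the master seed, so a row is bitwise reproducible.
#'
#' @param generator Function `n -> trial_data` drawing one dataset with the
#'   current RNG (e.g. `function(n) gen_model1(n, c = 0.3)`).
#' @param n Sample size per replicate.
#' @param n_reps Number of replicates (>= 2).
#' @param test_args Named list of arguments forwarded to [one_step_test()]
#'   (must include `estimator`).
#' @param alpha Level used for the rejection rate.
#' @param seed Master seed.
#' @return Object of class `"mc_row"`: data frame with one row per estimator
#'   (`mu`, `sigma`, `reject_rate` and their MC standard errors, `n_reps`,
#'   `n_failed`); per-replicate statistics in attribute `"t_values"`.
#' @export
monte_carlo <- function(generator, n, n_reps, test_args = list(),
                        alpha = 0.05, seed = 1) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  est <- test_args$estimator
  if (is.null(est)) stop("test_args must name the estimator(s)")
  tvals <- matrix(NA_real_, n_reps, length(est),
                  dimnames = list(NULL, est))
  failures <- character(0)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    dat <- generator(n)
    res <- tryCatch(
      do.call(one_step_test,
              c(list(data = dat, alpha = alpha, seed = rep_seeds[r]),
                test_args)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    if (inherits(res, "value_diff_test")) res <- list(res)
    for (one in res) tvals[r, one$estimator] <- one$statistic
  }
  ok <- stats::complete.cases(tvals)
  if (mean(!ok) > 0.01)
    warning("more than 1% of replicates failed; row flagged: ",
            paste(utils::head(unique(failures), 3), collapse = " | "))
  tv <- tvals[ok, , drop = FALSE]
  zcrit <- stats::qnorm(1 - alpha)
  rows <- lapply(est, function(e) {
    t_e <- tv[, e]
    r_e <- mean(t_e > zcrit)
    data.frame(estimator = e,
               mu = mean(t_e), sigma = stats::sd(t_e),
               reject_rate = r_e,
               se_mu = stats::sd(t_e) / sqrt(length(t_e)),
               se_sigma = stats::sd(t_e) / sqrt(2 * length(t_e)),
               se_reject = sqrt(r_e * (1 - r_e) / length(t_e)),
               n_reps = length(t_e), n_failed = sum(!ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "t_values") <- tvals
  attr(out, "seed") <- seed
  class(out) <- c("mc_row", class(out))
  out
}
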