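# Nuisance-function estimation. All fits are "frozen" objects: functions of
# new covariate values only, so that downstream scores at step j depend on the
# history they were fitted on and nothing else.

EPS_PI <- 0.01
EPS_K <- 0.01
EPS_S <- 1e-4

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Matrices arrive from several sources (containers, raw matrices); fits are
# made on named frames, so normalize names once at fit time and reapply them
# at predict time (column order is the contract).
named_X <- function(X) {
  X <- rbind(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  X
}

renamed_as <- function(Xnew, template_names) {
  Xnew <- rbind(Xnew)
  if (ncol(Xnew) != length(template_names))
    stop("covariate dimension mismatch at prediction time")
  colnames(Xnew) <- template_names
  Xnew
}

#' Fit (or fix) the propensity score
#'
#' @param X Covariate matrix.
#' @param A Treatment vector in {0, 1}.
#' @param mode `"logistic"` fits a main-effects logistic regression;
#'   `"known"` returns the supplied randomization probability as a constant.
#' @param known_pi Known P(A = 1), required for `mode = "known"`.
#' @param eps_pi Clipping bound: predictions are restricted to
#'   `[eps_pi, 1 - eps_pi]`.
#' @return A function `pi_hat(Xnew)` returning clipped propensities, with the
#'   fitted glm (if any) in attribute `"model"`.
#' @export
fit_propensity <- function(X, A, mode = c("logistic", "known"),
                           known_pi = NULL, eps_pi = EPS_PI) {
  mode <- match.arg(mode)
  if (mode == "known") {
    if (is.null(known_pi)) stop("known_pi required in known mode")
    p <- clip(known_pi, eps_pi, 1 - eps_pi)
    return(function(Xnew) rep(p, nrow(rbind(Xnew))))
  }
  if (length(unique(A)) < 2L)
    stop("degenerate fit: history contains a single treatment arm")
  X <- named_X(X)
  df <- data.frame(.A = A, X)
  fit <- stats::glm(.A ~ ., data = df, family = stats::binomial())
  f <- function(Xnew) {
    nd <- as.data.frame(renamed_as(Xnew, colnames(X)))
    p <- stats::predict(fit, newdata = nd, type = "response")
    clip(as.numeric(p), eps_pi, 1 - eps_pi)
  }
  attr(f, "model") <- fit
  f
}

#' Fit arm-wise outcome regressions for an uncensored outcome
#'
#' Fits one random (regression) forest per treatment arm. The control
#' conditional mean is the arm-0 prediction and the CATE is the difference of
#' the two arm predictions ("two-learner" strategy). Any regressor pair with
#' the same predict contract can be substituted via [oracle_nuisance()] or a
#' custom nuisance spec.
#'
#' @inheritParams fit_propensity
#' @param Y Outcome vector.
#' @param num_trees Trees per forest.
#' @param min_node Minimum node size (ranger default when `NULL`).
#' @param seed Seed forwarded to the forests.
#' @return List with functions `c0_hat(Xnew)` and `tau_hat(Xnew)`.
#' @export
fit_outcome_models <- function(X, A, Y, num_trees = 300, min_node = NULL,
                               seed = NULL) {
  for (a in 0:1) {
    if (sum(A == a) < 2L)
      stop("too few observations in arm ", a, " to fit an outcome model")
  }
  X <- named_X(X)
  fits <- lapply(0:1, function(a) {
    idx <- which(A == a)
    d <- data.frame(.Y = Y[idx], X[idx, , drop = FALSE])
    ranger::ranger(.Y ~ ., data = d, num.trees = num_trees,
                   min.node.size = if (is.null(min_node)) 5 else min_node,
                   seed = seed, num.threads = 1)
  })
  pred <- function(fit, Xnew)
    stats::predict(fit, data = as.data.frame(renamed_as(Xnew, colnames(X))),
                   num.threads = 1)$predictions
  list(
    c0_hat = function(Xnew) pred(fits[[1]], Xnew),
    tau_hat = function(Xnew) pred(fits[[2]], Xnew) - pred(fits[[1]], Xnew),
    forests = fits
  )
}

#' Fit arm-wise survival curves and RMST-scale outcome models
#'
#' Fits one random survival forest per arm. The control conditional RMST is
#' the integral of the arm-0 survival curve over `[0, L]` and the CATE (RMST
#' scale) is the difference of the two arm integrals.
#'
#' @inheritParams fit_outcome_models
#' @param U Observed times.
#' @param Delta Event indicators (1 = event).
#' @param L Restriction time.
#' @return List with `curves(Xnew, a)` returning `list(times, surv)` (one row
#'   of `surv` per row of `Xnew`), plus `c0_hat(Xnew)` and `tau_hat(Xnew)`.
#' @export
fit_survival_models <- function(X, A, U, Delta, L, num_trees = 300,
                                min_node = NULL, seed = NULL) {
  for (a in 0:1) {
    if (sum(Delta[A == a]) < 1L)
      stop("arm ", a, " has no observed events; cannot fit a survival model")
  }
  X <- named_X(X)
  fits <- lapply(0:1, function(a) {
    idx <- which(A == a)
    d <- data.frame(.U = U[idx], .D = Delta[idx], X[idx, , drop = FALSE])
    ranger::ranger(survival::Surv(.U, .D) ~ ., data = d,
                   num.trees = num_trees,
                   min.node.size = if (is.null(min_node)) 15 else min_node,
                   seed = seed, num.threads = 1)
  })
  curves <- function(Xnew, a) {
    fit <- fits[[a + 1L]]
    pr <- stats::predict(fit,
                         data = as.data.frame(renamed_as(Xnew, colnames(X))),
                         num.threads = 1)
    list(times = fit$unique.death.times, surv = rbind(pr$survival))
  }
  c0_hat <- function(Xnew) {
    cv <- curves(Xnew, 0)
    rmst_integral(cv$times, cv$surv, L)
  }
  list(
    curves = curves,
    c0_hat = c0_hat,
    tau_hat = function(Xnew) {
      cv <- curves(Xnew, 1)
      rmst_integral(cv$times, cv$surv, L) - c0_hat(Xnew)
    },
    forests = fits
  )
}

#' Fit the censoring model (Cox proportional hazards)
#'
#' Fits a Cox model with the observed time as response and `1 - Delta` as the
#' status, with covariates `(X, A)`, and extracts the Breslow baseline
#' cumulative hazard. The conditional censoring survival function is
#' `Kc(t | x, a) = exp(-Lambda_c(t | x, a))`.
#'
#' @inheritParams fit_survival_models
#' @return Object of class `"censoring_fit"`: list with `times` (cumulative-
#'   hazard step times), `basehaz` (Breslow baseline values at `times`) and
#'   `cumhaz(Xnew, Anew)` returning the n x length(times) matrix of
#'   conditional cumulative hazards. With no censoring events in the history a
#'   degenerate fit (`Kc` identically 1) is returned with a warning.
#' @export
fit_censoring_model <- function(X, A, U, Delta) {
  if (all(Delta == 1)) {
    warning("no censoring events in history; using Kc = 1")
    out <- list(times = numeric(0), basehaz = numeric(0),
                cumhaz = function(Xnew, Anew) {
                  matrix(0, nrow(rbind(Xnew)), 0)
                })
    class(out) <- "censoring_fit"
    return(out)
  }
  X <- named_X(X)
  d <- data.frame(.U = U, .S = 1 - Delta, X, .A = A)
  fit <- survival::coxph(survival::Surv(.U, .S) ~ ., data = d,
                         ties = "breslow")
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  bh <- survival::basehaz(fit, centered = FALSE)
  inc <- diff(c(0, bh$hazard))
  keep <- inc > 0
  times <- bh$time[keep]
  H0 <- cumsum(inc[keep])
  out <- list(
    times = times, basehaz = H0, model = fit,
    cumhaz = function(Xnew, Anew) {
      Z <- cbind(rbind(Xnew), Anew)
      lp <- as.vector(Z %*% beta)
      outer(exp(lp), H0)
    }
  )
  class(out) <- "censoring_fit"
  out
}

#' Censoring-martingale augmentation for one subject
#'
#' Evaluates the integral of `m(r | x, a) / Kc(r | x, a)` against the
#' censoring martingale over `[0, L]`, using its two-term rewrite:
#' a point term `(1 - DeltaL) * m(UL) / Kc(UL)` (only when the subject is
#' censored before `L`) minus the compensator sum over the cumulative-hazard
#' step points in `(0, UL]` of `dLambda_c(r) / Kc(r) * m(r)`, with
#' `Kc = exp(-Lambda_c)` evaluated right-continuously and floored at `eps_K`.
#'
#' @param ul Truncated observed time `min(U, L)` of the subject.
#' @param delta_l Truncated event indicator (0 = censored before `L`).
#' @param cumhaz_times Step times of the conditional cumulative censoring
#'   hazard for this subject.
#' @param cumhaz_values Cumulative hazard at those times (nondecreasing).
#' @param m_fun Function `m(r)`: conditional RMST after landmark `r`,
#'   vectorized over `r` (as [conditional_rmst()] is).
#' @param eps_K Floor for `Kc`.
#' @return The augmentation value (scalar). Zero when the hazard is null and
#'   the subject is uncensored.
#' @export
censoring_augmentation <- function(ul, delta_l, cumhaz_times, cumhaz_values,
                                   m_fun, eps_K = EPS_K) {
  stopifnot(length(cumhaz_times) == length(cumhaz_values))
  H_ul <- if (length(cumhaz_times)) {
    c(0, cumhaz_values)[findInterval(ul, cumhaz_times) + 1L]
  } else 0
  kc_ul <- max(exp(-H_ul), eps_K)
  term1 <- if (delta_l == 0) m_fun(ul) / kc_ul else 0
  use <- which(cumhaz_times <= ul)
  term2 <- 0
  if (length(use)) {
    dH <- diff(c(0, cumhaz_values))[use]
    kc <- pmax(exp(-cumhaz_values[use]), eps_K)
    term2 <- sum(dH / kc * m_fun(cumhaz_times[use]))
  }
  term1 - term2
}

# ---- nuisance specs ---------------------------------------------------------

#' Default forest-based nuisance estimator
#'
#' Builds a nuisance "spec": an object with a `fit(data, idx, seed)` method
#' that freezes all nuisance functions on the history `idx`. The default uses
#' logistic regression (or the known randomization probability) for the
#' propensity, arm-wise random forests for the outcome/CATE, arm-wise random
#' survival forests for conditional survival, and a Cox model for censoring.
#'
#' @param num_trees Trees per forest.
#' @param min_node Minimum node size (`NULL` = package defaults).
#' @param propensity `"auto"` uses the known probability when the data carry
#'   one and logistic regression otherwise; `"logistic"` forces a fit.
#' @return Object of class `"nuisance_spec"`.
#' @export
forest_nuisance <- function(num_trees = 300, min_node = NULL,
                            propensity = c("auto", "logistic")) {
  propensity <- match.arg(propensity)
  spec <- list(
    fit = function(data, idx, seed = NULL) {
      X <- data$X[idx, , drop = FALSE]
      A <- data$A[idx]
      use_known <- propensity == "auto" && !is.null(data$known_pi)
      pi_hat <- if (use_known) {
        fit_propensity(X, A, mode = "known", known_pi = data$known_pi)
      } else {
        fit_propensity(X, A, mode = "logistic")
      }
      # within-arm training indices (global), aligned with each forest's rows:
      # predictions at a forest's own training subjects are replaced by its
      # out-of-bag values, so history-based score variances are not
      # optimistically biased by in-bag fit
      idx_arm <- lapply(0:1, function(a) idx[A == a])
      if (inherits(data, "survival_trial")) {
        sm <- fit_survival_models(X, A, data$U[idx], data$Delta[idx],
                                  L = data$L, num_trees = num_trees,
                                  min_node = min_node, seed = seed)
        cm <- fit_censoring_model(X, A, data$U[idx], data$Delta[idx])
        curves_all <- function(data, a) {
          f <- sm$forests[[a + 1L]]
          cv <- sm$curves(data$X, a)
          oob <- f$survival
          ok <- is.finite(rowSums(oob))
          cv$surv[idx_arm[[a + 1L]][ok], ] <- oob[ok, , drop = FALSE]
          cv
        }
        new_nuisance_fit(pi_hat = pi_hat, surv = sm$curves,
                         c0_hat = sm$c0_hat, tau_hat = sm$tau_hat,
                         cens = cm, n_hist = length(idx),
                         curves_all = curves_all)
      } else {
        om <- fit_outcome_models(X, A, data$Y[idx], num_trees = num_trees,
                                 min_node = min_node, seed = seed)
        c0_tau_all <- function(data) {
          p <- lapply(0:1, function(a) {
            f <- om$forests[[a + 1L]]
            pr <- stats::predict(f, data = as.data.frame(
              renamed_as(data$X, f$forest$independent.variable.names)),
              num.threads = 1)$predictions
            oob <- f$predictions
            ok <- is.finite(oob)
            pr[idx_arm[[a + 1L]][ok]] <- oob[ok]
            pr
          })
          list(c0 = p[[1]], tau = p[[2]] - p[[1]])
        }
        new_nuisance_fit(pi_hat = pi_hat, c0_hat = om$c0_hat,
                         tau_hat = om$tau_hat, n_hist = length(idx),
                         c0_tau_all = c0_tau_all)
      }
    }
  )
  class(spec) <- "nuisance_spec"
  spec
}

#' Oracle (user-supplied) nuisance functions
#'
#' Wraps known true nuisance functions in the same spec interface as
#' [forest_nuisance()], for calibration studies and unbiasedness checks.
#' Continuous survival and censoring functions are discretized on a uniform
#' grid over `(0, L]`.
#'
#' @param pi_fun Function `X -> P(A = 1 | X)`.
#' @param c0_fun,tau_fun Functions of `X` (uncensored outcomes; for survival
#'   data they are derived from `surv_fun` and may be omitted).
#' @param surv_fun Function `(t, X, a) -> S(t | X, a)` vectorized over rows of
#'   `X` at a scalar `t` (survival data only).
#' @param cumhaz_fun Function `(t, X, a)` for the conditional cumulative
#'   censoring hazard (survival data only).
#' @param grid_size Number of discretization points on `(0, L]`.
#' @return Object of class `"nuisance_spec"`.
#' @export
oracle_nuisance <- function(pi_fun, c0_fun = NULL, tau_fun = NULL,
                            surv_fun = NULL, cumhaz_fun = NULL,
                            grid_size = 400) {
  spec <- list(
    fit = function(data, idx, seed = NULL) {
      if (inherits(data, "survival_trial")) {
        if (is.null(surv_fun)) stop("surv_fun required for survival data")
        grid <- seq(data$L / grid_size, data$L, length.out = grid_size)
        curves <- function(Xnew, a) {
          Xnew <- rbind(Xnew)
          surv <- vapply(grid, function(t) surv_fun(t, Xnew, a),
                         numeric(nrow(Xnew)))
          list(times = grid, surv = rbind(surv))
        }
        cens <- list(
          times = grid,
          cumhaz = function(Xnew, Anew) {
            Xnew <- rbind(Xnew)
            H <- vapply(grid, function(t) {
              h <- cumhaz_fun(t, Xnew, Anew)
              rep_len(as.numeric(h), nrow(Xnew))
            }, numeric(nrow(Xnew)))
            rbind(H)
          }
        )
        class(cens) <- "censoring_fit"
        new_nuisance_fit(pi_hat = function(Xn) pi_fun(rbind(Xn)),
                         surv = curves, cens = cens,
                         c0_hat = c0_fun, tau_hat = tau_fun,
                         n_hist = length(idx))
      } else {
        new_nuisance_fit(pi_hat = function(Xn) pi_fun(rbind(Xn)),
                         c0_hat = function(Xn) c0_fun(rbind(Xn)),
                         tau_hat = function(Xn) tau_fun(rbind(Xn)),
                         n_hist = length(idx))
      }
    }
  )
  class(spec) <- "nuisance_spec"
  spec
}

new_nuisance_fit <- function(pi_hat, c0_hat = NULL, tau_hat = NULL,
                             surv = NULL, cens = NULL, n_hist = NA_integer_,
                             c0_tau_all = NULL, curves_all = NULL) {
  structure(
    list(pi_hat = pi_hat, c0_hat = c0_hat, tau_hat = tau_hat,
         surv = surv, cens = cens, n_hist = n_hist,
         c0_tau_all = c0_tau_all, curves_all = curves_all),
    class = "nuisance_fit"
  )
}

resolve_nuisance <- function(nuisance, num_trees = 300, min_node = NULL) {
  if (inherits(nuisance, "nuisance_spec")) return(nuisance)
  if (is.character(nuisance) && nuisance == "forest")
    return(forest_nuisance(num_trees = num_trees, min_node = min_node))
  stop("nuisance must be \"forest\" or a nuisance_spec object")
}

# ---- per-subject nuisance components ---------------------------------------

# Evaluates the frozen fit at every subject of `data`, returning the
# per-subject quantities the score functions need. Truncation events (floors
# binding on pi or Kc) are counted.
nuisance_components <- function(data, fit, eps_pi = EPS_PI, eps_K = EPS_K,
                                eps_S = EPS_S) {
  n <- data$n
  pi_raw <- fit$pi_hat(data$X)
  pi <- clip(pi_raw, eps_pi, 1 - eps_pi)
  trunc_pi <- sum(pi != pi_raw)

  if (!inherits(data, "survival_trial")) {
    if (!is.null(fit$c0_tau_all)) {
      ct <- fit$c0_tau_all(data)
      return(list(pi = pi, c0 = ct$c0, tau = ct$tau,
                  trunc = c(pi = trunc_pi, kc = 0L)))
    }
    return(list(pi = pi, c0 = fit$c0_hat(data$X), tau = fit$tau_hat(data$X),
                trunc = c(pi = trunc_pi, kc = 0L)))
  }

  L <- data$L
  cv0 <- if (!is.null(fit$curves_all)) fit$curves_all(data, 0)
         else fit$surv(data$X, 0)
  cv1 <- if (!is.null(fit$curves_all)) fit$curves_all(data, 1)
         else fit$surv(data$X, 1)
  v0 <- rmst_integral(cv0$times, cv0$surv, L)
  v1 <- rmst_integral(cv1$times, cv1$surv, L)
  c0 <- v0
  tau <- v1 - v0

  # conditional censoring hazard at each subject's own covariates/arm
  H <- fit$cens$cumhaz(data$X, data$A)
  ctimes <- fit$cens$times
  kc_ul <- rep(1, n)
  aug <- numeric(0)
  trunc_kc <- 0L
  if (length(ctimes)) {
    idx_ul <- findInterval(data$UL, ctimes)
    H_ul <- cbind(0, H)[cbind(seq_len(n), idx_ul + 1L)]
    kc_ul_raw <- exp(-H_ul)
    kc_ul <- pmax(kc_ul_raw, eps_K)
    trunc_kc <- trunc_kc + sum(kc_ul != kc_ul_raw)

    Kc <- exp(-H)
    floored <- Kc < eps_K
    Kc <- pmax(Kc, eps_K)
    dH <- t(diff(t(cbind(0, H))))
    # m(r | X_i, A_i) at each hazard step and at UL_i, on the own-arm curve
    M <- matrix(0, n, length(ctimes))
    m_ul <- numeric(n)
    for (a in 0:1) {
      rows <- which(data$A == a)
      if (!length(rows)) next
      cv <- if (a == 0) cv0 else cv1
      sub <- cv$surv[rows, , drop = FALSE]
      M[rows, ] <- rmst_after(cv$times, sub, pmin(ctimes, L), L, eps_S = eps_S)
      m_ul[rows] <- diag_rmst_at(cv$times, sub, data$UL[rows], L, eps_S)
    }
    at_risk <- outer(data$UL, ctimes, `>=`)
    trunc_kc <- trunc_kc + sum(floored & at_risk)
    term2 <- rowSums(dH / Kc * M * at_risk)
    aug <- (1 - data$DeltaL) * m_ul / kc_ul - term2
  } else {
    aug <- rep(0, n)
  }
  list(pi = pi, c0 = c0, tau = tau, kc_ul = kc_ul, aug = aug,
       trunc = c(pi = trunc_pi, kc = trunc_kc))
}

# m(r_i) where each row i has its own landmark r_i (diagonal of rmst_after).
diag_rmst_at <- function(times, surv, r, L, eps_S = EPS_S) {
  surv <- rbind(surv)
  K <- length(times)
  if (K == 0L) return(pmax(rep(L, nrow(surv)), r))
  jump <- cbind(1, surv[, -K, drop = FALSE]) - surv
  w <- sweep(jump, 2L, times * (times <= L), `*`)
  cum <- t(apply(w, 1L, cumsum))
  idx <- findInterval(r, times)
  n <- nrow(surv)
  tail_sum <- cum[, K] - cbind(0, cum)[cbind(seq_len(n), idx + 1L)]
  s_L <- as.vector(step_surv_at(times, surv, L))
  s_r <- pmax(cbind(1, surv)[cbind(seq_len(n), idx + 1L)], eps_S)
  m <- (tail_sum + L * s_L) / s_r
  pmax(pmin(m, L), r)
}
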