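# Per-observation value-difference scores. Each score estimates, in
# expectation, Psi(d_opt) = V(d_opt) - V(0): the value of following the
# estimated optimal rule d(x) = 1(tau(x) > 0) minus the value of giving
# everyone control. All functions are vectorized over observations and take
# *frozen* nuisance values (propensity pi, control mean/RMST c0, CATE tau,
# and for censored data the censoring survival Kc at the truncated time and
# the censoring-martingale augmentation).
#
# Tie rule: tau(x) = 0 assigns control (d = 0), so the strict inequality
# tau > 0 defines the regime throughout.

regime_parts <- function(a, pi, tau) {
  d <- as.numeric(tau > 0)
  list(
    d = d,
    ind = as.numeric(a == d),          # 1{A = d(X)}
    pi_a = a * pi + (1 - a) * (1 - pi) # pi_A(X)
  )
}

#' Inverse-probability-weighted value-difference score (uncensored)
#'
#' `S_IPW = 1{A=d}/pi_A * Y - (1{A=d}/pi_A - 1) * (C0 + tau * d)
#'          - 1{A=0}/(1-pi) * Y`, with `d = 1(tau > 0)`.
#'
#' @param a Treatment indicators in {0, 1}.
#' @param y Outcomes.
#' @param pi Propensity values in (0, 1) (already clipped).
#' @param c0 Control conditional-mean values.
#' @param tau CATE values.
#' @return Numeric score vector.
#' @export
score_ipw <- function(a, y, pi, c0, tau) {
  rp <- regime_parts(a, pi, tau)
  aug <- c0 + tau * rp$d
  rp$ind / rp$pi_a * y - (rp$ind / rp$pi_a - 1) * aug -
    (a == 0) / (1 - pi) * y
}

#' Augmented IPW value-difference score (uncensored)
#'
#' Adds the control-arm regression augmentation
#' `(1{A=0}/(1-pi) - 1) * C0` to [score_ipw()]. When `tau <= 0` for every
#' subject the augmented score is identically zero (the degeneracy that
#' motivates the one-step procedure in the regular setting).
#'
#' @inheritParams score_ipw
#' @export
score_aipw <- function(a, y, pi, c0, tau) {
  score_ipw(a, y, pi, c0, tau) + ((a == 0) / (1 - pi) - 1) * c0
}

#' IPW value-difference score on the RMST scale (censored)
#'
#' `S_IPWS = DeltaL * 1{A=d} / (Kc(UL) pi_A) * UL
#'           - (1{A=d}/pi_A - 1) * zeta * (C0 + tau * d)
#'           - DeltaL * 1{A=0} / (Kc(UL) (1-pi)) * UL`.
#' The perturbation `zeta` equals 1 for the plain IPW estimator and a
#' mean-one positive draw for the augmented estimators.
#'
#' @inheritParams score_ipw
#' @param ul Truncated observed times `min(U, L)`.
#' @param delta_l Truncated event indicators.
#' @param kc_ul Censoring survival `Kc(UL | X, A)`, floored away from zero.
#' @param zeta Perturbation factor(s); default 1.
#' @export
score_ipw_surv <- function(a, ul, delta_l, kc_ul, pi, c0, tau, zeta = 1) {
  rp <- regime_parts(a, pi, tau)
  aug <- c0 + tau * rp$d
  delta_l * rp$ind / (kc_ul * rp$pi_a) * ul -
    (rp$ind / rp$pi_a - 1) * zeta * aug -
    delta_l * (a == 0) / (kc_ul * (1 - pi)) * ul
}

#' Augmented IPW score on the RMST scale (censored)
#'
#' [score_ipw_surv()] with the perturbation `zeta` in its middle term, plus
#' the control-arm augmentation `(1{A=0}/(1-pi) - 1) * C0`.
#'
#' @inheritParams score_ipw_surv
#' @export
score_aipw_surv <- function(a, ul, delta_l, kc_ul, pi, c0, tau, zeta = 1) {
  score_ipw_surv(a, ul, delta_l, kc_ul, pi, c0, tau, zeta = zeta) +
    ((a == 0) / (1 - pi) - 1) * c0
}

#' Censoring-augmented doubly robust score on the RMST scale
#'
#' Adds the censoring-martingale augmentation to [score_aipw_surv()]. The two
#' augmentation integrals (under the estimated optimal regime and under the
#' all-control regime) share the same integral value and differ only in their
#' weights, so the addition is
#' `(1{A=d}/pi_A - 1{A=0}/(1-pi)) * augmentation`.
#'
#' @inheritParams score_aipw_surv
#' @param aug Censoring-martingale augmentation values, see
#'   [censoring_augmentation()].
#' @export
score_caipw_surv <- function(a, ul, delta_l, kc_ul, pi, c0, tau, zeta = 1,
                             aug = 0) {
  rp <- regime_parts(a, pi, tau)
  score_aipw_surv(a, ul, delta_l, kc_ul, pi, c0, tau, zeta = zeta) +
    (rp$ind / rp$pi_a - (a == 0) / (1 - pi)) * aug
}

# Dispatch: score vector for all subjects of `data` under `estimator`,
# given per-subject nuisance components `comp` and perturbations `zeta`.
score_all <- function(data, estimator, comp, zeta = 1) {
  switch(estimator,
    ipw = score_ipw(data$A, data$Y, comp$pi, comp$c0, comp$tau),
    aipw = score_aipw(data$A, data$Y, comp$pi, comp$c0, comp$tau),
    ipws = score_ipw_surv(data$A, data$UL, data$DeltaL, comp$kc_ul,
                          comp$pi, comp$c0, comp$tau, zeta = 1),
    aipws = score_aipw_surv(data$A, data$UL, data$DeltaL, comp$kc_ul,
                            comp$pi, comp$c0, comp$tau, zeta = zeta),
    caipws = score_caipw_surv(data$A, data$UL, data$DeltaL, comp$kc_ul,
                              comp$pi, comp$c0, comp$tau, zeta = zeta,
                              aug = comp$aug),
    stop("unknown estimator: ", estimator)
  )
}
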