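# Independent reference evaluators used as oracles. Scalar, branch-by-branch
# transliterations of the score formulas and direct martingale sums; kept
# deliberately separate from the vectorized implementation paths.

ref_score_ipw_one <- function(a, y, pi, c0, tau) {
  d <- if (tau > 0) 1 else 0
  ind <- if (a == d) 1 else 0
  pi_a <- if (a == 1) pi else 1 - pi
  t1 <- ind / pi_a * y
  t2 <- (ind / pi_a - 1) * (c0 + tau * d)
  t3 <- (if (a == 0) 1 else 0) / (1 - pi) * y
  t1 - t2 - t3
}

ref_score_aipw_one <- function(a, y, pi, c0, tau) {
  corr <- ((if (a == 0) 1 else 0) / (1 - pi) - 1) * c0
  ref_score_ipw_one(a, y, pi, c0, tau) + corr
}

ref_score_ipws_one <- function(a, ul, dl, kc, pi, c0, tau, zeta = 1) {
  d <- if (tau > 0) 1 else 0
  ind <- if (a == d) 1 else 0
  pi_a <- if (a == 1) pi else 1 - pi
  t1 <- dl * ind / (kc * pi_a) * ul
  t2 <- (ind / pi_a - 1) * zeta * (c0 + tau * d)
  t3 <- dl * (if (a == 0) 1 else 0) / (kc * (1 - pi)) * ul
  t1 - t2 - t3
}

ref_score_aipws_one <- function(a, ul, dl, kc, pi, c0, tau, zeta = 1) {
  corr <- ((if (a == 0) 1 else 0) / (1 - pi) - 1) * c0
  ref_score_ipws_one(a, ul, dl, kc, pi, c0, tau, zeta) + corr
}

# Censoring-augmented score with the two augmentation integrals written as
# separately weighted terms (the printed form).
ref_score_caipws_one <- function(a, ul, dl, kc, pi, c0, tau, zeta, mart_int) {
  d <- if (tau > 0) 1 else 0
  ind <- if (a == d) 1 else 0
  pi_a <- if (a == 1) pi else 1 - pi
  w_opt <- ind / pi_a
  w_ctrl <- (if (a == 0) 1 else 0) / (1 - pi)
  ref_score_aipws_one(a, ul, dl, kc, pi, c0, tau, zeta) +
    w_opt * mart_int - w_ctrl * mart_int
}

# Direct evaluation of the censoring-martingale integral over (0, L]:
# integral of dNc(r)/Kc(r) m(r) minus integral of Y(r) dLambda(r)/Kc(r) m(r),
# with Nc jumping at U when the subject is censored before L and the at-risk
# process Y(r) = 1(U >= r), on the hazard's step grid.
ref_mart_integral <- function(u, delta, L, haz_times, haz_values, m_fun,
                              eps_K = 0.01) {
  kc_at <- function(t) {
    H <- if (length(haz_times)) c(0, haz_values)[findInterval(t, haz_times) + 1L]
         else 0
    max(exp(-H), eps_K)
  }
  counting <- 0
  if (delta == 0 && u < L) counting <- m_fun(u) / kc_at(u)
  comp <- 0
  dH <- diff(c(0, haz_values))
  for (k in seq_along(haz_times)) {
    r <- haz_times[k]
    if (r <= L && u >= r)  # at-risk indicator Y(r)
      comp <- comp + dH[k] / kc_at(r) * m_fun(r)
  }
  counting - comp
}

# Closed forms for exponential survival: E[min(T, L)] and
# E[min(T, L) | T >= r].
exp_rmst <- function(lambda, L) (1 - exp(-lambda * L)) / lambda
exp_rmst_after <- function(lambda, r, L) r + (1 - exp(-lambda * (L - r))) / lambda

# Step-curve discretization of an exponential survival function on (0, L].
exp_curve <- function(lambda, L, k = 2000) {
  times <- seq(L / k, L, length.out = k)
  list(times = times, surv = exp(-lambda * times))
}

# Mixed grid of score inputs for exhaustive small-grid comparisons.
score_case_grid <- function() {
  expand.grid(a = c(0, 1), y = c(-1.5, 0.7, 3), pi = c(0.3, 0.5),
              c0 = c(-1, 2), tau = c(-0.8, 0, 1.2))
}
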