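test_that("uncensored scores match hand evaluations and the scalar oracle", {
  # hand-computed cases
  expect_equal(score_ipw(1, 2, 0.5, 1, 1), 2)
  expect_equal(score_ipw(0, 3, 0.5, 2, -1), -2)
  expect_equal(score_aipw(0, 3, 0.5, 2, -1), 0)
  expect_equal(score_aipw(1, 2, 0.5, 1, 1), 1)

  g <- score_case_grid()
  got_ipw <- score_ipw(g$a, g$y, g$pi, g$c0, g$tau)
  got_aipw <- score_aipw(g$a, g$y, g$pi, g$c0, g$tau)
  for (i in seq_len(nrow(g))) {
    expect_equal(got_ipw[i],
                 ref_score_ipw_one(g$a[i], g$y[i], g$pi[i], g$c0[i], g$tau[i]))
    expect_equal(got_aipw[i],
                 ref_score_aipw_one(g$a[i], g$y[i], g$pi[i], g$c0[i], g$tau[i]))
  }
})

test_that("augmented score degenerates to exactly zero when no one benefits", {
  set.seed(81)
  n <- 200
  a <- rbinom(n, 1, 0.4)
  y <- rnorm(n, 3)
  pi <- runif(n, 0.2, 0.8)
  c0 <- rnorm(n)
  tau <- -runif(n)          # tau <= 0 everywhere (includes exact zeros)
  tau[1:50] <- 0
  expect_equal(score_aipw(a, y, pi, c0, tau), rep(0, n))
  expect_false(isTRUE(all.equal(mean(score_ipw(a, y, pi, c0, tau)), 0)))
  # survival analogue at zeta = 1
  expect_equal(score_aipw_surv(a, y + 4, rbinom(n, 1, 0.8), runif(n, 0.5, 1),
                               pi, c0, tau, zeta = 1), rep(0, n))
})

test_that("survival scores reduce to uncensored scores without censoring", {
  g <- score_case_grid()
  ipws <- score_ipw_surv(g$a, ul = g$y, delta_l = 1, kc_ul = 1,
                         g$pi, g$c0, g$tau, zeta = 1)
  aipws <- score_aipw_surv(g$a, ul = g$y, delta_l = 1, kc_ul = 1,
                           g$pi, g$c0, g$tau, zeta = 1)
  expect_equal(ipws, score_ipw(g$a, g$y, g$pi, g$c0, g$tau))
  expect_equal(aipws, score_aipw(g$a, g$y, g$pi, g$c0, g$tau))

  # term-by-term scalar oracle, censored branch included
  set.seed(82)
  for (i in 1:25) {
    a <- rbinom(1, 1, 0.5); ul <- runif(1, 0, 10); dl <- rbinom(1, 1, 0.6)
    kc <- runif(1, 0.3, 1); pi <- runif(1, 0.2, 0.8)
    c0 <- rnorm(1, 5); tau <- rnorm(1); z <- rexp(1)
    expect_equal(score_ipw_surv(a, ul, dl, kc, pi, c0, tau),
                 ref_score_ipws_one(a, ul, dl, kc, pi, c0, tau))
    expect_equal(score_aipw_surv(a, ul, dl, kc, pi, c0, tau, zeta = z),
                 ref_score_aipws_one(a, ul, dl, kc, pi, c0, tau, z))
  }
  # middle-term-only case: censored subject following the rule
  expect_equal(score_ipw_surv(1, 5, 0, 0.9, 0.5, 2, 1), -(1 / 0.5 - 1) * 3)
})

test_that("scores are linear in the perturbation factor", {
  set.seed(83)
  a <- 1; ul <- 6; dl <- 1; kc <- 0.8; pi <- 0.4; c0 <- 3; tau <- 0.5
  base <- score_aipw_surv(a, ul, dl, kc, pi, c0, tau, zeta = 1)
  z <- rexp(10000)
  draws <- score_aipw_surv(a, ul, dl, kc, pi, c0, tau, zeta = z)
  expect_lt(abs(mean(draws) - base), 3 * sd(draws) / sqrt(length(z)))
  # exact linearity: value at the mean equals mean of values
  expect_equal(score_aipw_surv(a, ul, dl, kc, pi, c0, tau, zeta = mean(z)),
               mean(draws))
})

test_that("censoring-augmented score matches the printed two-integral form", {
  # null augmentation: identical to the augmented score
  g <- score_case_grid()
  expect_equal(score_caipw_surv(g$a, g$y, 1, 1, g$pi, g$c0, g$tau,
                                zeta = 1, aug = 0),
               score_aipw_surv(g$a, g$y, 1, 1, g$pi, g$c0, g$tau, zeta = 1))
  # weight algebra: control subject under rule d = 0 gets zero net weight
  expect_equal(score_caipw_surv(0, 4, 1, 0.7, 0.4, 2, -1, zeta = 1, aug = 9),
               score_aipw_surv(0, 4, 1, 0.7, 0.4, 2, -1, zeta = 1))

  # 10-subject fixture with a 2-step hazard: term-by-term oracle at 1e-10
  set.seed(84)
  L <- 12
  haz_times <- c(3, 7); haz_vals <- c(0.2, 0.5)
  for (i in 1:10) {
    a <- rbinom(1, 1, 0.5); u <- runif(1, 1, 15); delta <- rbinom(1, 1, 0.6)
    ul <- min(u, L); dl <- if (u >= L) 1 else delta
    pi <- runif(1, 0.3, 0.7); c0 <- runif(1, 4, 8); tau <- rnorm(1)
    z <- rexp(1); lam <- runif(1, 0.05, 0.2)
    m_fun <- function(r) exp_rmst_after(lam, r, L)
    H_ul <- c(0, haz_vals)[findInterval(ul, haz_times) + 1]
    kc <- max(exp(-H_ul), 0.01)
    aug <- censoring_augmentation(ul, dl, haz_times, haz_vals, m_fun)
    mart <- ref_mart_integral(u, delta, L, haz_times, haz_vals, m_fun)
    expect_equal(aug, mart, tolerance = 1e-10)
    expect_equal(
      score_caipw_surv(a, ul, dl, kc, pi, c0, tau, zeta = z, aug = aug),
      ref_score_caipws_one(a, ul, dl, kc, pi, c0, tau, z, mart),
      tolerance = 1e-10)
  }
})

test_that("scores are unbiased for the value difference under oracle nuisances", {
  # uncensored: Psi(d_opt) = c * P(effect subgroup)
  set.seed(85)
  n <- 20000
  d <- gen_model1(n, c = 0.5)
  tr <- attr(d, "truth")
  psi_true <- 0.5 * (1 - 0.5787)   # c * P(tau > 0), analytic
  for (fn in list(score_ipw, score_aipw)) {
    s <- fn(d$A, d$Y, tr$pi_fun(d$X), tr$c0_fun(d$X), tr$tau_fun(d$X))
    expect_lt(abs(mean(s) - psi_true), 3 * sd(s) / sqrt(n))
  }
})

test_that("censoring-augmented score is doubly robust to a wrong survival model", {
  # T | X, A exponential-like AFT with a uniformly beneficial treatment;
  # survival/m model deliberately misspecified as a constant-hazard fit,
  # while the propensity and the censoring law are correct.
  set.seed(86)
  n <- 10000
  L <- 15
  X1 <- rnorm(n)
  A <- rbinom(n, 1, 0.5)
  mu <- 1 + 0.3 * X1 + 0.5 * A
  T_time <- exp(mu) * rexp(n)        # exponential given X, A
  rho <- 0.04
  C <- rexp(n, rho)
  U <- pmin(T_time, C); Delta <- as.numeric(T_time <= C)
  ul <- pmin(U, L); dl <- ifelse(U >= L, 1, Delta)

  # truth for the target: V(d_opt) - V(0) with d_opt = 1 everywhere
  set.seed(87)
  Xmc <- rnorm(2e5)
  Zmc <- rexp(2e5)
  psi_true <- mean(pmin(exp(1 + 0.3 * Xmc + 0.5) * Zmc, L)) -
    mean(pmin(exp(1 + 0.3 * Xmc) * Zmc, L))

  # misspecified arm-wise constant hazards (ignore X)
  lam_hat <- vapply(0:1, function(a)
    sum(Delta[A == a]) / sum(U[A == a]), numeric(1))
  lam_i <- lam_hat[A + 1]
  c0_mis <- rep(exp_rmst(lam_hat[1], L), n)
  tau_mis <- rep(exp_rmst(lam_hat[2], L) - exp_rmst(lam_hat[1], L), n)
  stopifnot(tau_mis[1] > 0)  # regime still d = 1 everywhere (correct sign)

  kc_ul <- pmax(exp(-rho * ul), 0.01)
  grid <- seq(L / 800, L, length.out = 800)
  aug <- vapply(seq_len(n), function(i) {
    censoring_augmentation(ul[i], dl[i], grid, rho * grid,
                           function(r) exp_rmst_after(lam_i[i], r, L))
  }, numeric(1))
  s <- score_caipw_surv(A, ul, dl, kc_ul, rep(0.5, n), c0_mis, tau_mis,
                        zeta = 1, aug = aug)
  expect_lt(abs(mean(s) - psi_true), 3 * sd(s) / sqrt(n))
})
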