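test_that("treatment-blind partitions have the stated sizes and are seeded", {
  set.seed(1)
  p <- partition_sbt(100, 50, 10)
  expect_equal(p$rn, 5)
  expect_equal(length(p$initial), 50)
  expect_true(all(lengths(p$chunks) == 10))
  # remainder folds into the initial chunk
  set.seed(1)
  p2 <- partition_sbt(103, 50, 10)
  expect_equal(p2$rn, 5)
  expect_equal(length(p2$initial), 53)
  expect_setequal(c(p2$initial, unlist(p2$chunks)), 1:103)
  expect_equal(anyDuplicated(c(p2$initial, unlist(p2$chunks))), 0)
  # determinism under a fixed seed
  set.seed(9); a <- partition_sbt(100, 50, 10)
  set.seed(9); b <- partition_sbt(100, 50, 10)
  expect_identical(a, b)
  expect_error(partition_sbt(55, 50, 10), "configuration error")
})

test_that("propensity-matched partitions fix per-chunk treated counts", {
  set.seed(2)
  A <- sample(rep(c(1, 0), c(40, 60)))
  p <- partition_sap_match(A, ln = 50, m = 10, pi = 0.4)
  expect_equal(p$rn, 5)
  treated <- vapply(p$chunks, function(ix) sum(A[ix]), numeric(1))
  expect_equal(treated, rep(4, 5))   # 4 treated / 6 control at pi = 0.4
  expect_setequal(c(p$initial, unlist(p$chunks)), seq_along(A))

  A5 <- sample(rep(c(1, 0), c(50, 50)))
  p5 <- partition_sap_match(A5, 50, 10, pi = 0.5)
  expect_equal(vapply(p5$chunks, function(ix) sum(A5[ix]), numeric(1)),
               rep(5, 5))

  # non-integer m * pi: largest-remainder counts alternate and average m * pi
  A45 <- sample(rep(c(1, 0), c(90, 110)))
  p45 <- partition_sap_match(A45, 100, 10, pi = 0.45)
  t45 <- vapply(p45$chunks, function(ix) sum(A45[ix]), numeric(1))
  expect_equal(t45, c(4, 5, 4, 5, 4, 5, 4, 5, 4, 5))
  expect_equal(mean(t45), 4.5)

  expect_error(partition_sap_match(rep(c(1, 0), c(5, 95)), 50, 10, pi = 0.4),
               "treated")
})

test_that("history-conditional variance estimators match hand calculations", {
  expect_equal(chunk_variance_pooled(rep(3, 40), m = 10, q_j = 1e-4),
               sqrt(1e-4))
  expect_equal(chunk_variance_pooled(rep(c(0, 2), 20), m = 10, q_j = 1e-9),
               sqrt(1 / 10))
  set.seed(3)
  for (i in 1:100) {
    x <- rnorm(sample(10:200, 1))
    n <- length(x)
    expect_equal(chunk_variance_pooled(x, 10, 1e-12),
                 sqrt(var(x) * (n - 1) / n / 10))
  }
  expect_error(chunk_variance_pooled(numeric(0), 10, 1e-3), "empty history")

  # both arms constant at different values: stratified floors, pooled does not
  sc <- rep(c(0, 2), each = 20)
  a <- rep(c(0, 1), each = 20)
  expect_equal(chunk_variance_stratified(sc, a, 10, 0.5, 1e-9), sqrt(1e-9))
  expect_equal(chunk_variance_pooled(sc, 10, 1e-9), sqrt(1 / 10))
  # equal arm means: between-arm variation vanishes, so the stratified
  # estimate at the empirical proportion coincides with the pooled one
  set.seed(12)
  s0 <- rnorm(30); s0 <- s0 - mean(s0)
  s1 <- rnorm(20); s1 <- s1 - mean(s1)
  sc2 <- c(s0, s1)
  a2 <- rep(c(0, 1), c(30, 20))
  expect_equal(chunk_variance_stratified(sc2, a2, 10, mean(a2), 1e-12),
               chunk_variance_pooled(sc2, 10, 1e-12))
  expect_error(chunk_variance_stratified(sc, rep(1, 40), 10, 0.5, 1e-3),
               "absent")
})

test_that("pooled variance dominates the stratified variance (chunk-design gain)", {
  set.seed(4)
  for (i in 1:200) {
    n <- sample(30:300, 1)
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(a)) < 2) next
    x <- rnorm(n, mean = 2 * a * rbinom(1, 1, 0.7))
    q <- 10^runif(1, -9, -3)
    expect_gte(chunk_variance_pooled(x, 10, q) + 1e-12,
               chunk_variance_stratified(x, a, 10, mean(a), q))
  }
})

test_that("chunk combination yields the standardized statistic and decision rule", {
  # all chunk estimates zero with an active floor
  r0 <- combine_chunks(rep(0, 8), rep(sqrt(1e-3), 8))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 0.5)
  expect_false(r0$rejected)
  # single chunk with psi = sigma
  r1 <- combine_chunks(1.3, 1.3)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$p_value, 1 - pnorm(1))
  # invariants: p = 1 - Phi(T), rejection iff T > z_{1-alpha}
  set.seed(5)
  psi <- rnorm(12); sig <- rexp(12) + 0.1
  rr <- combine_chunks(psi, sig, alpha = 0.1)
  expect_equal(rr$statistic, sum(psi / sig) / sqrt(12))
  expect_equal(rr$p_value, 1 - pnorm(rr$statistic))
  expect_equal(rr$rejected, rr$statistic > qnorm(0.9))
  expect_equal(rr$psi_pooled, sum(psi / sig) / sum(1 / sig))
})

test_that("estimators at step j never read current or future chunks", {
  set.seed(6)
  d <- gen_model1(240, c = 0.4)
  set.seed(100)
  part <- partition_sbt(240, 120, 10)
  run <- function(data) {
    one_step_test(data, estimator = "aipw", partition = part,
                  num_trees = 40, seed = 7)
  }
  base <- run(d)
  # poison the final chunk's outcomes: everything up to chunk rn - 1 must be
  # bit-identical, and sigma of chunk rn (history-based) must be too
  last <- part$chunks[[part$rn]]
  d2 <- d
  d2$Y[last] <- d2$Y[last] + 1e3
  pois <- run(d2)
  rn <- part$rn
  expect_identical(base$chunk_trace[1:(rn - 1), ], pois$chunk_trace[1:(rn - 1), ])
  expect_identical(base$chunk_trace$sigma_hat[rn], pois$chunk_trace$sigma_hat[rn])
  expect_false(base$chunk_trace$psi_hat[rn] == pois$chunk_trace$psi_hat[rn])
})

test_that("statistic invariances hold under deterministic nuisances", {
  set.seed(8)
  d <- gen_model1(200, c = 0.5)
  orc <- oracle_from_design(d)
  set.seed(101)
  part <- partition_sbt(200, 100, 10)
  base <- one_step_test(d, "ipw", partition = part, nuisance = orc, seed = 1)

  # permuting subjects within each chunk leaves T unchanged
  part_perm <- part
  part_perm$chunks <- lapply(part$chunks, rev)
  perm <- one_step_test(d, "ipw", partition = part_perm, nuisance = orc,
                        seed = 1)
  expect_equal(perm$statistic, base$statistic)

  # with nuisances and variance history frozen at C0, chunk order is
  # irrelevant; with the default growing history it is not
  part_shuf <- part
  part_shuf$chunks <- part$chunks[c(5, 3, 1, 2, 4, 10, 8, 6, 7, 9)]
  frozen <- function(p) {
    one_step_test(d, "ipw", partition = p, nuisance = orc, seed = 1,
                  refit_stride = p$rn, sigma_history = "initial")
  }
  expect_equal(frozen(part_shuf)$statistic, frozen(part)$statistic)
})

test_that("oracle-nuisance null calibration keeps size at or below alpha", {
  gen <- function(n) gen_model1(n, c = -1)
  row <- monte_carlo(gen, n = 400, n_reps = 100,
                     test_args = list(estimator = "ipw",
                                      nuisance = oracle_nuisance(
                                        pi_fun = function(X) rep(0.5, nrow(X)),
                                        c0_fun = function(X)
                                          3.18 + 0.2 * X[, 1] + X[, 2] + 0.5 * X[, 3],
                                        tau_fun = function(X)
                                          -as.numeric(X[, 4] - 0.5 * X[, 2]^2 > 0))),
                     seed = 11)
  expect_lte(row$reject_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
  expect_lt(abs(row$mu), 3 * row$se_mu + 0.3)
})
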