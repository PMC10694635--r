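# The sequential one-step engine: chunking, history-conditional variance
# estimation, and the standardized test statistic.

#' Treatment-blind sequential partition (SBT)
#'
#' Randomly permutes subjects, assigns the first `ln` (plus any remainder
#' after filling whole chunks) to the initial chunk C0, and splits the rest
#' into `rn = floor((n - ln) / m)` chunks of exactly `m`.
#'
#' @param n Number of subjects.
#' @param ln Initial-chunk size.
#' @param m Chunk size.
#' @return Object of class `"chunk_partition"`: list with `initial` (indices
#'   of C0), `chunks` (list of index vectors), `m`, `rn`.
#' @export
partition_sbt <- function(n, ln, m) {
  rn <- floor((n - ln) / m)
  if (rn < 1L) stop("configuration error: n - ln < m leaves no chunk")
  perm <- sample.int(n)
  n0 <- n - rn * m
  chunks <- split(perm[(n0 + 1L):n], rep(seq_len(rn), each = m))
  structure(list(initial = perm[seq_len(n0)], chunks = unname(chunks),
                 m = m, rn = rn),
            class = "chunk_partition")
}

#' Propensity-matched sequential partition (SAP-match)
#'
#' Assigns subjects to chunks so that every chunk's treated count matches the
#' marginal treatment probability: with `m * pi` an integer each chunk holds
#' exactly `m * pi` treated and `m (1 - pi)` control subjects; otherwise
#' per-chunk treated counts follow the largest-remainder sequence
#' `floor(j m pi) - floor((j-1) m pi)` so the average count is `m * pi`.
#' Remaining subjects form the initial chunk C0.
#'
#' @param A Treatment vector for all subjects.
#' @param ln Initial-chunk size.
#' @param m Chunk size.
#' @param pi Target treatment proportion; defaults to the sample proportion
#'   `mean(A)` (the observational-data substitution).
#' @return A `"chunk_partition"` (see [partition_sbt()]) with attribute
#'   `"treated_per_chunk"`.
#' @export
partition_sap_match <- function(A, ln, m, pi = mean(A)) {
  n <- length(A)
  rn <- floor((n - ln) / m)
  if (rn < 1L) stop("configuration error: n - ln < m leaves no chunk")
  t_per <- diff(floor(seq_len(rn) * m * pi + 1e-9))
  t_per <- c(floor(m * pi + 1e-9), t_per)
  need1 <- sum(t_per)
  need0 <- rn * m - need1
  id1 <- sample(which(A == 1))
  id0 <- sample(which(A == 0))
  if (length(id1) < need1)
    stop("infeasible SAP-match: need ", need1, " treated subjects, have ",
         length(id1))
  if (length(id0) < need0)
    stop("infeasible SAP-match: need ", need0, " control subjects, have ",
         length(id0))
  chunks <- vector("list", rn)
  p1 <- p0 <- 0L
  for (j in seq_len(rn)) {
    k1 <- t_per[j]
    k0 <- m - k1
    chunks[[j]] <- c(id1[p1 + seq_len(k1)], id0[p0 + seq_len(k0)])
    p1 <- p1 + k1
    p0 <- p0 + k0
  }
  initial <- setdiff(seq_len(n), unlist(chunks))
  structure(list(initial = initial, chunks = chunks, m = m, rn = rn),
            class = c("chunk_partition"),
            treated_per_chunk = t_per)
}

#' Pooled history-conditional SD of a chunk estimate
#'
#' Estimates the conditional standard deviation of a chunk mean of `m`
#' scores by the (population) variance of the historical score vector divided
#' by `m`, floored at `q_j` to keep the standardization finite.
#'
#' @param scores Score values of every historical subject, evaluated with the
#'   currently frozen nuisance functions.
#' @param m Chunk size.
#' @param q_j Positive floor for the variance (a sequence decreasing to 0).
#' @return `sigma_hat_j` (scalar).
#' @export
chunk_variance_pooled <- function(scores, m, q_j) {
  if (!length(scores)) stop("empty history")
  v <- mean(scores^2) - mean(scores)^2
  sqrt(max(q_j, v / m))
}

#' Arm-stratified history-conditional SD (SAP-match chunks)
#'
#' For chunks with fixed treated count `m * pi`, the conditional variance of
#' the chunk mean is the propensity-weighted mixture of within-arm score
#' variances divided by `m`. Never exceeds the pooled estimate (up to the
#' shared floor), since between-arm variation drops out.
#'
#' @inheritParams chunk_variance_pooled
#' @param a Treatment indicators of the historical subjects.
#' @param pi Treatment proportion (known value, or the sample proportion).
#' @return `sigma_hat_{j, m pi}` (scalar).
#' @export
chunk_variance_stratified <- function(scores, a, m, pi, q_j) {
  if (!length(scores)) stop("empty history")
  if (length(unique(a)) < 2L)
    stop("an arm is absent from the history; cannot stratify")
  pv <- function(x) mean(x^2) - mean(x)^2
  v1 <- pv(scores[a == 1])
  v0 <- pv(scores[a == 0])
  sqrt(max(q_j, (pi * v1 + (1 - pi) * v0) / m))
}

#' Combine chunk estimates into the one-step test statistic
#'
#' `T = rn^{-1/2} sum_j psi_j / sigma_j`, one-sided p-value `1 - Phi(T)`,
#' and the precision-weighted pooled value difference
#' `sum_j psi_j / sigma_j / sum_j 1 / sigma_j`.
#'
#' @param psi Per-chunk value-difference estimates.
#' @param sigma Per-chunk conditional-SD estimates (positive).
#' @param alpha One-sided test level.
#' @return List with `statistic`, `p_value`, `psi_pooled`, `rejected`,
#'   `alpha`, `rn`.
#' @export
combine_chunks <- function(psi, sigma, alpha = 0.05) {
  stopifnot(length(psi) == length(sigma), all(sigma > 0))
  rn <- length(psi)
  z <- psi / sigma
  T_stat <- sum(z) / sqrt(rn)
  list(statistic = T_stat,
       p_value = stats::pnorm(T_stat, lower.tail = FALSE),
       psi_pooled = sum(z) / sum(1 / sigma),
       rejected = T_stat > stats::qnorm(1 - alpha),
       alpha = alpha, rn = rn)
}

#' One-step value-difference subgroup test
#'
#' Tests the null hypothesis that no subgroup benefits from the active
#' treatment (`tau(x) <= 0` for all `x`) against the existence of a
#' positive-probability subgroup with `tau(x) > 0`. The data are split into
#' an initial chunk, on which nuisance functions are first fitted, and `rn`
#' sequential chunks of size `m`; each chunk contributes a value-difference
#' estimate standardized by a history-conditional SD, and the standardized
#' sum is asymptotically standard normal under the null — including at the
#' exceptional law where `P(tau(X) = 0) > 0`.
#'
#' @param data An `uncensored_trial` or `survival_trial`.
#' @param estimator Character vector of score estimators: `"ipw"`, `"aipw"`
#'   (uncensored) or `"ipws"`, `"aipws"`, `"caipws"` (survival). Several can
#'   be computed in one pass over shared nuisance fits.
#' @param chunking `"sbt"` (treatment-blind random chunks, pooled variance)
#'   or `"sap-match"` (fixed per-chunk treated counts, arm-stratified
#'   variance).
#' @param m Chunk size.
#' @param ln Initial-chunk size; default `floor(n / 2)`.
#' @param alpha One-sided level.
#' @param refit_stride Refit nuisances every `refit_stride` chunks. The fit
#'   used at chunk `j` is always based on a subset of the history before `j`,
#'   so validity is unaffected; values above 1 trade adaptation for compute.
#' @param nuisance `"forest"` (default, see [forest_nuisance()]) or a
#'   `nuisance_spec` such as [oracle_nuisance()].
#' @param num_trees,min_node Forwarded to [forest_nuisance()] when
#'   `nuisance = "forest"`.
#' @param q_floor Function `j -> q_j`, the positive variance floor sequence.
#' @param pi Treatment proportion for SAP-match composition and the
#'   stratified variance; default: the known randomization probability if the
#'   data carry one, else the sample proportion of treated.
#' @param seed Master seed; separate substreams are derived for the
#'   partition, the perturbation draws and the forests.
#' @param partition Optional pre-built `"chunk_partition"` (overrides
#'   `chunking`'s random allocation but not its variance estimator).
#' @param sigma_history `"cumulative"` (default) evaluates the variance over
#'   the full history before chunk j; `"initial"` freezes it at C0, which
#'   together with `refit_stride >= rn` makes the statistic invariant to
#'   chunk order.
#' @return If one estimator is requested, a `"value_diff_test"`; otherwise a
#'   named list of them (class `"value_diff_tests"`). Each result carries the
#'   statistic `T`, one-sided `p_value`, pooled estimate `psi_pooled`, the
#'   per-chunk trace and configuration echo.
#' @examples
#' set.seed(7)
#' d <- gen_model1(300, c = 0.8)
#' one_step_test(d, estimator = "aipw", num_trees = 50, seed = 1)
#' @export
one_step_test <- function(data,
                          estimator,
                          chunking = c("sbt", "sap-match"),
                          m = 10,
                          ln = NULL,
                          alpha = 0.05,
                          refit_stride = 1L,
                          nuisance = "forest",
                          num_trees = 300,
                          min_node = NULL,
                          q_floor = function(j) 1e-3 / j,
                          pi = NULL,
                          seed = NULL,
                          partition = NULL,
                          sigma_history = c("cumulative", "initial")) {
  stopifnot(inherits(data, "trial_data"))
  chunking <- match.arg(chunking)
  sigma_history <- match.arg(sigma_history)
  survival <- inherits(data, "survival_trial")
  valid <- if (survival) c("ipws", "aipws", "caipws") else c("ipw", "aipw")
  bad <- setdiff(estimator, valid)
  if (length(bad))
    stop("estimator(s) ", paste(bad, collapse = ", "), " incompatible with ",
         if (survival) "survival" else "continuous", " outcome")
  n <- data$n
  if (is.null(ln)) ln <- floor(n / 2)
  if (n - ln < m) stop("configuration error: n - ln < m")
  spec <- resolve_nuisance(nuisance, num_trees = num_trees,
                           min_node = min_node)
  if (is.null(pi))
    pi <- if (!is.null(data$known_pi)) data$known_pi else mean(data$A)

  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(2^30, 3)

  if (is.null(partition)) {
    set.seed(sub_seeds[1])
    partition <- if (chunking == "sbt") partition_sbt(n, ln, m)
                 else partition_sap_match(data$A, ln, m, pi = pi)
  }
  rn <- partition$rn

  zeta <- rep(1, n)
  if (survival && any(estimator %in% c("aipws", "caipws"))) {
    set.seed(sub_seeds[2])
    zeta <- stats::rexp(n)
  }

  hist_idx <- partition$initial
  psi <- sigma <- matrix(NA_real_, rn, length(estimator),
                         dimnames = list(NULL, estimator))
  n_hist <- integer(rn)
  trunc <- c(pi = 0L, kc = 0L)
  comp <- NULL
  for (j in seq_len(rn)) {
    if (is.null(comp) || (j - 1L) %% refit_stride == 0L) {
      fit <- spec$fit(data, hist_idx, seed = sub_seeds[3] + j)
      comp <- nuisance_components(data, fit)
      trunc <- trunc + comp$trunc
    }
    cj <- partition$chunks[[j]]
    q_j <- q_floor(j)
    h_idx <- if (sigma_history == "cumulative") hist_idx else partition$initial
    n_hist[j] <- length(hist_idx)
    for (est in estimator) {
      s <- score_all(data, est, comp, zeta = zeta)
      psi[j, est] <- mean(s[cj])
      sigma[j, est] <- if (chunking == "sbt") {
        chunk_variance_pooled(s[h_idx], m, q_j)
      } else {
        chunk_variance_stratified(s[h_idx], data$A[h_idx], m, pi, q_j)
      }
    }
    hist_idx <- c(hist_idx, cj)
  }

  results <- lapply(estimator, function(est) {
    cmb <- combine_chunks(psi[, est], sigma[, est], alpha = alpha)
    structure(
      c(cmb,
        list(estimator = est, chunking = chunking,
             chunk_trace = data.frame(j = seq_len(rn), psi_hat = psi[, est],
                                      sigma_hat = sigma[, est],
                                      n_hist = n_hist),
             n = n, m = m, ln = length(partition$initial),
             refit_stride = refit_stride, pi = pi, seed = seed,
             truncation = as.list(trunc),
             sigma_history = sigma_history)),
      class = "value_diff_test"
    )
  })
  names(results) <- estimator
  if (length(results) == 1L) return(results[[1]])
  structure(results, class = "value_diff_tests")
}

#' @export
print.value_diff_test <- function(x, ...) {
  cat(sprintf("One-step value-difference test (%s, %s chunking)\n",
              toupper(x$estimator), toupper(x$chunking)))
  cat(sprintf("  chunks: rn = %d of size m = %d, initial chunk %d of n = %d\n",
              x$rn, x$m, x$ln, x$n))
  cat(sprintf("  T = %.3f, one-sided p = %.4g, pooled value difference = %.4f\n",
              x$statistic, x$p_value, x$psi_pooled))
  cat(sprintf("  H0 (no benefiting subgroup) %s at alpha = %g\n",
              if (x$rejected) "REJECTED" else "not rejected", x$alpha))
  if (x$truncation$kc > 0 || x$truncation$pi > 0)
    cat(sprintf("  truncations: pi clipped %d, Kc floored %d\n",
                x$truncation$pi, x$truncation$kc))
  invisible(x)
}

#' @export
print.value_diff_tests <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}
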