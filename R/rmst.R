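# Step-function survival-curve utilities.
#
# Convention throughout: a curve is represented by sorted jump times `times`
# (> 0) and right-continuous values `surv[k] = S(times[k])`, with S(t) = 1 for
# t < times[1]. Integrals use half-open intervals [t_k, t_{k+1}).

# Integral of S(t) dt over [0, L] for each row of a curve matrix.
rmst_integral <- function(times, surv, L) {
  surv <- rbind(surv)  # allow a single curve as a vector
  starts <- c(0, times)
  ends <- c(times, Inf)
  w <- pmax(0, pmin(ends, L) - pmin(starts, L))
  as.vector(cbind(1, surv) %*% w)
}

# S(t) at scalar/vector t for each row (right-continuous; 1 before first jump).
step_surv_at <- function(times, surv, t) {
  surv <- rbind(surv)
  idx <- findInterval(t, times)
  cbind(1, surv)[, idx + 1L, drop = FALSE]
}

#' Conditional restricted mean survival time after a landmark
#'
#' Given a step-function estimate of the survival curve, evaluates
#' `m(r) = E[min(T, L) | T >= r]` as the Stieltjes sum
#' `(sum over jump times z in (r, L] of z * (-dS(z)) + L * S(L)) / S(r)`.
#' The result always lies in `[r, L]` and is nondecreasing in `r`.
#'
#' @param times Sorted positive jump times of the survival curve.
#' @param surv Right-continuous survival values at `times` (one curve).
#' @param r Landmark time(s), each in `[0, L]`.
#' @param L Restriction time.
#' @param eps_S Floor applied to `S(r)` in the denominator.
#' @return Numeric vector `m(r)` of the same length as `r`.
#' @examples
#' # single point mass at t = 5:
#' conditional_rmst(times = 5, surv = 0, r = 0, L = 10)  # 5
#' conditional_rmst(times = 5, surv = 0, r = 10, L = 10) # L
#' @export
conditional_rmst <- function(times, surv, r, L, eps_S = 1e-4) {
  if (any(r < 0) || any(r > L)) stop("landmark r must lie in [0, L]")
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  unname(drop(rmst_after(times, matrix(surv, nrow = 1), r, L, eps_S = eps_S)))
}

# m(r) for each row of a curve matrix, vectorized over r: returns a matrix
# with one row per curve and one column per landmark in r.
rmst_after <- function(times, surv, r, L, eps_S = 1e-4) {
  surv <- rbind(surv)
  K <- length(times)
  if (K == 0L) {  # jump-free curve: all mass beyond L
    m <- matrix(L, max(nrow(surv), 1L), length(r))
    return(sweep(m, 2L, r, pmax))
  }
  # jump sizes -dS at each time; S(t_0-) = 1
  jump <- cbind(1, surv[, -K, drop = FALSE]) - surv
  w <- sweep(jump, 2L, times * (times <= L), `*`)
  cum <- t(apply(w, 1L, cumsum))                   # sum of z * (-dS) for z <= r
  tot <- cum[, K]
  idx <- findInterval(r, times)
  tail_sum <- tot - cbind(0, cum)[, idx + 1L, drop = FALSE]
  s_L <- as.vector(step_surv_at(times, surv, L))
  s_r <- pmax(step_surv_at(times, surv, r), eps_S)
  m <- (tail_sum + outer(s_L, rep(L, length(r)))) / s_r
  # guard against round-off outside the feasible band [r, L]
  m <- pmin(m, L)
  sweep(m, 2L, r, pmax)
}
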