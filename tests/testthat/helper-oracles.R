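# Independent oracles used across the suite. Each reimplements the quantity
# under test by a generic route (convex programming, enumeration, direct
# formula) so the package code is checked against an independent computation.

# sparse fused-lasso objective
fl_objective <- function(y, b, lam1, lam2) {
  0.5 * sum((y - b)^2) + lam1 * sum(abs(b)) + lam2 * sum(abs(diff(b)))
}

# generic convex-program solution of the sparse fused lasso by ADMM with
# two splits (one per l1 term); early-stopped on primal residuals
admm_fused <- function(y, lam1, lam2, rho = 2, max_iter = 50000, tol = 1e-11) {
  n <- length(y)
  st <- function(a, k) sign(a) * pmax(abs(a) - k, 0)
  if (n == 1L) return(st(y, lam1))
  D <- diff(diag(n))
  A <- diag(n) + rho * crossprod(D) + rho * diag(n)
  cA <- chol(A)
  z1 <- y; z2 <- as.numeric(D %*% y)
  u1 <- numeric(n); u2 <- numeric(n - 1L)
  for (it in seq_len(max_iter)) {
    b <- y + rho * (z1 - u1) + rho * as.numeric(crossprod(D, z2 - u2))
    beta <- backsolve(cA, forwardsolve(t(cA), b))
    z1_old <- z1; z2_old <- z2
    z1 <- st(beta + u1, lam1 / rho)
    Db <- as.numeric(D %*% beta)
    z2 <- st(Db + u2, lam2 / rho)
    u1 <- u1 + beta - z1
    u2 <- u2 + Db - z2
    if (it %% 50L == 0L &&
        max(abs(beta - z1)) < tol && max(abs(Db - z2)) < tol &&
        max(abs(z1 - z1_old)) < tol && max(abs(z2 - z2_old)) < tol) break
  }
  z1
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties assumed)
wilcox_enum_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n2 <- length(x2)
  r <- rank(pooled)
  u_obs <- sum(r[(length(x1) + 1):length(pooled)]) - n2 * (n2 + 1) / 2
  mu <- length(x1) * n2 / 2
  sets <- utils::combn(length(pooled), n2)
  us <- apply(sets, 2L, function(idx) sum(r[idx]) - n2 * (n2 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# 1-D Cox partial likelihood (no ties) for a single covariate, maximized by
# golden-section search: the written-out product over risk sets
cox_grid_mle <- function(time, event, x, lower = -6, upper = 6) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(lower, upper), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# direct Aalen-Johansen computation for a small fixture: loops over event
# times applying S(t-) * d_k / n
aalen_johansen_hand <- function(time, status, cause) {
  ut <- sort(unique(time[status != 0]))
  s_prev <- 1
  cif <- 0
  out_t <- numeric(0); out_cif <- numeric(0)
  for (tt in ut) {
    n_risk <- sum(time >= tt)
    d_all <- sum(time == tt & status != 0)
    d_k <- sum(time == tt & status == cause)
    cif <- cif + s_prev * d_k / n_risk
    s_prev <- s_prev * (1 - d_all / n_risk)
    out_t <- c(out_t, tt); out_cif <- c(out_cif, cif)
  }
  list(time = out_t, cif = out_cif)
}

# two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, summing those with probability <= observed
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x)
    stats::dhyper(x, m1, m2, k), numeric(1L))
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
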