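# Independent oracles used to cross-check the package's own solvers.

# Brute-force solver for the SVM dual QP
#   min 1/2 a' Q a - e' a,  y'a = 0,  0 <= a <= C
# via kernlab's interior-point QP solver, then polished by solving the
# equality-constrained KKT system on the free set exactly.  Fully
# independent of the package's SMO path.
qp_dual_oracle <- function(K, y, C, ridge = 1e-9) {
  n <- length(y)
  Q <- outer(y, y) * K
  ip <- kernlab::ipop(c = rep(-1, n), H = Q + diag(ridge, n),
                      A = matrix(y, 1), b = 0,
                      l = rep(0, n), u = rep(C, n), r = 0,
                      sigf = 7, maxiter = 100)
  a <- kernlab::primal(ip)
  # active-set refinement seeded by the interior-point iterate: solve the
  # equality-constrained KKT system on the free set exactly, then repair
  # the working set until the full KKT conditions hold
  eps <- 1e-5 * C
  state <- ifelse(a < eps, 0L, ifelse(a > C - eps, 2L, 1L)) # 0=lo,1=free,2=hi
  best <- NULL
  for (pass in 1:200) {
    free <- state == 1L; hi <- state == 2L
    a <- numeric(n); a[hi] <- C
    nu <- 0
    if (any(free)) {
      g <- drop(Q[free, hi, drop = FALSE] %*% rep(C, sum(hi))) - 1
      M <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      sol <- tryCatch(solve(M, c(-g, -sum(y[hi]) * C)),
                      error = function(e) NULL)
      if (is.null(sol)) break
      a[free] <- sol[seq_len(sum(free))]
      nu <- sol[sum(free) + 1]
    }
    # box violations among free variables: clamp the worst one
    viol_lo <- which(free)[a[free] < -1e-10]
    viol_hi <- which(free)[a[free] > C + 1e-10]
    if (length(viol_lo) + length(viol_hi) > 0) {
      if (length(viol_lo) > 0 &&
          (length(viol_hi) == 0 || min(a[viol_lo]) < -max(a[viol_hi] - C))) {
        state[viol_lo[which.min(a[viol_lo])]] <- 0L
      } else {
        state[viol_hi[which.max(a[viol_hi])]] <- 2L
      }
      next
    }
    # stationarity of bound variables: s_r = (Qa - 1 + nu y)_r
    s <- drop(Q %*% pmin(pmax(a, 0), C)) - 1 + nu * y
    bad_lo <- which(state == 0L & s < -1e-9)
    bad_hi <- which(state == 2L & s > 1e-9)
    if (length(bad_lo) + length(bad_hi) == 0) { best <- a; break }
    cand <- c(bad_lo, bad_hi)
    worst <- cand[which.max(abs(s[cand]))]
    state[worst] <- 1L
  }
  if (is.null(best)) best <- pmin(pmax(a, 0), C)  # fall back to last iterate
  obj <- 0.5 * drop(t(best) %*% Q %*% best) - sum(best)
  list(lambda = best, objective = obj)
}

# a small well-separated binary task in PC-score space
make_binary_task <- function(n_per = 12, J = 2, gap = 4, seed = 1) {
  set.seed(seed)
  Z <- rbind(matrix(rnorm(n_per * J), n_per) + gap / 2,
             matrix(rnorm(n_per * J), n_per) - gap / 2)
  list(Z = Z, y = rep(c(1, -1), each = n_per))
}
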