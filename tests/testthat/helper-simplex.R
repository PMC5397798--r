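# Dense two-phase tableau simplex, used as an independent oracle for tiny
# LP instances:  min c'x  s.t.  A x <= b,  x >= 0  (b may be negative).
# The right-hand side is perturbed lexicographically so bases stay
# non-degenerate (no cycling under the Dantzig rule), ratio-test ties take
# the largest pivot element (numerical stability), and the returned vertex
# is re-verified against the unperturbed system.

simplexLP <- function(obj, A, b, tol = 1e-7, maxit = 50000L) {
  m <- nrow(A); n <- ncol(A)
  T <- cbind(A, diag(m))                  # slack form: A x + s = b
  rhs <- b
  flip <- rhs < 0
  T[flip, ] <- -T[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  rhs <- rhs + 1e-9 * seq_len(m)          # degeneracy-breaking perturbation
  nx <- n + m
  T <- cbind(T, diag(m))                  # artificials
  basis <- nx + seq_len(m)

  pivot <- function(T, rhs, basis, r, cIn) {
    pv <- T[r, cIn]
    T[r, ] <- T[r, ] / pv
    rhs[r] <- rhs[r] / pv
    upd <- which(abs(T[, cIn]) > 0)
    upd <- upd[upd != r]
    if (length(upd)) {
      f <- T[upd, cIn]
      T[upd, ] <- T[upd, , drop = FALSE] - outer(f, T[r, ])
      rhs[upd] <- rhs[upd] - f * rhs[r]
    }
    basis[r] <- cIn
    list(T = T, rhs = rhs, basis = basis)
  }

  run <- function(T, rhs, basis, costs, allowed) {
    for (it in seq_len(maxit)) {
      cb <- costs[basis]
      red <- costs - as.vector(cb %*% T)
      red[!allowed] <- Inf
      if (min(red) >= -1e-9)
        return(list(T = T, rhs = rhs, basis = basis,
                    value = sum(cb * rhs)))
      cIn <- which.min(red)               # Dantzig rule
      col <- T[, cIn]
      ok <- which(col > tol)
      if (!length(ok)) stop("oracle LP unbounded")
      ratio <- rhs[ok] / col[ok]
      near <- ok[ratio <= min(ratio) + 1e-12]
      r <- near[which.max(col[near])]     # ties: largest pivot
      p <- pivot(T, rhs, basis, r, cIn)
      T <- p$T; rhs <- p$rhs; basis <- p$basis
    }
    stop("simplex iteration limit")
  }

  phase1 <- run(T, rhs, basis, c(rep(0, nx), rep(1, m)), rep(TRUE, nx + m))
  if (phase1$value > 1e-6) stop("oracle LP infeasible")
  T <- phase1$T; rhs <- phase1$rhs; basis <- phase1$basis
  # pivot remaining basic artificials out where possible; rows whose
  # artificial cannot leave are redundant and keep it (blocked from entry)
  for (r in which(basis > nx)) {
    cand <- which(abs(T[r, seq_len(nx)]) > tol)
    if (length(cand)) {
      cIn <- cand[which.max(abs(T[r, cand]))]
      p <- pivot(T, rhs, basis, r, cIn)
      T <- p$T; rhs <- p$rhs; basis <- p$basis
    }
  }
  allowed <- c(rep(TRUE, nx), rep(FALSE, m))
  phase2 <- run(T, rhs, basis, c(obj, rep(0, m), rep(0, m)), allowed)
  x <- numeric(nx + m)
  x[phase2$basis] <- phase2$rhs
  xn <- x[seq_len(n)]
  # certify the vertex against the original system
  viol <- max(c(A %*% xn - b, -xn, 0))
  if (viol > 1e-5)
    stop("oracle simplex returned an infeasible vertex (violation ",
         format(viol), ")")
  list(value = sum(obj * xn), x = xn)
}
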