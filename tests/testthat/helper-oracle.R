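# independent oracle for the soft-margin SVM objective on tiny instances.
#
# Route 1 (QP): libsvm via e1071 (tolerance 1e-8, shrinking off — the
# shrinking heuristic is unreliable at tight tolerances), followed by an
# iterated active-set polish: given a candidate partition into free and
# bound support vectors, the KKT conditions reduce to a linear system
# whose solution is exact; the partition is re-derived from the polished
# margins and the solve repeated. Every candidate is scored by the primal
# objective with the bias minimized exactly (piecewise-linear in the bias,
# so the optimum sits at a breakpoint), and any primal value is an upper
# bound on the optimum, so the minimum over candidates is a valid oracle.

oracle_objective_from_w <- function(w, x, y, C) {
  m <- as.numeric(x %*% w)
  min(vapply(
    y - m,
    function(b) 0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (m + b))),
    numeric(1)
  ))
}

# exact KKT solve for a given free/bound partition; NULL when the system
# is singular or the solution leaves the box. With no free vector the
# candidate is the bound-only weight vector (exact when the optimal dual
# coefficients are integral multiples of C).
kkt_solve <- function(free, bnd, K, x, y, C) {
  nf <- length(free)
  if (nf == 0L) {
    if (length(bnd) == 0L) return(NULL)
    return(list(
      w = as.numeric(crossprod(x[bnd, , drop = FALSE], C * y[bnd])),
      bias = 0
    ))
  }
  A <- rbind(cbind(K[free, free, drop = FALSE], 1), c(rep(1, nf), 0))
  rhs <- c(
    y[free] - (if (length(bnd)) K[free, bnd, drop = FALSE] %*% (C * y[bnd]) else 0),
    -C * sum(y[bnd])
  )
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    # singular (degenerate) partition: any solution of the consistent
    # system is a valid candidate; take the minimum-norm one
    sol <- tryCatch(MASS::ginv(A) %*% rhs, error = function(e) NULL)
    if (is.null(sol) || max(abs(A %*% sol - rhs)) > 1e-6) return(NULL)
    sol <- as.numeric(sol)
  }
  beta <- sol[seq_len(nf)]
  alpha_f <- y[free] * beta
  if (any(alpha_f < -1e-8) || any(alpha_f > C + 1e-8)) return(NULL)
  w <- as.numeric(crossprod(x[free, , drop = FALSE], beta))
  if (length(bnd)) {
    w <- w + as.numeric(crossprod(x[bnd, , drop = FALSE], C * y[bnd]))
  }
  list(w = w, bias = sol[nf + 1])
}

svm_oracle_objective <- function(x, y, C = 10) {
  x <- as.matrix(x)
  n <- length(y)
  K <- tcrossprod(x)
  fit <- suppressWarnings(e1071::svm(
    x, factor(y),
    kernel = "linear", cost = C, scale = FALSE,
    tolerance = 1e-8, shrinking = FALSE
  ))
  alpha <- numeric(n)
  alpha[fit$index] <- abs(as.numeric(fit$coefs))
  w <- as.numeric(crossprod(x, alpha * y))
  best <- oracle_objective_from_w(w, x, y, C)
  # the zero-weight classifier (predict one class) is the optimum of some
  # degenerate instances and always a valid upper bound
  best <- min(best, oracle_objective_from_w(numeric(ncol(x)), x, y, C))

  # candidate partitions: from the dual coefficients, then re-derived from
  # polished margins at several tolerances; each candidate's primal value
  # is an upper bound on the optimum, so the minimum is a valid oracle
  try_partition <- function(free, bnd) {
    sol <- kkt_solve(free, bnd, K, x, y, C)
    if (is.null(sol)) return(NULL)
    cand <- oracle_objective_from_w(sol$w, x, y, C)
    if (cand < best) best <<- cand
    sol
  }
  sol <- try_partition(
    which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6)),
    which(alpha >= C * (1 - 1e-6))
  )
  w_ref <- if (is.null(sol)) w else sol$w
  b_ref <- if (is.null(sol)) 0 else sol$bias
  for (tol_margin in c(1e-7, 1e-5, 1e-3)) {
    m <- y * (as.numeric(x %*% w_ref) + b_ref)
    try_partition(
      which(abs(m - 1) <= tol_margin),
      which(m < 1 - tol_margin)
    )
  }
  best
}
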