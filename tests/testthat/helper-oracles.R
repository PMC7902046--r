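# Independent brute-force oracles for the constrained-optimization
# primitives. These never share code with the solvers they check.

# Row-reduce S to a maximal independent row set (both oracles need the rank).
oracle_rowbasis <- function(S) {
  qrt <- qr(t(S))
  r <- qrt$rank
  list(Se = S[sort(qrt$pivot[seq_len(r)]), , drop = FALSE], rank = r)
}

# Orthonormal null-space basis of a matrix (columns), via SVD.
oracle_nullspace <- function(A, tol = 1e-8) {
  n <- ncol(A)
  sv <- svd(A, nu = 0, nv = n)
  d <- c(sv$d, rep(0, n - length(sv$d)))
  sv$v[, d <= tol * max(d, 1), drop = FALSE]
}

# Exhaustive vertex enumeration of {S v = 0, lb <= v <= ub}: every vertex
# has (n - rank) bounds active; enumerate all subsets and all lb/ub sign
# patterns, solve for the basic coordinates, keep feasible points. Returns
# the best objective value over vertices for maximization of v[obj].
fba_vertex_oracle <- function(model, tol = 1e-7) {
  S <- model$S
  n <- ncol(S)
  rb <- oracle_rowbasis(S)
  Se <- rb$Se
  r <- nrow(Se)
  n_free <- n - r
  stopifnot(n_free >= 0)
  obj_idx <- which(model$reaction_ids == model$objective_id)
  best <- -Inf
  subsets <- utils::combn(n, n_free, simplify = FALSE)
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_free)))
  for (free in subsets) {
    basic <- setdiff(seq_len(n), free)
    SB <- Se[, basic, drop = FALSE]
    qsb <- qr(SB)
    if (qsb$rank < r) next  # degenerate basis, vertex covered elsewhere
    # all 2^f lb/ub assignments of the free coordinates at once
    fixed_vals <- matrix(model$lb[free], n_free, nrow(signs))
    fixed_vals[t(signs)] <- matrix(model$ub[free], n_free,
                                   nrow(signs))[t(signs)]
    rhs <- -Se[, free, drop = FALSE] %*% fixed_vals
    vb <- qr.solve(qsb, rhs)
    for (cc in seq_len(ncol(vb))) {
      v <- numeric(n)
      v[free] <- fixed_vals[, cc]
      v[basic] <- vb[, cc]
      if (all(v >= model$lb - tol) && all(v <= model$ub + tol)) {
        best <- max(best, v[obj_idx])
      }
    }
  }
  best
}

# Random feasible points by bounded null-space sampling: draw a direction in
# the null space of S and shrink it into the box (lb <= 0 <= ub assumed).
sample_feasible_points <- function(model, n_points, seed) {
  N <- oracle_nullspace(model$S)
  n <- ncol(model$S)
  withr::with_seed(seed, {
    lapply(seq_len(n_points), function(i) {
      v <- as.numeric(N %*% stats::rnorm(ncol(N)))
      if (max(abs(v)) < 1e-12) return(v)
      shrink <- suppressWarnings(min(
        1,
        min(model$ub[v > 1e-12] / v[v > 1e-12]),
        min(model$lb[v < -1e-12] / v[v < -1e-12])))
      v * shrink * stats::runif(1)
    })
  })
}

# Analytic equality-constrained MOMA: fix selected coordinates, project the
# reference onto the affine solution set of the remaining system (pinv
# particular solution + orthonormal null-space correction). Valid whenever
# the box constraints are inactive at the optimum (wide-bound instances).
moma_nullspace_oracle <- function(model, vref, fixed_ids, fixed_vals) {
  n <- ncol(model$S)
  idx_fixed <- match(fixed_ids, model$reaction_ids)
  idx_free <- setdiff(seq_len(n), idx_fixed)
  Sf <- model$S[, idx_free, drop = FALSE]
  b <- -model$S[, idx_fixed, drop = FALSE] %*% fixed_vals
  sv <- svd(Sf)
  pos <- sv$d > 1e-9 * max(sv$d)
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  p <- as.numeric(pinv %*% b)
  # consistency check: the fixed values must admit a steady state
  if (max(abs(Sf %*% p - b)) > 1e-6) return(NULL)
  N <- oracle_nullspace(Sf)
  vref_free <- vref[idx_free]
  z <- t(N) %*% (vref_free - p)
  v_free <- p + as.numeric(N %*% z)
  v <- numeric(n)
  v[idx_fixed] <- fixed_vals
  v[idx_free] <- v_free
  stats::setNames(v, model$reaction_ids)
}
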