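#' Solver configuration
#'
#' Numerical settings shared by [solve_fba()] and [solve_moma()].
#'
#' @param feasibility_tol Tolerance used when checking bound/mass-balance
#'   feasibility of returned solutions. Default `1e-9`.
#' @param optimality_tol Relative tolerance at which two successive solves of
#'   the regularization ladder (see [solve_fba()]) are declared converged.
#'   Default `1e-8`.
#' @param eps_ladder Decreasing sequence of regularization weights tried by
#'   [solve_fba()]. The ladder stops as soon as two successive weights agree
#'   on the objective to `optimality_tol`.
#' @param unbounded_tol Flux magnitude beyond which a solution is declared
#'   unbounded (only reachable when the model carries infinite bounds).
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(feasibility_tol = 1e-9, optimality_tol = 1e-8,
                           eps_ladder = c(1e-4, 1e-6, 1e-8),
                           unbounded_tol = 1e7) {
  structure(list(feasibility_tol = feasibility_tol,
                 optimality_tol = optimality_tol,
                 eps_ladder = eps_ladder,
                 unbounded_tol = unbounded_tol),
            class = "solver_control")
}

# Assemble the constrained-QP skeleton shared by FBA and MOMA. Pinned fluxes
# (lb == ub, the encoding of knockouts and flux doublings) are eliminated by
# substitution: the active-set solver handles the remaining non-degenerate
# box-plus-equality system far more robustly than a system carrying exact
# equality pairs. The steady-state rows of the reduced system are pruned to
# an independent set; consistency of the pruned rows is re-verified on every
# solution (an inconsistent pinned system means infeasibility).
qp_problem <- function(S, lb, ub) {
  n <- ncol(S)
  pinned <- is.finite(lb) & lb == ub
  free <- which(!pinned)
  v_pin <- lb[pinned]
  rhs <- if (any(pinned)) {
    -as.numeric(S[, pinned, drop = FALSE] %*% v_pin)
  } else {
    numeric(nrow(S))
  }
  Sf <- S[, free, drop = FALSE]
  keep <- if (nrow(Sf) && length(free)) {
    qrt <- qr(t(Sf))
    sort(qrt$pivot[seq_len(qrt$rank)])
  } else {
    integer(0)
  }
  Se <- Sf[keep, , drop = FALSE]
  be <- rhs[keep]
  nf <- length(free)
  lo <- which(is.finite(lb[free]))
  hi <- which(is.finite(ub[free]))
  Amat <- cbind(t(Se),
                diag(nf)[, lo, drop = FALSE],
                -diag(nf)[, hi, drop = FALSE])
  bvec <- c(be, lb[free][lo], -ub[free][hi])
  list(S = S, n = n, free = free, pinned = which(pinned), v_pin = v_pin,
       Amat = Amat, bvec = bvec, meq = nrow(Se),
       res_tol = 1e-7 * (1 + max(abs(v_pin), 0)))
}

# One strictly convex QP over the free coordinates:
# min 1/2 w ||x||^2 - d' x  s.t. the assembled constraints. Returns the full
# flux vector, or NULL when the constraint set admits no solution.
qp_solve <- function(w, d, prob) {
  x <- numeric(prob$n)
  x[prob$pinned] <- prob$v_pin
  nf <- length(prob$free)
  if (nf > 0) {
    if (ncol(prob$Amat) == 0) {
      x[prob$free] <- d[prob$free] / w
    } else {
      attempt <- function(bvec) {
        tryCatch(
          quadprog::solve.QP(Dmat = diag(w, nf), dvec = d[prob$free],
                             Amat = prob$Amat, bvec = bvec,
                             meq = prob$meq),
          error = function(e) e
        )
      }
      ans <- attempt(prob$bvec)
      if (inherits(ans, "error") &&
          grepl("inconsistent", conditionMessage(ans))) {
        # Heavily degenerate vertices (many coincident active bounds) can
        # make the active-set method report a spurious inconsistency.
        # Deterministically relax each inequality by a distinct O(1e-9)
        # amount to break the ties; equalities stay exact, so genuinely
        # infeasible pin sets remain infeasible.
        bvec2 <- prob$bvec
        n_ineq <- length(bvec2) - prob$meq
        if (n_ineq > 0) {
          idx <- prob$meq + seq_len(n_ineq)
          bvec2[idx] <- bvec2[idx] - 1e-9 * seq_len(n_ineq)
        }
        ans <- attempt(bvec2)
      }
      if (inherits(ans, "error")) {
        if (grepl("inconsistent", conditionMessage(ans))) return(NULL)
        stop(ans)
      }
      x[prob$free] <- ans$solution
    }
  }
  # pruned / pinned rows must still balance; otherwise the pin set is lethal
  if (max(abs(as.numeric(prob$S %*% x))) > prob$res_tol) return(NULL)
  x
}

#' Flux balance analysis with a deterministic least-norm tie-break
#'
#' Maximizes the biomass flux subject to steady-state mass balance
#' (`S V = 0`) and flux bounds. Because the flux polytope generally admits
#' many alternate optima, the problem is solved by exact L2 regularization:
#' `min eps/2 ||V||^2 - V_biomass` for a small `eps`, which for `eps` below a
#' problem-dependent threshold returns exactly the minimum-norm point of the
#' optimal face (Mangasarian & Meyer's exact-regularization property of linear
#' programs). A decreasing ladder of `eps` values is solved until two
#' successive weights agree on the objective, making the returned flux vector
#' reproducible bit-for-bit for identical inputs.
#'
#' @param model A [metabolic_model()].
#' @param overrides Optional [bound_override()] replacing selected bounds
#'   (design constraints, uptake caps).
#' @param control A [solver_control()].
#' @return A [flux_state()]; `status` is `"optimal"`, `"infeasible"` (no
#'   fluxes returned) or `"unbounded"` (diagnostics list the runaway
#'   reactions).
#' @export
solve_fba <- function(model, overrides = NULL, control = solver_control()) {
  b <- apply_overrides(model, overrides)
  n <- length(model$reaction_ids)
  cc <- as.numeric(model$reaction_ids == model$objective_id)
  prob <- qp_problem(model$S, b$lb, b$ub)

  prev_obj <- NULL
  sol <- NULL
  for (eps in control$eps_ladder) {
    x <- qp_solve(eps, cc, prob)
    if (is.null(x)) {
      return(flux_state(NULL, NA_real_, status = "infeasible"))
    }
    obj <- sum(cc * x)
    sol <- x
    if (!is.null(prev_obj) &&
        abs(obj - prev_obj) <= control$optimality_tol * (1 + abs(obj))) {
      break
    }
    prev_obj <- obj
  }
  if (max(abs(sol)) > control$unbounded_tol) {
    runaway <- model$reaction_ids[abs(sol) > control$unbounded_tol]
    return(flux_state(NULL, NA_real_, status = "unbounded",
                      diagnostics = list(unbounded_reactions = runaway)))
  }
  fl <- stats::setNames(sol, model$reaction_ids)
  flux_state(fl, unname(fl[model$objective_id]), status = "optimal")
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the flux vector of a perturbed (bioengineered) strain closest in
#' squared Euclidean distance to a reference (wild-type) flux distribution,
#' subject to steady-state mass balance and the override-modified bounds:
#' `min sum_j (V_j - V_ref,j)^2` s.t. `S V = 0`, `lb' <= V <= ub'`. Solved as
#' a strictly convex quadratic program (Goldfarb-Idnani active set), so the
#' minimizer is unique and deterministic.
#'
#' @param model A [metabolic_model()] (the unmodified network).
#' @param reference A [flux_state()] (or named numeric vector) of the
#'   unmodified strain; typically a [solve_fba()] solution.
#' @param overrides A [bound_override()] carrying the perturbation
#'   (knockouts, flux doublings, uptake caps).
#' @param control A [solver_control()].
#' @return A [flux_state()] whose `objective_value` is the biomass flux of the
#'   adjusted strain and whose diagnostics carry the squared distance to the
#'   reference; `status` is `"infeasible"` when the overrides admit no
#'   steady-state flux (the caller decides whether that design is lethal).
#' @export
solve_moma <- function(model, reference, overrides = NULL,
                       control = solver_control()) {
  vref <- if (inherits(reference, "flux_state")) reference$fluxes else reference
  if (is.null(vref) || !all(model$reaction_ids %in% names(vref))) {
    stop("reference must provide a flux for every model reaction",
         call. = FALSE)
  }
  vref <- as.numeric(vref[model$reaction_ids])
  b <- apply_overrides(model, overrides)
  prob <- qp_problem(model$S, b$lb, b$ub)
  x <- qp_solve(1, vref, prob)
  if (is.null(x)) {
    return(flux_state(NULL, NA_real_, status = "infeasible"))
  }
  fl <- stats::setNames(x, model$reaction_ids)
  flux_state(fl, unname(fl[model$objective_id]), status = "optimal",
             diagnostics = list(sq_distance = sum((x - vref)^2)))
}
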