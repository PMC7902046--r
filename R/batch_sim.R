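#' Batch-culture conditions
#'
#' Initial state and numerical grid for a batch simulation.
#'
#' @param initial_concentrations Named numeric vector of extracellular
#'   concentrations in mM (e.g. `c(glc_e = 22, nh4_e = 18)`). Every named
#'   metabolite must have an exchange reaction in the model. Values must be
#'   non-negative.
#' @param primary_substrate Metabolite id of the limiting carbon source; the
#'   simulation stops when its concentration falls below
#'   `exhaustion_threshold`.
#' @param initial_cell_density Starting cell concentration, gDW/L.
#'   Default 0.01.
#' @param delta_t Time step, h. Default 1.
#' @param max_time Simulation horizon, h. Default 24.
#' @param mu_min Growth rate (1/h) below which growth is treated as zero: the
#'   exponential concentration update is replaced by its linear limit and the
#'   simulation terminates. Default 1e-6.
#' @param exhaustion_threshold Substrate concentration (mM) considered
#'   exhausted. Default 1e-3.
#' @return A list of class `batch_conditions`.
#' @export
batch_conditions <- function(initial_concentrations, primary_substrate,
                             initial_cell_density = 0.01, delta_t = 1,
                             max_time = 24, mu_min = 1e-6,
                             exhaustion_threshold = 1e-3) {
  if (delta_t <= 0) stop("delta_t must be positive", call. = FALSE)
  if (any(initial_concentrations < 0)) {
    stop("initial concentrations must be non-negative", call. = FALSE)
  }
  if (!(primary_substrate %in% names(initial_concentrations))) {
    stop("primary_substrate must appear in initial_concentrations",
         call. = FALSE)
  }
  structure(list(initial_concentrations = initial_concentrations,
                 primary_substrate = primary_substrate,
                 initial_cell_density = initial_cell_density,
                 delta_t = delta_t, max_time = max_time, mu_min = mu_min,
                 exhaustion_threshold = exhaustion_threshold),
            class = "batch_conditions")
}

#' The extracellular concentration update of the batch scheme
#'
#' `conc_new = conc_old + v_ex * dcell / mu` where `dcell` is the cell-density
#' increment over the step. In the exponential regime
#' `dcell = cell * (exp(mu * dt) - 1)`, so the factor `dcell / mu` replaces
#' the naive linear factor `dt * cell`; as `mu -> 0` the exponential factor
#' tends to the linear one, which is used directly below `mu_min`.
#'
#' @param conc Concentration before the step, mM.
#' @param v_ex Exchange flux, mmol/gDW/h (negative = uptake).
#' @param cell Cell density at the start of the step, gDW/L.
#' @param mu Growth rate, 1/h.
#' @param dt Step length, h.
#' @param mu_min Threshold below which the linear form is used.
#' @param linear Force the linear update `conc + v_ex * dt * cell` regardless
#'   of `mu` (the textbook first-order form).
#' @return Updated concentration (may be negative; callers cap uptake so it
#'   is not).
#' @export
concentration_update <- function(conc, v_ex, cell, mu, dt, mu_min = 1e-6,
                                 linear = FALSE) {
  conc + v_ex * step_factor(cell, mu, dt, mu_min, linear)
}

# dcell/mu (exponential regime) or dt*cell (linear regime): the factor
# converting an exchange flux into a concentration increment.
step_factor <- function(cell, mu, dt, mu_min = 1e-6, linear = FALSE) {
  if (linear || mu <= mu_min) dt * cell else cell * expm1(mu * dt) / mu
}

#' Simulate a wild-type batch culture
#'
#' Repeatedly solves FBA on the model and propagates cell density and
#' extracellular concentrations forward: at each time point the exchange
#' lower bounds of tracked metabolites are capped so that no concentration
#' can go negative over the coming step, FBA is solved, cell density is
#' updated as `cell * exp(mu * dt)`, and each tracked concentration by
#' `conc + v_ex * dcell / mu`. The run stops when the primary substrate is
#' exhausted, growth ceases (`mu <= mu_min`), or `max_time` is reached.
#'
#' Because the uptake cap depends on the growth rate, each step performs a
#' small fixed-point iteration: solve, project concentrations, tighten the
#' offending exchange bounds, re-solve (at most ten times; in practice it
#' binds only on the final, substrate-limited step).
#'
#' @param model A [metabolic_model()].
#' @param conditions A [batch_conditions()].
#' @param control A [solver_control()].
#' @return A `batch_time_series`: list with `times` (h), `cell_density`
#'   (gDW/L), `concentrations` (time x metabolite matrix, mM),
#'   `growth_rates` (1/h), `fluxes` (list of [flux_state()]), and flags
#'   `exhausted` and `lethal`.
#' @export
run_wt_batch <- function(model, conditions, control = solver_control()) {
  propagate_batch(model, conditions, control, step_solver = function(k, caps) {
    solve_fba(model, caps, control)
  })
}

#' Simulate a bioengineered strain against a wild-type trajectory
#'
#' Propagates an engineered strain on the wild-type time grid: at each time
#' point MOMA is solved against the wild-type flux vector of that time point
#' under design-derived bound overrides, and the engineered strain's own cell
#' density and concentrations are advanced from its own MOMA fluxes (a design
#' that slows growth therefore also slows substrate depletion). If MOMA is
#' infeasible at some time point the design is flagged lethal and an all-zero
#' flux vector is recorded from that point on.
#'
#' @param model A [metabolic_model()].
#' @param wt_series A wild-type series from [run_wt_batch()] on the same
#'   model.
#' @param overrides_fn Function `(k, wt_flux)` returning the
#'   [bound_override()] for time index `k`; typically built from a design via
#'   [design_to_overrides()] so the doubling category tracks the wild-type
#'   flux of the same time point.
#' @param control A [solver_control()].
#' @param overlay_wt If `TRUE`, skip independent propagation and re-use the
#'   wild-type concentration/density trajectory, only recomputing fluxes
#'   (the alternative reading of per-time-point MOMA overlays).
#' @return A `batch_time_series` (same shape as [run_wt_batch()]).
#' @export
run_designed_batch <- function(model, wt_series, overrides_fn,
                               control = solver_control(),
                               overlay_wt = FALSE) {
  cond <- wt_series$conditions
  K <- length(wt_series$times)
  solver <- function(k, caps) {
    kk <- min(k, K)  # past the end of the WT grid, reuse the final reference
    ref <- wt_series$fluxes[[kk]]
    if (is.null(ref$fluxes)) {
      return(flux_state(NULL, NA_real_, status = "infeasible"))
    }
    ov <- combine_overrides(overrides_fn(kk, ref), caps)
    solve_moma(model, ref, ov, control)
  }
  if (overlay_wt) {
    fluxes <- vector("list", K)
    mus <- numeric(K)
    lethal <- FALSE
    for (k in seq_len(K)) {
      fs <- solver(k, NULL)
      if (fs$status != "optimal") {
        lethal <- TRUE
        fs <- flux_state(stats::setNames(numeric(length(model$reaction_ids)),
                                         model$reaction_ids),
                         0, status = "lethal")
      }
      fluxes[[k]] <- fs
      mus[k] <- fs$objective_value
    }
    out <- wt_series
    out$fluxes <- fluxes
    out$growth_rates <- mus
    out$lethal <- lethal
    return(out)
  }
  propagate_batch(model, cond, control, step_solver = solver, max_steps = K)
}

# Shared explicit-update loop for wild-type and engineered strains.
# step_solver(k, cap_overrides) returns a flux_state; infeasible solves mark
# the run lethal and freeze the state with zero fluxes.
propagate_batch <- function(model, conditions, control, step_solver,
                            max_steps = Inf) {
  dt <- conditions$delta_t
  mu_min <- conditions$mu_min
  conc <- conditions$initial_concentrations
  tracked <- names(conc)
  missing_ex <- setdiff(tracked, names(model$exchange_map))
  if (length(missing_ex)) {
    stop("no exchange reaction for tracked metabolite(s): ",
         paste(missing_ex, collapse = ", "), call. = FALSE)
  }
  ex_rxns <- model$exchange_map[tracked]
  cell <- conditions$initial_cell_density

  times <- numeric(0)
  cells <- numeric(0)
  concs <- NULL
  mus <- numeric(0)
  fluxes <- list()
  lethal <- FALSE
  exhausted <- FALSE

  t <- 0
  k <- 0
  zero_flux <- stats::setNames(numeric(length(model$reaction_ids)),
                               model$reaction_ids)
  repeat {
    k <- k + 1
    # fixed-point loop on the uptake caps: no tracked concentration may be
    # driven below zero during the coming step
    caps <- NULL
    fs <- NULL
    for (it in 1:10) {
      fs <- step_solver(k, caps)
      if (fs$status != "optimal") break
      mu <- fs$objective_value
      fac <- step_factor(cell, mu, dt, mu_min)
      v_ex <- fs$fluxes[ex_rxns]
      proj <- conc + v_ex * fac
      viol <- which(proj < -control$feasibility_tol)
      if (!length(viol)) break
      need <- -conc[viol] / fac
      new_caps <- bound_override(ex_rxns[viol],
                                 lb = pmax(model$lb[ex_rxns[viol]], need),
                                 ub = model$ub[ex_rxns[viol]])
      caps <- combine_overrides(caps, new_caps)
    }
    if (fs$status != "optimal") {
      if (k == 1 && identical(fs$status, "infeasible") &&
          is.infinite(max_steps)) {
        stop("simulation error: model infeasible at t = 0 under the given ",
             "batch conditions", call. = FALSE)
      }
      lethal <- TRUE
      fs <- flux_state(zero_flux, 0, status = "lethal")
    }
    mu <- fs$objective_value
    times <- c(times, t)
    cells <- c(cells, cell)
    concs <- rbind(concs, conc)
    mus <- c(mus, mu)
    fluxes[[length(fluxes) + 1L]] <- fs

    if (lethal && k >= max_steps) break
    if (lethal && is.infinite(max_steps)) break
    if (!lethal) {
      if (conc[conditions$primary_substrate] <=
          conditions$exhaustion_threshold) {
        exhausted <- TRUE
        break
      }
      if (mu <= mu_min && is.infinite(max_steps)) break
    }
    if (k >= max_steps || t + dt > conditions$max_time + 1e-9) break

    if (!lethal) {
      fac <- step_factor(cell, mu, dt, mu_min)
      conc[tracked] <- pmax(conc[tracked] + fs$fluxes[ex_rxns] * fac, 0)
      cell <- cell * exp(max(mu, 0) * dt)
    }
    t <- t + dt
  }
  rownames(concs) <- NULL
  structure(list(times = times, cell_density = cells,
                 concentrations = concs, growth_rates = mus, fluxes = fluxes,
                 conditions = conditions, lethal = lethal,
                 exhausted = exhausted),
            class = "batch_time_series")
}

#' @export
print.batch_time_series <- function(x, ...) {
  cat("batch_time_series:", length(x$times), "time points, t = ",
      min(x$times), "..", max(x$times), "h\n")
  cat("  final cell density:", format(utils::tail(x$cell_density, 1)),
      "gDW/L\n")
  if (x$lethal) cat("  lethal design (infeasible adjustment)\n")
  if (x$exhausted) cat("  substrate exhausted\n")
  invisible(x)
}

#' Final concentration of a metabolite in a batch series
#'
#' @param series A `batch_time_series`.
#' @param metabolite Extracellular metabolite id.
#' @return Concentration (mM) at the last recorded time point.
#' @export
final_concentration <- function(series, metabolite) {
  if (!(metabolite %in% colnames(series$concentrations))) {
    stop("metabolite '", metabolite, "' is not tracked in this series",
         call. = FALSE)
  }
  unname(series$concentrations[nrow(series$concentrations), metabolite])
}
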