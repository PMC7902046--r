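#' Construct a stoichiometric metabolic model
#'
#' The central container for all simulation in omgsim: a stoichiometric matrix
#' with per-reaction flux bounds, a biomass objective, an exchange-reaction map
#' for extracellular metabolites, and a feature map linking reactions to the
#' protein and transcript identifiers used when labelling synthetic omics data.
#'
#' @param metabolite_ids Character vector of unique metabolite identifiers
#'   (rows of `S`).
#' @param reaction_ids Character vector of unique reaction identifiers
#'   (columns of `S`).
#' @param S Numeric stoichiometric matrix, `length(metabolite_ids)` rows by
#'   `length(reaction_ids)` columns. Coefficients are dimensionless.
#' @param lb,ub Numeric vectors of lower/upper flux bounds, one per reaction,
#'   in mmol/gDW/h. `lb[j] <= ub[j]` is enforced.
#' @param objective_id Identifier of the biomass (objective) reaction.
#' @param exchange_map Optional named character vector mapping metabolite id to
#'   the id of its exchange reaction. When `NULL`, exchange reactions are
#'   auto-detected as columns of `S` with exactly one nonzero entry.
#' @param feature_map Optional data frame with columns `reaction_id`,
#'   `protein_id`, `transcript_id`. When `NULL` a synthetic map
#'   (`PROT_<rxn>`, `GENE_<rxn>`) is generated.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S, lb, ub,
                            objective_id, exchange_map = NULL,
                            feature_map = NULL) {
  S <- as.matrix(S)
  rownames(S) <- metabolite_ids
  colnames(S) <- reaction_ids
  model <- structure(
    list(
      metabolite_ids = as.character(metabolite_ids),
      reaction_ids = as.character(reaction_ids),
      S = S,
      lb = stats::setNames(as.numeric(lb), reaction_ids),
      ub = stats::setNames(as.numeric(ub), reaction_ids),
      objective_id = objective_id,
      exchange_map = exchange_map,
      feature_map = feature_map
    ),
    class = "metabolic_model"
  )
  if (is.null(exchange_map)) {
    model$exchange_map <- detect_exchanges(model)
  }
  if (is.null(feature_map)) {
    model$feature_map <- data.frame(
      reaction_id = model$reaction_ids,
      protein_id = paste0("PROT_", model$reaction_ids),
      transcript_id = paste0("GENE_", model$reaction_ids),
      stringsAsFactors = FALSE
    )
  }
  validate_metabolic_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks matrix dimensions, identifier uniqueness, bound ordering, objective
#' membership and the single-nonzero-entry property of mapped exchange
#' reactions. Called by every constructor and loader; exported so external
#' model sources can be vetted directly.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_metabolic_model <- function(model) {
  m <- length(model$metabolite_ids)
  n <- length(model$reaction_ids)
  if (!is.matrix(model$S) || nrow(model$S) != m || ncol(model$S) != n) {
    stop("stoichiometric matrix must be ", m, " x ", n,
         " (metabolites x reactions)", call. = FALSE)
  }
  if (anyDuplicated(model$reaction_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(model$reaction_ids[duplicated(model$reaction_ids)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(model$metabolite_ids)) {
    stop("duplicate metabolite ids", call. = FALSE)
  }
  if (length(model$lb) != n || length(model$ub) != n) {
    stop("bounds must have one entry per reaction", call. = FALSE)
  }
  bad <- which(model$lb > model$ub)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(model$reaction_ids[bad], collapse = ", "), call. = FALSE)
  }
  if (!(model$objective_id %in% model$reaction_ids)) {
    stop("objective reaction '", model$objective_id,
         "' is not in the model", call. = FALSE)
  }
  if (length(model$exchange_map)) {
    for (i in seq_along(model$exchange_map)) {
      rxn <- model$exchange_map[[i]]
      met <- names(model$exchange_map)[i]
      if (!(rxn %in% model$reaction_ids) || !(met %in% model$metabolite_ids)) {
        stop("exchange map entry ", met, " -> ", rxn,
             " references unknown ids", call. = FALSE)
      }
      nz <- sum(model$S[, rxn] != 0)
      if (nz != 1L) {
        stop("exchange reaction '", rxn, "' must have exactly one nonzero ",
             "stoichiometric entry (has ", nz, ")", call. = FALSE)
      }
    }
  }
  invisible(model)
}

# Exchange reactions are columns of S with a single nonzero entry; the mapped
# metabolite is the one carrying that entry.
detect_exchanges <- function(model) {
  nz_count <- colSums(model$S != 0)
  ex_rxns <- model$reaction_ids[nz_count == 1L]
  if (!length(ex_rxns)) return(stats::setNames(character(0), character(0)))
  mets <- vapply(ex_rxns, function(r) {
    model$metabolite_ids[which(model$S[, r] != 0)]
  }, character(1))
  stats::setNames(ex_rxns, mets)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$metabolite_ids), "metabolites,",
      length(x$reaction_ids), "reactions\n")
  cat("  objective:", x$objective_id, "\n")
  cat("  exchanges:", length(x$exchange_map), "\n")
  invisible(x)
}

#' Bound overrides for reactions
#'
#' A set of per-reaction bound replacements, the carrier for strain-design
#' constraints (knockouts, flux doublings) and for the uptake caps applied
#' during batch simulation. Equality constraints are encoded as `lb == ub`.
#'
#' @param reaction_id Character vector of reaction ids.
#' @param lb,ub Numeric replacement bounds (recycled to length of
#'   `reaction_id`); `lb <= ub` elementwise.
#' @return A `bound_override` data frame with columns `reaction_id`, `lb`, `ub`.
#' @export
bound_override <- function(reaction_id = character(0), lb = numeric(0),
                           ub = numeric(0)) {
  ov <- data.frame(reaction_id = as.character(reaction_id),
                   lb = rep_len(as.numeric(lb), length(reaction_id)),
                   ub = rep_len(as.numeric(ub), length(reaction_id)),
                   stringsAsFactors = FALSE)
  if (any(ov$lb > ov$ub)) {
    stop("override lb > ub for: ",
         paste(ov$reaction_id[ov$lb > ov$ub], collapse = ", "), call. = FALSE)
  }
  class(ov) <- c("bound_override", "data.frame")
  ov
}

#' Fix one or more fluxes to exact values
#'
#' Convenience wrapper building an equality [bound_override] (`lb == ub ==`
#' value), e.g. `fix_flux("MDH", 0)` for a knockout.
#'
#' @param reaction_id Character vector of reaction ids.
#' @param value Numeric target flux values (recycled).
#' @return A `bound_override`.
#' @export
fix_flux <- function(reaction_id, value) {
  bound_override(reaction_id, value, value)
}

# Merge overrides into a model's bounds; later entries win on collision.
apply_overrides <- function(model, overrides) {
  if (is.null(overrides) || !nrow(overrides)) {
    return(list(lb = model$lb, ub = model$ub))
  }
  unknown <- setdiff(overrides$reaction_id, model$reaction_ids)
  if (length(unknown)) {
    stop("override references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lb <- model$lb
  ub <- model$ub
  lb[overrides$reaction_id] <- overrides$lb
  ub[overrides$reaction_id] <- overrides$ub
  list(lb = lb, ub = ub)
}

# Concatenate override sets; entries in `b` shadow entries in `a`.
combine_overrides <- function(a, b) {
  if (is.null(a) || !nrow(a)) return(b)
  if (is.null(b) || !nrow(b)) return(a)
  keep <- !(a$reaction_id %in% b$reaction_id)
  out <- rbind(a[keep, , drop = FALSE], b)
  class(out) <- c("bound_override", "data.frame")
  out
}

#' Construct a flux state
#'
#' One solved flux vector at one time point, as returned by [solve_fba()] and
#' [solve_moma()].
#'
#' @param fluxes Named numeric vector of fluxes (mmol/gDW/h), one per reaction.
#' @param objective_value Value of the objective (biomass) flux, 1/h.
#' @param status Solver status: `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @param diagnostics Optional list of solver diagnostics.
#' @return An object of class `flux_state`.
#' @export
flux_state <- function(fluxes, objective_value, status = "optimal",
                       diagnostics = list()) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, diagnostics = diagnostics),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state (", x$status, "): objective = ",
      format(x$objective_value), ", ", length(x$fluxes), " fluxes\n", sep = "")
  invisible(x)
}

#' Maximum mass-balance residual of a flux state
#'
#' Computes `max_i |sum_j S_ij V_j|`, the worst steady-state violation across
#' metabolites. Optimal solutions should satisfy this to solver tolerance.
#'
#' @param model A `metabolic_model`.
#' @param flux A `flux_state` solved against `model`.
#' @return A single non-negative number.
#' @export
mass_balance_residual <- function(model, flux) {
  v <- flux$fluxes[model$reaction_ids]
  max(abs(as.numeric(model$S %*% v)))
}

#' Write a flux state as a two-column TSV
#'
#' The fluxomics export format: reaction id and flux value, tab-separated,
#' with a header row.
#'
#' @param flux A `flux_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(flux, path) {
  df <- data.frame(reaction_id = names(flux$fluxes),
                   flux = as.numeric(flux$fluxes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
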