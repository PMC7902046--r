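#' Specification for the built-in toy model
#'
#' Parameters of the deterministic toy genome-scale-model stand-in built by
#' [make_toy_model()]: a glucose-fed central-carbon skeleton (glycolysis,
#' pyruvate dehydrogenase, an anaplerotic/TCA-like energy loop, acetate
#' overflow) with a heterologous product branch from the acetyl-CoA hub to a
#' secreted target metabolite.
#'
#' @param n_pathway_steps Number of reactions on the product branch between
#'   the acetyl-CoA hub and the intracellular target. Default 2.
#' @param branch_yield Mol target per mol acetyl-CoA consumed by the first
#'   branch step. Must exceed ~0.254 so the biomass composition below stays
#'   physical. Default 0.5 (two acetyl-CoA per product, isoprenoid-like).
#' @param uptake_max Maximum glucose uptake rate, mmol/gDW/h. Default 10.
#' @param biomass_yield Growth yield on glucose, gDW/mmol; the biomass
#'   reaction is scaled so the FBA growth optimum is exactly
#'   `uptake_max * biomass_yield`. Default 0.1.
#' @param target_id Identifier of the extracellular target metabolite.
#'   Default `"prod_e"`.
#' @return A list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(n_pathway_steps = 2, branch_yield = 0.5,
                           uptake_max = 10, biomass_yield = 0.1,
                           target_id = "prod_e") {
  stopifnot(n_pathway_steps >= 1, uptake_max > 0, biomass_yield > 0)
  if (branch_yield <= 0.15 / (0.8 - 0.625 / 3)) {
    stop("branch_yield must exceed ~0.254 for a physical biomass ",
         "composition", call. = FALSE)
  }
  structure(list(n_pathway_steps = n_pathway_steps,
                 branch_yield = branch_yield,
                 uptake_max = uptake_max,
                 biomass_yield = biomass_yield,
                 target_id = target_id),
            class = "toy_model_spec")
}

#' Build the deterministic toy metabolic model
#'
#' Constructs a small (17 metabolites, 26 reactions at the default pathway
#' length) mass-balanced network: glucose uptake, two parallel glycolytic
#' routes with different ATP yields (GLYC, ED), pyruvate dehydrogenase and a
#' formate-lyase alternative (PDH, PFL), anaplerosis and its
#' carboxykinase-like reverse (PPC, PPCK), a citrate energy loop (CS + CITD
#' yielding ATP), acetate and lactate overflow with acetate re-assimilation
#' (PTA, ACS, LDH), an ATP maintenance sink (ATPM), a biomass reaction
#' drawing pyruvate, acetyl-CoA, oxaloacetate, ATP and the branch
#' metabolites, and an `n_pathway_steps`-reaction branch from acetyl-CoA to
#' a secreted target product. The biomass stoichiometry is scaled so the FBA growth optimum
#' equals `uptake_max * biomass_yield` exactly, which makes closed-form checks
#' of the batch dynamics possible. Entirely deterministic: no randomness.
#'
#' The decoy reactions PPC, CS, CITD, PTA and ATPM carry a mix of zero and
#' nonzero wild-type flux, giving the categorical design space (knockout /
#' no-modification / double) nontrivial, mechanistically coupled effects under
#' MOMA.
#'
#' @param spec A [toy_model_spec()].
#' @return A validated [metabolic_model()].
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  y <- spec$branch_yield
  Y <- spec$biomass_yield
  n_br <- spec$n_pathway_steps

  branch_mets <- if (n_br == 1) "prod_c" else c("ipp_c",
    if (n_br > 2) paste0("bint", seq_len(n_br - 2), "_c") else character(0),
    "prod_c")
  mets <- c("glc_e", "glc_c", "pyr_c", "accoa_c", "oaa_c", "cit_c", "co2_c",
            "atp_c", "ac_c", "ac_e", "lac_c", "lac_e", "for_c", "for_e",
            branch_mets, "prod_e")

  rxn <- function(id, stoich, lb, ub) {
    list(id = id, stoich = stoich, lb = lb, ub = ub)
  }
  first_branch_met <- branch_mets[1]
  last_branch_met <- branch_mets[length(branch_mets)]
  # Biomass drains per unit growth flux, scaled by 1/Y. The composition is
  # balanced so that (a) total carbon demand is exactly 2/Y pyruvate
  # equivalents, making the growth optimum exactly uptake * Y, and (b) the
  # ATP demand exceeds the glycolytic supply, forcing flux through the
  # CS/CITD energy loop at the wild-type optimum — every decoy then carries
  # flux and categorical modifications have graded, non-degenerate effects.
  # Both the first branch intermediate (isoprenoid precursors go into
  # membranes and quinones) and the final product are drawn, so consecutive
  # branch steps carry distinct wild-type fluxes and their modifications are
  # distinguishable.
  branch_draw <- if (n_br == 1) {
    stats::setNames(-0.15, last_branch_met)
  } else {
    stats::setNames(c(-0.05, -0.1), c(first_branch_met, last_branch_met))
  }
  accoa_coef <- 0.8 - 0.15 / y - 0.625 / 3
  bm <- c(c(pyr_c = -1.0, accoa_c = -accoa_coef, oaa_c = -0.2,
            atp_c = -2.55), branch_draw) / Y

  rxns <- list(
    rxn("EX_glc_e", c(glc_e = -1), -spec$uptake_max, 1000),
    rxn("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000),
    rxn("GLYC", c(glc_c = -1, pyr_c = 2, atp_c = 2), 0, 1000),
    rxn("ED", c(glc_c = -1, pyr_c = 2, atp_c = 1), 0, 1000),
    rxn("PDH", c(pyr_c = -1, accoa_c = 1, co2_c = 1), 0, 1000),
    rxn("PPC", c(pyr_c = -1, co2_c = -1, oaa_c = 1), 0, 1000),
    rxn("PPCK", c(oaa_c = -1, atp_c = -1, pyr_c = 1, co2_c = 1), 0, 1000),
    rxn("CS", c(accoa_c = -1, oaa_c = -1, cit_c = 1), 0, 1000),
    rxn("CITD", c(cit_c = -1, oaa_c = 1, co2_c = 2, atp_c = 3), 0, 1000),
    rxn("PTA", c(accoa_c = -1, ac_c = 1), 0, 1000),
    rxn("ACS", c(ac_c = -1, atp_c = -1, accoa_c = 1), 0, 1000),
    rxn("ACt", c(ac_c = -1, ac_e = 1), 0, 1000),
    rxn("EX_ac_e", c(ac_e = -1), 0, 1000),
    rxn("LDH", c(pyr_c = -1, lac_c = 1), 0, 1000),
    rxn("LACt", c(lac_c = -1, lac_e = 1), 0, 1000),
    rxn("EX_lac_e", c(lac_e = -1), 0, 1000),
    rxn("PFL", c(pyr_c = -1, accoa_c = 1, for_c = 1), 0, 1000),
    rxn("FORt", c(for_c = -1, for_e = 1), 0, 1000),
    rxn("EX_for_e", c(for_e = -1), 0, 1000),
    rxn("EX_co2_c", c(co2_c = -1), -1000, 1000),
    rxn("IPPS", stats::setNames(c(-1 / y, -0.5, 1),
                                c("accoa_c", "atp_c", first_branch_met)),
        0, 1000)
  )
  if (n_br > 1) {
    for (k in 2:n_br) {
      sid <- paste0("PS", k)
      rxns <- c(rxns, list(rxn(sid,
        stats::setNames(c(-1, 1), c(branch_mets[k - 1], branch_mets[k])),
        0, 1000)))
    }
  }
  rxns <- c(rxns, list(
    rxn("PRODt", c(prod_c = -1, prod_e = 1), 0, 1000),
    rxn("EX_prod_e", c(prod_e = -1), 0, 1000),
    rxn("ATPM", c(atp_c = -1), 0, 1000),
    rxn("BIOMASS", bm, 0, 1000)
  ))

  rxn_ids <- vapply(rxns, `[[`, character(1), "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxn_ids))
  for (r in rxns) S[names(r$stoich), r$id] <- r$stoich
  metabolic_model(mets, rxn_ids, S,
                  lb = vapply(rxns, `[[`, numeric(1), "lb"),
                  ub = vapply(rxns, `[[`, numeric(1), "ub"),
                  objective_id = "BIOMASS")
}

#' Default design-target reactions of the toy model
#'
#' Eight reactions around the acetyl-CoA hub of [make_toy_model()] eligible
#' for categorical modification, mirroring the eight-input design space used
#' for genome-scale runs: the fluxes feeding or draining the hub (PDH, PFL,
#' PPC, PPCK, CS, CITD) plus the product branch (IPPS and the final branch
#' step). Most carry nonzero wild-type flux, so their categorical
#' modifications have graded, distinguishable effects under MOMA.
#'
#' @param model A toy model from [make_toy_model()].
#' @return Character vector of reaction ids.
#' @export
toy_design_targets <- function(model) {
  branch <- grep("^(IPPS|PS[0-9]+)$", model$reaction_ids, value = TRUE)
  last_branch <- branch[length(branch)]
  unique(c("PDH", "PFL", "PPC", "PPCK", "CS", "CITD", "IPPS", last_branch))
}

#' Ground-truth production maps for surrogate testing
#'
#' Computes a design-to-production map over an explicit design space, either
#' mechanistically (full batch + MOMA simulation per design, the same route
#' as [simulate_design_production()]) or from a closed-form additive rule
#' (noiseless per-category effects), for use as an oracle when testing the
#' recommender.
#'
#' @param model A [metabolic_model()].
#' @param design_space Integer matrix, one row per design, columns named by
#'   target reaction ids, entries in \{0, 1, 2\}.
#' @param rule `"mechanistic"` or `"additive"`.
#' @param wt_series For the mechanistic rule, a wild-type
#'   [run_wt_batch()] series on `model`.
#' @param target_metabolite For the mechanistic rule, the extracellular
#'   target metabolite id.
#' @param effects For the additive rule, a 3 x d matrix of per-category
#'   effects (rows = categories 0/1/2); the production of a design is
#'   `baseline + sum_j effects[category_j + 1, j]`, clamped at zero.
#' @param baseline Additive-rule baseline production. Default 1.
#' @param control A [solver_control()].
#' @return Numeric vector of productions (mM), one per row of `design_space`.
#' @export
make_ground_truth <- function(model, design_space,
                              rule = c("mechanistic", "additive"),
                              wt_series = NULL, target_metabolite = NULL,
                              effects = NULL, baseline = 1,
                              control = solver_control()) {
  rule <- match.arg(rule)
  if (is.null(colnames(design_space))) {
    stop("design_space must have reaction ids as column names", call. = FALSE)
  }
  if (rule == "additive") {
    if (is.null(effects) || nrow(effects) != 3 ||
        ncol(effects) != ncol(design_space)) {
      stop("additive rule needs a 3 x d effects matrix", call. = FALSE)
    }
    vals <- apply(design_space, 1, function(row) {
      baseline + sum(effects[cbind(row + 1, seq_along(row))])
    })
    return(pmax(as.numeric(vals), 0))
  }
  if (nrow(design_space) > 1e5) {
    stop("mechanistic ground truth over ", nrow(design_space),
         " designs is too large; subsample the space", call. = FALSE)
  }
  if (is.null(wt_series) || is.null(target_metabolite)) {
    stop("mechanistic rule needs wt_series and target_metabolite",
         call. = FALSE)
  }
  apply(design_space, 1, function(row) {
    d <- design(stats::setNames(as.integer(row), colnames(design_space)))
    simulate_design_production(model, wt_series, d, target_metabolite,
                               control = control)$production
  })
}
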