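#' Run one simulated Design-Build-Test-Learn cycle
#'
#' The complete loop on one model: (1) simulate a wild-type batch culture;
#' (2) draw an initial Latin-hypercube batch of categorical designs;
#' (3) simulate the production of each design through per-time-point MOMA
#' (the mechanistic ground truth); (4) train the bootstrap-ensemble
#' surrogate on (design, production) pairs; (5) recommend the top-k unseen
#' designs; (6) re-simulate the recommendations to obtain their observed
#' productions.
#'
#' @param model A [metabolic_model()].
#' @param conditions A [batch_conditions()] tracking the target metabolite.
#' @param target_reactions Character vector of design-target reaction ids.
#' @param target_metabolite Extracellular target metabolite id (the
#'   response).
#' @param n_designs Size of the initial training batch including the wild
#'   type. Default 96 (one microtiter plate).
#' @param k Number of recommendations. Default 10.
#' @param seed Integer seed for design sampling and surrogate bootstraps.
#' @param surrogate A [surrogate_config()].
#' @param cv_folds Folds for the cross-validated predictions (`NULL` to
#'   skip). Default 10.
#' @param control A [solver_control()].
#' @return A list: `wt_series`, `designs` ([design_batch()]), `productions`
#'   (numeric, mM), `training` ([training_set()]), `surrogate`, `cv`
#'   (cross-validated predictions or `NULL`), `recommendations`
#'   (`recommendation_set`), `observed` (simulated productions of the
#'   recommendations, mM).
#' @export
run_dbtl_cycle <- function(model, conditions, target_reactions,
                           target_metabolite, n_designs = 96, k = 10,
                           seed = 1, surrogate = surrogate_config(),
                           cv_folds = 10, control = solver_control()) {
  wt_series <- run_wt_batch(model, conditions, control)
  batch <- latin_hypercube_designs(n_designs, target_reactions,
                                   rng_seed = seed)
  productions <- vapply(batch$designs, function(d) {
    simulate_design_production(model, wt_series, d, target_metabolite,
                               control = control)$production
  }, numeric(1))
  training <- training_set(design_matrix(batch), productions)
  fit <- fit_surrogate(training, surrogate, rng_seed = seed)
  cv <- if (!is.null(cv_folds)) {
    crossval_predictions(training, folds = cv_folds, rng_seed = seed,
                         config = surrogate)
  }
  recs <- recommend(fit, k = k)
  rxns <- fit$reactions
  observed <- vapply(seq_len(nrow(recs)), function(i) {
    d <- design(stats::setNames(as.integer(unlist(recs[i, rxns])), rxns))
    simulate_design_production(model, wt_series, d, target_metabolite,
                               control = control)$production
  }, numeric(1))
  list(wt_series = wt_series, designs = batch, productions = productions,
       training = training, surrogate = fit, cv = cv,
       recommendations = recs, observed = observed)
}
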