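#' Configuration of the mock-omics transformations
#'
#' Parameters of the deterministic-plus-noise mappings from fluxes to
#' proteomics, transcriptomics and metabolomics tables.
#'
#' @param k Proteomics linear constant: protein abundance is `|V|/k`
#'   (proteins/cell per mmol/gDW/h). Default 0.1.
#' @param q Transcriptomics linear constant: transcript abundance is `P/q`
#'   (FPKM per protein/cell). Default 0.833.
#' @param noise_fraction Relative noise level: Gaussian noise with standard
#'   deviation `noise_fraction * signal` is added to proteomics and
#'   transcriptomics values (metabolomics carries no noise term). In
#'   `[0, 1)`. Default 0.05.
#' @param rng_seed Integer seed for the noise generator; `NULL` uses the
#'   session RNG state.
#' @param signed_fluxes If `TRUE`, apply the proteomics map to the signed
#'   flux `V` rather than `|V|` (the literal linear form; negative fluxes
#'   then clamp to zero abundance).
#' @return A list of class `omics_config`.
#' @export
omics_config <- function(k = 0.1, q = 0.833, noise_fraction = 0.05,
                         rng_seed = NULL, signed_fluxes = FALSE) {
  stopifnot(k > 0, q > 0, noise_fraction >= 0, noise_fraction < 1)
  structure(list(k = k, q = q, noise_fraction = noise_fraction,
                 rng_seed = rng_seed, signed_fluxes = signed_fluxes),
            class = "omics_config")
}

# Build an omics table row set; shared shape across the three data types.
omics_table <- function(time, feature_id, value, unit) {
  tibble::tibble(time = time, feature_id = feature_id,
                 value = as.numeric(value), unit = unit)
}

# Add seeded multiplicative-scale Gaussian noise and clamp at zero. Signals
# of exactly zero stay exactly zero (their noise sd is zero).
add_relative_noise <- function(signal, noise_fraction) {
  if (noise_fraction == 0 || !length(signal)) return(pmax(signal, 0))
  noisy <- signal + stats::rnorm(length(signal), 0,
                                 noise_fraction * abs(signal))
  pmax(noisy, 0)
}

with_omics_seed <- function(config, expr) {
  if (is.null(config$rng_seed)) expr
  else withr::with_seed(config$rng_seed, expr)
}

#' Mock proteomics from a flux state
#'
#' Protein abundance per mapped reaction: `P_j = |V_j| / k + beta` with
#' `beta ~ N(0, (noise_fraction * |V_j| / k)^2)`, clamped at zero, so a zero
#' flux always yields exactly zero protein. Noise draws are consumed in
#' sorted reaction-id order from a generator seeded by `config$rng_seed`, so
#' row order can never change the values.
#'
#' @param flux A solved [flux_state()].
#' @param model The [metabolic_model()] supplying the reaction-to-protein
#'   feature map; reactions absent from the map are skipped with a warning.
#' @param config An [omics_config()].
#' @param time Time stamp (h) attached to every row. Default 0.
#' @return A tibble with columns `time`, `feature_id` (protein id), `value`
#'   (proteins/cell), `unit`.
#' @export
proteomics_from_fluxes <- function(flux, model, config = omics_config(),
                                   time = 0) {
  stopifnot(identical(flux$status, "optimal"))
  fm <- model$feature_map
  rxns <- sort(intersect(names(flux$fluxes), fm$reaction_id))
  skipped <- setdiff(names(flux$fluxes), fm$reaction_id)
  if (length(skipped)) {
    warning("skipping ", length(skipped),
            " reaction(s) without feature-map entries: ",
            paste(utils::head(skipped, 5), collapse = ", "), call. = FALSE)
  }
  v <- flux$fluxes[rxns]
  base <- if (config$signed_fluxes) v / config$k else abs(v) / config$k
  vals <- with_omics_seed(config,
                          add_relative_noise(base, config$noise_fraction))
  prot <- fm$protein_id[match(rxns, fm$reaction_id)]
  omics_table(time, prot, vals, "proteins/cell")
}

#' Mock transcriptomics from a proteomics table
#'
#' Transcript abundance linearly tied to protein abundance:
#' `T_j = P_j / q + gamma` with `gamma ~ N(0, (noise_fraction * P_j / q)^2)`,
#' clamped at zero; unit FPKM. Protein identifiers are translated to
#' transcript identifiers through the model's feature map.
#'
#' @param prot A proteomics tibble from [proteomics_from_fluxes()].
#' @param model The [metabolic_model()] supplying the feature map.
#' @param config An [omics_config()].
#' @return A tibble with columns `time`, `feature_id` (transcript id),
#'   `value` (FPKM), `unit`.
#' @export
transcriptomics_from_proteomics <- function(prot, model,
                                            config = omics_config()) {
  fm <- model$feature_map
  ord <- order(prot$feature_id)
  prot <- prot[ord, ]
  base <- prot$value / config$q
  vals <- with_omics_seed(config,
                          add_relative_noise(base, config$noise_fraction))
  genes <- fm$transcript_id[match(prot$feature_id, fm$protein_id)]
  omics_table(prot$time, genes, vals, "FPKM")
}

#' Mock metabolomics from a flux state
#'
#' Intracellular metabolite abundance as the mean absolute stoichiometric
#' flux through the metabolite: `M_i = sum_j |S_ij V_j| / n_i`, where `j`
#' ranges over the `n_i` reactions with `S_ij != 0`. No noise term; a
#' metabolite whose incident fluxes are all zero gets exactly zero (no
#' fluxes, no metabolite). Metabolites participating in no reaction are
#' excluded with a warning.
#'
#' @param flux A solved [flux_state()].
#' @param model The [metabolic_model()].
#' @param time Time stamp (h) attached to every row. Default 0.
#' @return A tibble with columns `time`, `feature_id` (metabolite id),
#'   `value` (mM, nominal), `unit`.
#' @export
metabolomics_from_fluxes <- function(flux, model, time = 0) {
  stopifnot(identical(flux$status, "optimal"))
  v <- flux$fluxes[model$reaction_ids]
  incident <- model$S != 0
  n_i <- rowSums(incident)
  orphan <- model$metabolite_ids[n_i == 0]
  if (length(orphan)) {
    warning("excluding metabolite(s) with no reactions: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  keep <- n_i > 0
  M <- rowSums(abs(model$S * rep(v, each = nrow(model$S))))[keep] / n_i[keep]
  mets <- model$metabolite_ids[keep]
  ord <- order(mets)
  omics_table(time, mets[ord], unname(M[ord]), "mM")
}

#' Full multiomics tables for a batch time series
#'
#' Applies the three omics transformations to every time point of a batch
#' series, consuming one shared seeded generator across the whole run.
#'
#' @param series A `batch_time_series` from [run_wt_batch()] or
#'   [run_designed_batch()].
#' @param model The [metabolic_model()].
#' @param config An [omics_config()]; its seed governs the entire run.
#' @return A list of tibbles: `proteomics`, `transcriptomics`,
#'   `metabolomics`.
#' @export
omics_from_series <- function(series, model, config = omics_config()) {
  per_point <- function() {
    cfg_noseed <- config
    cfg_noseed$rng_seed <- NULL
    prot_l <- list(); trans_l <- list(); metab_l <- list()
    for (i in seq_along(series$times)) {
      fs <- series$fluxes[[i]]
      if (!identical(fs$status, "optimal")) next
      t <- series$times[i]
      p <- proteomics_from_fluxes(fs, model, cfg_noseed, time = t)
      prot_l[[length(prot_l) + 1L]] <- p
      trans_l[[length(trans_l) + 1L]] <-
        transcriptomics_from_proteomics(p, model, cfg_noseed)
      metab_l[[length(metab_l) + 1L]] <-
        metabolomics_from_fluxes(fs, model, time = t)
    }
    list(proteomics = do.call(rbind, prot_l),
         transcriptomics = do.call(rbind, trans_l),
         metabolomics = do.call(rbind, metab_l))
  }
  with_omics_seed(config, per_point())
}
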