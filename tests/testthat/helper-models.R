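# Shared fixtures built in code: small deterministic models and random
# instances for the solver oracles.

# 3-reaction chain: uptake (<= 10) -> conversion -> biomass, all yields 1.
chain_model <- function(uptake = 10) {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("R_up", "R_conv", "R_bio")))
  metabolic_model(c("A", "B"), c("R_up", "R_conv", "R_bio"), S,
                  lb = c(0, 0, 0), ub = c(uptake, 1000, 1000),
                  objective_id = "R_bio")
}

# Random bounded feasible instance: lb <= 0 <= ub, finite bounds, random
# sparse stoichiometry. V = 0 is always feasible and the box is compact, so
# FBA is always feasible and bounded.
random_instance <- function(seed, n_mets = 6, n_rxns = 10, bound = 10) {
  withr::with_seed(seed, {
    repeat {
      S <- matrix(sample(c(-2, -1, 0, 1, 2), n_mets * n_rxns, replace = TRUE,
                         prob = c(0.08, 0.22, 0.4, 0.22, 0.08)),
                  nrow = n_mets)
      if (all(rowSums(S != 0) > 0) && all(colSums(S != 0) > 0)) break
    }
    mets <- paste0("m", seq_len(n_mets))
    rxns <- paste0("r", seq_len(n_rxns))
    dimnames(S) <- list(mets, rxns)
    lb <- -round(stats::runif(n_rxns, 0, bound), 3)
    ub <- round(stats::runif(n_rxns, 0, bound), 3)
    obj <- sample(rxns, 1)
    metabolic_model(mets, rxns, S, lb, ub, objective_id = obj)
  })
}

# Wide-bound instance for MOMA oracle tests: bounds so loose that the QP's
# box constraints can never be active at the optimum.
random_wide_instance <- function(seed, n_mets = 5, n_rxns = 9) {
  random_instance(seed, n_mets, n_rxns, bound = 10) |>
    (\(m) {
      m$lb[] <- -1000
      m$ub[] <- 1000
      m
    })()
}

toy_conditions <- function(glc = 22) {
  batch_conditions(c(glc_e = glc, prod_e = 0, ac_e = 0),
                   primary_substrate = "glc_e")
}
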