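test_that("model constructor enforces structural invariants", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_identical(dim(m$S), c(2L, 3L))
  # exchange auto-detection: single nonzero column entries
  expect_identical(unname(m$exchange_map["A"]), "R_up")
  expect_error(
    metabolic_model(c("A"), c("r1"), matrix(1, 1, 1), lb = 2, ub = 1,
                    objective_id = "r1"),
    "lower bound exceeds upper bound")
  expect_error(
    metabolic_model(c("A"), c("r1", "r1"), matrix(1, 1, 2), lb = c(0, 0),
                    ub = c(1, 1), objective_id = "r1"),
    "duplicate reaction ids")
  expect_error(
    metabolic_model(c("A"), c("r1"), matrix(1, 1, 1), lb = 0, ub = 1,
                    objective_id = "nope"),
    "not in the model")
})

test_that("bound overrides validate and merge correctly", {
  m <- chain_model()
  expect_error(bound_override("R_up", 2, 1), "lb > ub")
  ov <- omgsim:::combine_overrides(fix_flux("R_up", 5), fix_flux("R_up", 3))
  expect_equal(nrow(ov), 1L)   # later entry shadows
  expect_equal(ov$lb, 3)
  b <- omgsim:::apply_overrides(m, fix_flux("R_up", 4))
  expect_equal(unname(b$lb["R_up"]), 4)
  expect_equal(unname(b$ub["R_up"]), 4)
  expect_error(omgsim:::apply_overrides(m, fix_flux("missing", 0)),
               "unknown reaction")
})

test_that("FBA solves the bound-limited chain and the starved model", {
  m <- chain_model(uptake = 10)
  fs <- solve_fba(m)
  expect_identical(fs$status, "optimal")
  expect_equal(fs$objective_value, 10, tolerance = 1e-8)
  # no input, no growth
  starved <- solve_fba(m, bound_override("R_up", 0, 0))
  expect_equal(starved$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA detects infeasible override sets", {
  m <- chain_model()
  # conversion forced on while uptake is off: no steady state exists
  ov <- combine_overrides(fix_flux("R_up", 0), fix_flux("R_conv", 5))
  fs <- solve_fba(m, ov)
  expect_identical(fs$status, "infeasible")
  expect_null(fs$fluxes)
})

test_that("FBA optimum matches exhaustive vertex enumeration on random models", {
  for (seed in 1:12) {
    m <- random_instance(seed)
    fs <- solve_fba(m)
    expect_identical(fs$status, "optimal")
    oracle <- fba_vertex_oracle(m)
    expect_equal(fs$objective_value, oracle, tolerance = 1e-6,
                 label = paste("instance seed", seed))
  }
})

test_that("FBA dominates random feasible points and balances mass", {
  m <- random_instance(3)
  fs <- solve_fba(m)
  pts <- sample_feasible_points(m, 1000, seed = 99)
  obj_idx <- which(m$reaction_ids == m$objective_id)
  best_sampled <- max(vapply(pts, function(v) v[obj_idx], numeric(1)))
  expect_gte(fs$objective_value, best_sampled - 1e-9)
  expect_lte(mass_balance_residual(m, fs),
             1e-6 * max(abs(fs$fluxes)) + 1e-9)
})

test_that("FBA is deterministic bit-for-bit", {
  m <- make_toy_model()
  a <- solve_fba(m)
  b <- solve_fba(m)
  expect_identical(a$fluxes, b$fluxes)
  expect_identical(a$objective_value, b$objective_value)
})

test_that("MOMA returns the reference when nothing is perturbed", {
  m <- make_toy_model()
  ref <- solve_fba(m)
  ms <- solve_moma(m, ref)
  expect_identical(ms$status, "optimal")
  expect_lt(ms$diagnostics$sq_distance, 1e-12)
  expect_equal(ms$fluxes, ref$fluxes, tolerance = 1e-7)
})

test_that("MOMA honors equality overrides exactly", {
  m <- make_toy_model()
  ref <- solve_fba(m)
  active <- names(which(abs(ref$fluxes) > 1))[1]
  ms <- solve_moma(m, ref, fix_flux(active, 0))
  expect_equal(unname(ms$fluxes[active]), 0, tolerance = 1e-10)
})

test_that("MOMA matches the null-space least-squares oracle", {
  checked <- 0
  for (seed in 1:12) {
    m <- random_wide_instance(seed)
    N <- oracle_nullspace(m$S)
    vref <- withr::with_seed(seed * 7, stats::setNames(
      as.numeric(N %*% stats::rnorm(ncol(N), 0, 3)), m$reaction_ids))
    j <- m$reaction_ids[1]
    target <- 0.5 * vref[[j]]
    oracle <- moma_nullspace_oracle(m, vref, j, target)
    if (is.null(oracle)) next
    ms <- solve_moma(m, vref, fix_flux(j, target))
    expect_identical(ms$status, "optimal")
    expect_equal(unname(ms$fluxes), unname(oracle), tolerance = 1e-6,
                 label = paste("MOMA instance seed", seed))
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("MOMA solution is closer to reference than any sampled feasible point", {
  m <- random_wide_instance(4)
  N <- oracle_nullspace(m$S)
  vref <- withr::with_seed(11, stats::setNames(
    as.numeric(N %*% stats::rnorm(ncol(N), 0, 3)), m$reaction_ids))
  j <- m$reaction_ids[2]
  ov <- fix_flux(j, 0)
  ms <- solve_moma(m, vref, ov)
  # feasible competitors: null-space points of the KO-restricted system
  m_ko <- m
  m_ko$lb[j] <- m_ko$ub[j] <- 0
  pts <- sample_feasible_points(m_ko, 300, seed = 12)
  d_star <- sum((ms$fluxes - vref)^2)
  d_all <- vapply(pts, function(v) sum((v - vref)^2), numeric(1))
  expect_true(all(d_star <= d_all + 1e-9))
})

test_that("flux TSV export writes reaction/flux pairs", {
  m <- chain_model()
  fs <- solve_fba(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flux_tsv(fs, path)
  back <- utils::read.delim(path)
  expect_identical(names(back), c("reaction_id", "flux"))
  expect_equal(back$flux, unname(fs$fluxes))
})
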