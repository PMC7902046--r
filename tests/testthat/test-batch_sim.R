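test_that("the concentration update reproduces the linear depletion rule", {
  # 22 mM glucose, uptake -15 mmol/gDW/h, dt*cell = 0.1 gDW.h/L -> 20.5 mM
  expect_equal(concentration_update(22, -15, cell = 0.1, mu = 0.7, dt = 1,
                                    linear = TRUE), 20.5)
  # the exponential factor reduces to the linear one as mu -> 0
  expect_equal(concentration_update(22, -15, cell = 0.1, mu = 1e-12, dt = 1),
               20.5, tolerance = 1e-9)
  # and exceeds it for growing cultures (expm1(mu dt)/mu > dt)
  expect_lt(concentration_update(22, -15, cell = 0.1, mu = 0.5, dt = 1), 20.5)
})

test_that("a culture started without substrate records a single zero-growth point", {
  m <- make_toy_model()
  cond <- batch_conditions(c(glc_e = 0, prod_e = 0, ac_e = 0), "glc_e")
  ser <- run_wt_batch(m, cond)
  expect_length(ser$times, 1L)
  expect_lte(ser$growth_rates[1], cond$mu_min)
  expect_true(ser$exhausted)
})

test_that("batch conditions are validated", {
  expect_error(batch_conditions(c(glc_e = 22), "glc_e", delta_t = 0),
               "delta_t")
  expect_error(batch_conditions(c(glc_e = -1), "glc_e"), "non-negative")
  expect_error(batch_conditions(c(glc_e = 22), "nope"),
               "primary_substrate")
})

test_that("wild-type trajectory matches the closed-form exponential solution", {
  # constant-yield regime: mu = uptake * yield while glucose is unlimited,
  # so cell(t) = c0 exp(mu t) and glc(t) = glc0 - (u/mu) (cell(t) - c0)
  m <- make_toy_model()
  cond <- batch_conditions(c(glc_e = 22, prod_e = 0, ac_e = 0), "glc_e",
                           delta_t = 0.1)
  ser <- run_wt_batch(m, cond)
  mu0 <- 10 * 0.1
  free <- which(ser$growth_rates > 0.999 * mu0)   # pre-cap phase
  expect_gt(length(free), 10)
  tt <- ser$times[free]
  cells_cf <- cond$initial_cell_density * exp(mu0 * tt)
  glc_cf <- 22 - (10 / mu0) * (cells_cf - cond$initial_cell_density)
  expect_equal(ser$cell_density[free], cells_cf, tolerance = 0.02)
  expect_equal(unname(ser$concentrations[free, "glc_e"]), glc_cf,
               tolerance = 0.02)
})

test_that("batch series invariants hold: monotone substrate, non-negative state", {
  m <- make_toy_model()
  ser <- run_wt_batch(m, toy_conditions())
  expect_true(all(diff(ser$times) > 0))
  expect_true(all(ser$concentrations >= -1e-9))
  expect_true(all(diff(ser$concentrations[, "glc_e"]) <= 1e-9))
  expect_true(all(diff(ser$cell_density) >= -1e-9))
  expect_true(ser$exhausted || max(ser$times) >= ser$conditions$max_time - 1)
})

test_that("carbon is conserved: substrate carbon bounds excreted carbon", {
  # per step: 6C * glucose uptake >= 2C acetate + 1C CO2 + 3C lactate +
  # 1C formate + 4C product excreted (biomass absorbs the remainder)
  m <- make_toy_model()
  ser <- run_wt_batch(m, toy_conditions())
  for (fs in ser$fluxes) {
    if (!identical(fs$status, "optimal")) next
    cin <- -6 * fs$fluxes[["EX_glc_e"]]
    cout <- 2 * fs$fluxes[["EX_ac_e"]] + fs$fluxes[["EX_co2_c"]] +
      3 * fs$fluxes[["EX_lac_e"]] + fs$fluxes[["EX_for_e"]] +
      4 * fs$fluxes[["EX_prod_e"]]
    expect_gte(cin + 1e-6, cout)
  }
})

test_that("empty designs reproduce the wild-type trajectory", {
  m <- make_toy_model()
  wt <- run_wt_batch(m, toy_conditions())
  same <- run_designed_batch(m, wt, function(k, ref) bound_override())
  expect_equal(same$times, wt$times)
  expect_equal(same$cell_density, wt$cell_density, tolerance = 1e-6)
  expect_equal(same$concentrations, wt$concentrations, tolerance = 1e-6)
})

test_that("shutting substrate uptake at t = 0 yields zero growth and product", {
  m <- make_toy_model()
  wt <- run_wt_batch(m, toy_conditions())
  starved <- run_designed_batch(m, wt, function(k, ref) fix_flux("GLCt", 0))
  expect_true(all(starved$growth_rates <= 1e-6))
  expect_equal(final_concentration(starved, "prod_e"), 0, tolerance = 1e-9)
})

test_that("halving the time step changes final product by less than 5%", {
  m <- make_toy_model()
  up <- design(stats::setNames(c(2L, rep(1L, 7)),
                               c("IPPS", setdiff(toy_design_targets(m),
                                                 "IPPS"))))
  prods <- vapply(c(1, 0.5), function(dt) {
    cond <- batch_conditions(c(glc_e = 22, prod_e = 0, ac_e = 0), "glc_e",
                             delta_t = dt)
    wt <- run_wt_batch(m, cond)
    simulate_design_production(m, wt, up, "prod_e")$production
  }, numeric(1))
  expect_gt(prods[1], 0)
  expect_lt(abs(prods[2] - prods[1]) / prods[1], 0.05)
})

test_that("designed-strain fluxes match an independent SLSQP recomputation", {
  # re-solve each time point's adjustment problem with a different
  # optimizer (sequential quadratic programming from nloptr) and propagate
  # independently; final production must agree
  m <- make_toy_model()
  cond <- batch_conditions(c(glc_e = 22, prod_e = 0, ac_e = 0), "glc_e",
                           delta_t = 1, max_time = 8)
  wt <- run_wt_batch(m, cond)
  d <- design(stats::setNames(c(0L, 2L, rep(1L, 6)),
                              c("CS", "IPPS",
                                setdiff(toy_design_targets(m),
                                        c("CS", "IPPS")))))
  got <- simulate_design_production(m, wt, d, "prod_e")

  slsqp_moma <- function(vref, lb, ub) {
    x0 <- pmin(pmax(vref, lb), ub)
    res <- nloptr::slsqp(
      x0, function(x) sum((x - vref)^2), gr = function(x) 2 * (x - vref),
      lower = lb, upper = ub,
      heq = function(x) as.numeric(m$S %*% x), heqjac = function(x) m$S,
      control = list(xtol_rel = 1e-12, maxeval = 5000))
    stats::setNames(res$par, m$reaction_ids)
  }
  expect_false(got$lethal)
  # independent propagation on the same grid, recording before updating as
  # the simulator does (the last recorded state is the production readout)
  conc <- cond$initial_concentrations
  cell <- cond$initial_cell_density
  ex <- m$exchange_map[names(conc)]
  last_recorded <- conc
  for (k in seq_along(wt$times)) {
    ref <- wt$fluxes[[k]]$fluxes
    lb <- m$lb; ub <- m$ub
    ov <- design_to_overrides(d, wt$fluxes[[k]])
    lb[ov$reaction_id] <- ov$lb; ub[ov$reaction_id] <- ov$ub
    # uptake caps as in the simulator
    for (it in 1:10) {
      v <- slsqp_moma(ref, lb, ub)
      mu <- v[[m$objective_id]]
      fac <- if (mu > cond$mu_min) cell * expm1(mu * 1) / mu else cell
      proj <- conc + v[ex] * fac
      viol <- which(proj < -1e-9)
      if (!length(viol)) break
      lb[ex[viol]] <- pmax(lb[ex[viol]], -conc[viol] / fac)
    }
    last_recorded <- conc
    if (conc[["glc_e"]] <= cond$exhaustion_threshold) break
    if (k == length(wt$times)) break
    conc <- pmax(conc + v[ex] * fac, 0)
    cell <- cell * exp(max(mu, 0))
  }
  expect_equal(got$production, unname(last_recorded["prod_e"]),
               tolerance = 1e-4)
})
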