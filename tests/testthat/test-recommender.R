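# Additive synthetic ground truth over a d-reaction space: production is a
# noiseless (or noisy) sum of per-category effects, the closed-form oracle
# for surrogate quality checks.
additive_truth <- function(d, seed, noise_sd = 0) {
  rxns <- paste0("r", seq_len(d))
  effects <- withr::with_seed(seed, matrix(stats::runif(3 * d, -1, 1), 3, d))
  effects[2, ] <- 0                      # NoMod is the neutral category
  list(reactions = rxns, effects = effects,
       value = function(X) {
         base <- apply(X, 1, function(row) {
           5 + sum(effects[cbind(row + 1, seq_along(row))])
         })
         if (noise_sd > 0) base <- base + stats::rnorm(length(base), 0,
                                                       noise_sd)
         pmax(base, 0)
       })
}

lhs_training <- function(truth, n, seed, noise_seed = seed + 100) {
  batch <- latin_hypercube_designs(n, truth$reactions, rng_seed = seed)
  X <- design_matrix(batch)
  y <- withr::with_seed(noise_seed, truth$value(X))
  training_set(X, y)
}

test_that("training sets enforce their invariants", {
  X <- matrix(c(0L, 1L, 2L, 1L), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(training_set(X, c(-1, 2)), ">= 0")
  expect_error(training_set(X, c(1, 2)), "at least")   # n < d + 2
  X4 <- rbind(X, c(2L, 0L), c(2L, 2L))
  expect_silent(training_set(X4, 1:4))
  expect_error(training_set(rbind(X4, c(1L, 1L)), 1:5), "duplicate")
})

test_that("a constant response yields constant certain predictions", {
  truth <- additive_truth(4, seed = 2)
  tr <- lhs_training(truth, 30, seed = 2)
  tr0 <- training_set(tr$X, rep(0, nrow(tr$X)))
  fit <- fit_surrogate(tr0, rng_seed = 1)
  p <- predict(fit, enumerate_design_space(truth$reactions)[1:20, ])
  expect_equal(p$mean, rep(0, 20))
  expect_equal(p$sd, rep(0, 20))
  cv <- crossval_predictions(tr0, folds = 5, rng_seed = 1)
  expect_equal(cv$predicted_mean, rep(0, nrow(tr0$X)))
})

test_that("noiseless additive truth is learned to high cross-validated R2", {
  truth <- additive_truth(8, seed = 5)
  tr <- lhs_training(truth, 96, seed = 5)
  cv <- crossval_predictions(tr, folds = 10, rng_seed = 5,
                             config = surrogate_config(member = "linear"))
  r2 <- 1 - sum((cv$observed - cv$predicted_mean)^2) /
    sum((cv$observed - mean(cv$observed))^2)
  expect_gte(r2, 0.9)
})

test_that("cross-validated RMSE stays near the generator's noise floor", {
  noise_sd <- 0.2
  truth <- additive_truth(6, seed = 9, noise_sd = noise_sd)
  tr <- lhs_training(truth, 96, seed = 9)
  cv <- crossval_predictions(tr, folds = 10, rng_seed = 9,
                             config = surrogate_config(member = "linear"))
  rmse <- sqrt(mean((cv$observed - cv$predicted_mean)^2))
  expect_lt(rmse, noise_sd * 1.2 + 0.1)
})

test_that("fold assignment partitions the instances exactly once", {
  truth <- additive_truth(5, seed = 3)
  tr <- lhs_training(truth, 40, seed = 3)
  cv <- crossval_predictions(tr, folds = 7, rng_seed = 3)
  expect_identical(nrow(cv), 40L)
  expect_true(all(table(cv$fold) %in% c(5L, 6L)))
  expect_error(crossval_predictions(tr, folds = 41, rng_seed = 1),
               "more folds")
  expect_error(crossval_predictions(tr, folds = 1, rng_seed = 1),
               "at least 2")
})

test_that("row order does not change the fitted model for a fixed seed", {
  truth <- additive_truth(5, seed = 4)
  tr <- lhs_training(truth, 40, seed = 4)
  perm <- withr::with_seed(77, sample(nrow(tr$X)))
  tr_perm <- training_set(tr$X[perm, ], tr$y[perm])
  f1 <- fit_surrogate(tr, rng_seed = 11)
  f2 <- fit_surrogate(tr_perm, rng_seed = 11)
  cand <- enumerate_design_space(truth$reactions)[seq(1, 243, by = 11), ]
  expect_equal(predict(f1, cand), predict(f2, cand))
})

test_that("the held-out optimum of a noiseless truth is recommended first", {
  truth <- additive_truth(3, seed = 6)
  space <- enumerate_design_space(truth$reactions)
  y <- truth$value(space)
  best <- which.max(y)
  tr <- training_set(space[-best, ], y[-best])
  fit <- fit_surrogate(tr, surrogate_config(member = "linear"),
                       rng_seed = 2)
  recs <- recommend(fit, k = 1)
  expect_identical(unname(as.integer(recs[1, truth$reactions])),
                   unname(space[best, ]))
})

test_that("recommendations are unseen, distinct, and bounded by the space", {
  truth <- additive_truth(8, seed = 8)
  tr <- lhs_training(truth, 96, seed = 8)
  fit <- fit_surrogate(tr, rng_seed = 8)
  recs <- recommend(fit, k = 10)
  mat <- as.matrix(recs[, truth$reactions])
  expect_identical(nrow(mat), 10L)
  expect_identical(anyDuplicated(mat), 0L)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_length(intersect(key(mat), key(tr$X)), 0)
  # exhausting the space is an error
  space3 <- enumerate_design_space(paste0("r", 1:3))
  y3 <- truth$value(space3[, 1:3, drop = FALSE] * 0 + space3 * 0 + 1)
  full <- training_set(space3, seq_len(nrow(space3)))
  ffit <- fit_surrogate(full, rng_seed = 1)
  expect_error(recommend(ffit, k = 1), "no unseen")
  expect_error(recommend(fit, k = 1e6), "exceeds")
})

test_that("predictive uncertainty shrinks as training grows from 24 to 96", {
  truth <- additive_truth(8, seed = 10, noise_sd = 0.1)
  cand <- enumerate_design_space(truth$reactions)[seq(1, 6561, by = 37), ]
  mean_sd <- vapply(c(24, 96), function(n) {
    tr <- lhs_training(truth, n, seed = 10)
    fit <- fit_surrogate(tr, surrogate_config(member = "linear"),
                         rng_seed = 10)
    mean(predict(fit, cand)$sd)
  }, numeric(1))
  expect_lt(mean_sd[2], mean_sd[1])
})

test_that("recommendation files round-trip through the CSV/TSV dialect", {
  truth <- additive_truth(4, seed = 12)
  tr <- lhs_training(truth, 30, seed = 12)
  fit <- fit_surrogate(tr, rng_seed = 12)
  recs <- recommend(fit, k = 5)
  dpath <- withr::local_tempfile(fileext = ".csv")
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_recommendations(recs, dpath, ppath)
  back <- read_designs_csv(dpath, includes_wt = FALSE)
  expect_equal(unname(design_matrix(back)),
               unname(as.matrix(recs[, truth$reactions])))
  preds <- readr::read_tsv(ppath, show_col_types = FALSE)
  expect_equal(preds$mean, recs$mean)
})
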