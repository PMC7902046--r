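#' Training set for the production surrogate
#'
#' Pairs of categorical designs and their (simulated or measured) production
#' responses.
#'
#' @param X Integer matrix or data frame, one row per strain, one column per
#'   target reaction, entries in \{0, 1, 2\}; no duplicate rows.
#' @param y Numeric vector of non-negative production responses (mM).
#' @return A list of class `training_set`.
#' @export
training_set <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) {
    stop("training X must have reaction ids as column names", call. = FALSE)
  }
  if (!all(X %in% 0:2)) stop("categories must be in {0,1,2}", call. = FALSE)
  if (anyDuplicated(X)) stop("duplicate design rows in X", call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  if (any(y < 0)) stop("production responses must be >= 0", call. = FALSE)
  if (nrow(X) < ncol(X) + 2) {
    stop("need at least ", ncol(X) + 2, " instances to fit (have ",
         nrow(X), ")", call. = FALSE)
  }
  structure(list(X = X, y = as.numeric(y)), class = "training_set")
}

#' Surrogate configuration
#'
#' @param n_members Number of bootstrap ensemble members. Default 200.
#' @param member Base learner for each ensemble member: `"tree"` (a regression
#'   tree on the categorical inputs; captures the strong interactions of
#'   knockout landscapes, e.g. a modification that is beneficial only when a
#'   competing pathway is intact) or `"linear"` (rank-safe least squares on
#'   one-hot indicators; appropriate for additive responses).
#' @param acquisition `"median"` (default) ranks candidate designs by the
#'   ensemble median of predicted production, which is robust to the
#'   strongly bimodal member predictions that arise when part of the
#'   bootstrap ensemble classifies a candidate as non-viable; `"mean"` is
#'   classical pure exploitation; `"expected_improvement"` ranks by expected
#'   improvement over the best training response, estimated from the
#'   ensemble samples.
#' @param tree_control An [rpart::rpart.control()] list for tree members;
#'   the default grows deep trees (`minsplit = 5`, `cp = 0.002`) because the
#'   bootstrap ensemble, not pruning, supplies the variance control.
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(n_members = 200,
                             member = c("tree", "linear"),
                             acquisition = c("median", "mean",
                                             "expected_improvement"),
                             tree_control = rpart::rpart.control(
                               minsplit = 5, cp = 0.002, xval = 0)) {
  stopifnot(n_members >= 2)
  structure(list(n_members = n_members,
                 member = match.arg(member),
                 acquisition = match.arg(acquisition),
                 tree_control = tree_control),
            class = "surrogate_config")
}

# One-hot encoding of the categorical design matrix: intercept + KO and UP
# indicators per reaction (NoMod is the baseline level).
one_hot <- function(X) {
  d <- ncol(X)
  out <- matrix(0, nrow(X), 1 + 2 * d)
  out[, 1] <- 1
  for (j in seq_len(d)) {
    out[, 2 * j] <- as.numeric(X[, j] == 0L)
    out[, 2 * j + 1] <- as.numeric(X[, j] == 2L)
  }
  colnames(out) <- c("(intercept)",
                     as.vector(rbind(paste0(colnames(X), ":KO"),
                                     paste0(colnames(X), ":UP"))))
  out
}

# Rank-safe least squares: pivoted QR, unidentifiable coefficients set to 0
# (a bootstrap resample can lose a category level entirely).
fit_linear_member <- function(Z, y) {
  qz <- qr(Z)
  beta <- qr.coef(qz, y)
  beta[is.na(beta)] <- 0
  beta
}

# Categorical data frame view of a design matrix (factor levels fixed to the
# full category set so resamples and candidates always align).
as_factor_frame <- function(X) {
  df <- as.data.frame(lapply(seq_len(ncol(X)), function(j) {
    factor(X[, j], levels = 0:2)
  }))
  names(df) <- colnames(X)
  df
}

#' Fit the probabilistic production surrogate
#'
#' A bootstrap ensemble of rank-safe linear regressions on one-hot-encoded
#' design categories. Each of `n_members` members is fit on a bootstrap
#' resample of the training rows; the spread of member predictions is the
#' predictive uncertainty. Rows are internally processed in a canonical
#' (lexicographic) design order, so permuting the training rows leaves the
#' fitted model unchanged for a fixed seed. This surrogate reproduces the
#' decision-relevant interface of heavier Bayesian recommendation engines
#' (probabilistic predictions, mean ranking with uncertainty) without their
#' posterior machinery.
#'
#' @param training A [training_set()].
#' @param config A [surrogate_config()].
#' @param rng_seed Integer seed governing the bootstrap resamples.
#' @return An object of class `surrogate_model`.
#' @export
fit_surrogate <- function(training, config = surrogate_config(),
                          rng_seed = 1) {
  stopifnot(inherits(training, "training_set"))
  ord <- do.call(order, split(training$X, col(training$X)))
  X <- training$X[ord, , drop = FALSE]
  y <- training$y[ord]
  n <- nrow(X)
  members <- withr::with_seed(rng_seed, {
    if (config$member == "linear") {
      Z <- one_hot(X)
      lapply(seq_len(config$n_members), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        fit_linear_member(Z[idx, , drop = FALSE], y[idx])
      })
    } else {
      df <- as_factor_frame(X)
      df$.y <- y
      lapply(seq_len(config$n_members), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                     method = "anova", control = config$tree_control)
      })
    }
  })
  structure(list(members = members, reactions = colnames(training$X),
                 X_train = X, y_train = y, config = config,
                 rng_seed = rng_seed),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("surrogate_model:", length(x$members), "bootstrap members over",
      length(x$reactions), "target reactions,", nrow(x$X_train),
      "training designs\n")
  invisible(x)
}

#' Predictive distributions for candidate designs
#'
#' @param object A [fit_surrogate()] model.
#' @param newX Integer matrix of candidate designs (columns matching the
#'   training reactions).
#' @param ... Unused.
#' @return A tibble with one row per candidate: `mean`, `sd`, quantiles
#'   `q05`/`q50`/`q95` of the ensemble; the full member-by-candidate sample
#'   matrix is attached as attribute `"samples"`.
#' @export
predict.surrogate_model <- function(object, newX, ...) {
  newX <- as.matrix(newX)
  if (!identical(colnames(newX), object$reactions)) {
    newX <- newX[, object$reactions, drop = FALSE]
  }
  samples <- if (object$config$member == "linear") {
    Z <- one_hot(newX)
    vapply(object$members, function(beta) as.numeric(Z %*% beta),
           numeric(nrow(newX)))
  } else {
    df <- as_factor_frame(newX)
    vapply(object$members, function(tr) {
      unname(stats::predict(tr, newdata = df))
    }, numeric(nrow(newX)))
  }
  samples <- matrix(samples, nrow = nrow(newX))
  qs <- t(apply(samples, 1, stats::quantile, probs = c(0.05, 0.5, 0.95),
                names = FALSE))
  out <- tibble::tibble(
    mean = rowMeans(samples),
    sd = apply(samples, 1, stats::sd),
    q05 = qs[, 1], q50 = qs[, 2], q95 = qs[, 3])
  attr(out, "samples") <- samples
  out
}

#' Cross-validated predictions
#'
#' k-fold cross-validation of the surrogate: each training instance is
#' predicted exactly once, by an ensemble that never saw it.
#'
#' @param training A [training_set()].
#' @param folds Number of folds (>= 2, <= number of instances). Default 10.
#' @param rng_seed Integer seed (fold assignment and member bootstraps).
#' @param config A [surrogate_config()].
#' @return A tibble with columns `observed`, `predicted_mean`,
#'   `predicted_sd`, `fold`, in the original row order of `training`.
#' @export
crossval_predictions <- function(training, folds = 10, rng_seed = 1,
                                 config = surrogate_config()) {
  n <- nrow(training$X)
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  if (folds > n) stop("more folds (", folds, ") than instances (", n, ")",
                      call. = FALSE)
  assignment <- withr::with_seed(rng_seed,
                                 sample(rep_len(seq_len(folds), n)))
  pred_mean <- pred_sd <- numeric(n)
  for (f in seq_len(folds)) {
    test <- which(assignment == f)
    train <- which(assignment != f)
    ts <- training_set(training$X[train, , drop = FALSE], training$y[train])
    model <- fit_surrogate(ts, config, rng_seed = rng_seed + f)
    p <- stats::predict(model, training$X[test, , drop = FALSE])
    pred_mean[test] <- p$mean
    pred_sd[test] <- p$sd
  }
  tibble::tibble(observed = training$y, predicted_mean = pred_mean,
                 predicted_sd = pred_sd, fold = assignment)
}

#' Recommend the top-k unseen designs
#'
#' Exhaustively scores every category vector of the design space
#' (`3^d <= 1e6` enforced), removes designs present in the training set (and
#' any extra exclusions), and returns the `k` best by the acquisition rule —
#' by default decreasing ensemble-median predicted production. Ties are
#' broken by higher predicted mean, lower predicted sd, then lexicographic
#' category order, so the ranking is deterministic.
#'
#' @param model A [fit_surrogate()] model.
#' @param k Number of recommendations (>= 1).
#' @param exclude Optional extra design matrix to exclude (the training set
#'   is always excluded).
#' @param n_categories Number of categories per reaction. Default 3.
#' @return A `recommendation_set`: tibble with the design columns, `rank`,
#'   and predictive summaries (`mean`, `sd`, `q05`, `q50`, `q95`).
#' @export
recommend <- function(model, k, exclude = NULL, n_categories = 3) {
  stopifnot(k >= 1)
  space <- enumerate_design_space(model$reactions, n_categories)
  seen <- rbind(model$X_train,
                if (!is.null(exclude)) as.matrix(exclude))
  key <- function(m) apply(m, 1, paste, collapse = ",")
  unseen <- space[!(key(space) %in% key(seen)), , drop = FALSE]
  if (!nrow(unseen)) stop("no unseen designs left to recommend",
                          call. = FALSE)
  if (k > nrow(unseen)) {
    stop("k = ", k, " exceeds the ", nrow(unseen), " unseen designs",
         call. = FALSE)
  }
  p <- stats::predict(model, unseen)
  score <- switch(model$config$acquisition,
    expected_improvement = {
      best <- max(model$y_train)
      rowMeans(pmax(attr(p, "samples") - best, 0))
    },
    median = p$q50,
    mean = p$mean)
  lex <- do.call(order, split(unseen, col(unseen)))
  lex_rank <- order(lex)
  ord <- order(-score, -p$mean, p$sd, lex_rank)
  top <- ord[seq_len(k)]
  out <- tibble::as_tibble(as.data.frame(unseen[top, , drop = FALSE]))
  out$rank <- seq_len(k)
  out$mean <- p$mean[top]
  out$sd <- p$sd[top]
  out$q05 <- p$q05[top]
  out$q50 <- p$q50[top]
  out$q95 <- p$q95[top]
  class(out) <- c("recommendation_set", class(out))
  out
}

#' Write recommendations: designs CSV plus predictions TSV
#'
#' Emits the recommended designs in the same CSV dialect as
#' [write_designs_csv()] and, alongside, a TSV of the predictive summaries.
#'
#' @param recs A `recommendation_set` from [recommend()].
#' @param design_path Path for the designs CSV.
#' @param prediction_path Path for the predictions TSV.
#' @return `design_path`, invisibly.
#' @export
write_recommendations <- function(recs, design_path, prediction_path) {
  rxns <- setdiff(names(recs), c("rank", "mean", "sd", "q05", "q50", "q95"))
  designs <- lapply(seq_len(nrow(recs)), function(i) {
    design(stats::setNames(as.integer(unlist(recs[i, rxns])), rxns),
           label = paste0("REC", recs$rank[i]))
  })
  write_designs_csv(design_batch(designs, includes_wt = FALSE), design_path)
  readr::write_tsv(recs[, c("rank", "mean", "sd", "q05", "q50", "q95")],
                   prediction_path)
  invisible(design_path)
}
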