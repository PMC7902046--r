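#' A categorical strain design
#'
#' An ordered map from target reaction id to a modification category:
#' 0 = knockout (KO), 1 = no modification (NoMod), 2 = flux doubling (UP).
#' The all-1 design is the canonical wild type.
#'
#' @param categories Named integer vector with values in \{0, 1, 2\}; names
#'   are target reaction ids.
#' @param label Line-name string; defaults to `"WT"` for the all-1 design and
#'   a category signature otherwise.
#' @return An object of class `design`.
#' @export
design <- function(categories, label = NULL) {
  categories <- stats::setNames(as.integer(categories), names(categories))
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("design categories must be named by reaction id", call. = FALSE)
  }
  if (!all(categories %in% 0:2)) {
    stop("design categories must be 0 (KO), 1 (NoMod) or 2 (UP)",
         call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (all(categories == 1L)) "WT"
             else paste0("D", paste(categories, collapse = ""))
  }
  structure(list(categories = categories, label = label), class = "design")
}

is_wt_design <- function(d) all(d$categories == 1L)

#' @export
print.design <- function(x, ...) {
  cat("design", x$label, ":",
      paste(names(x$categories), x$categories, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' A batch of distinct designs
#'
#' @param designs List of [design()] objects over identical target reactions,
#'   pairwise distinct in their category vectors.
#' @param includes_wt Whether the batch is expected to contain exactly one
#'   all-1 (wild-type) design.
#' @return An object of class `design_batch`.
#' @export
design_batch <- function(designs, includes_wt = TRUE) {
  mat <- do.call(rbind, lapply(designs, function(d) d$categories))
  if (anyDuplicated(mat)) {
    stop("design batch contains duplicate category vectors", call. = FALSE)
  }
  n_wt <- sum(apply(mat, 1, function(r) all(r == 1L)))
  if (includes_wt && n_wt != 1L) {
    stop("batch flagged includes_wt must contain exactly one all-1 design",
         call. = FALSE)
  }
  structure(list(designs = designs, includes_wt = includes_wt),
            class = "design_batch")
}

#' @export
print.design_batch <- function(x, ...) {
  cat("design_batch:", length(x$designs), "designs over",
      length(x$designs[[1]]$categories), "target reactions\n")
  invisible(x)
}

#' Category matrix of a design batch
#'
#' @param batch A [design_batch()].
#' @return Integer matrix, one row per design, columns named by target
#'   reaction; row names are design labels.
#' @export
design_matrix <- function(batch) {
  mat <- do.call(rbind, lapply(batch$designs, function(d) d$categories))
  rownames(mat) <- vapply(batch$designs, function(d) d$label, character(1))
  mat
}

#' Size of a categorical design space
#'
#' `n_categories ^ n_reactions`, computed in double precision with an
#' overflow guard (exact for results below 2^53).
#'
#' @param n_reactions Number of target reactions (>= 1).
#' @param n_categories Number of categories per reaction (>= 1).
#' @return The number of possible designs, as a numeric scalar.
#' @export
design_space_size <- function(n_reactions, n_categories) {
  stopifnot(n_reactions >= 1, n_categories >= 1)
  size <- as.numeric(n_categories)^as.numeric(n_reactions)
  if (size > 2^53) {
    stop("design space size exceeds exact integer range (", n_categories,
         "^", n_reactions, ")", call. = FALSE)
  }
  size
}

#' Enumerate every category vector of a design space
#'
#' @param reactions Character vector of target reaction ids.
#' @param n_categories Number of categories. Default 3.
#' @return Integer matrix with `n_categories^length(reactions)` rows, columns
#'   named by `reactions`, entries in `0:(n_categories-1)`.
#' @export
enumerate_design_space <- function(reactions, n_categories = 3) {
  d <- length(reactions)
  size <- design_space_size(d, n_categories)
  if (size > 1e6) {
    stop("refusing to enumerate ", size, " designs; space too large",
         call. = FALSE)
  }
  grid <- as.matrix(expand.grid(rep(list(0:(n_categories - 1)), d),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- reactions
  storage.mode(grid) <- "integer"
  grid
}

# Continuous [0,1] coordinate -> category: floor(3x), clipped to 2 at x = 1.
coordinate_to_category <- function(x, n_categories = 3) {
  out <- pmin(floor(n_categories * x), n_categories - 1)
  storage.mode(out) <- "integer"
  out
}

#' Latin-hypercube sample of initial designs
#'
#' Draws `n - 1` space-filling points from a Latin hypercube on the unit cube
#' `[0,1]^d`, maps each coordinate to a category via `floor(3 x)` (clipped to
#' 2 at `x = 1`), deduplicates by redrawing collided rows (keeping the
#' stratified rows that did not collide), and appends the all-1 wild-type
#' design — yielding exactly `n` distinct designs, the initial-cycle batch
#' for surrogate training.
#'
#' @param n Total number of designs including the appended wild type.
#' @param reactions Character vector of target reaction ids (the hypercube
#'   dimensions).
#' @param rng_seed Integer seed.
#' @param n_categories Number of categories. Default 3.
#' @return A [design_batch()] of `n` distinct designs with one wild type.
#' @export
latin_hypercube_designs <- function(n, reactions, rng_seed,
                                    n_categories = 3) {
  d <- length(reactions)
  size <- design_space_size(d, n_categories)
  if (n > size) {
    stop("requested ", n, " designs but the space has only ", size,
         call. = FALSE)
  }
  stopifnot(n >= 1)
  withr::with_seed(rng_seed, {
    cats <- if (n > 1) {
      coordinate_to_category(lhs::randomLHS(n - 1, d), n_categories)
    } else {
      matrix(integer(0), 0, d)
    }
    wt_row <- rep(1L, d)
    key <- function(m) apply(m, 1, paste, collapse = ",")
    for (iter in 1:1000) {
      dup <- duplicated(key(cats)) | key(cats) == paste(wt_row, collapse = ",")
      if (!any(dup)) break
      redraw <- matrix(stats::runif(sum(dup) * d), ncol = d)
      cats[dup, ] <- coordinate_to_category(redraw, n_categories)
      if (iter == 1000) {
        stop("could not deduplicate designs after 1000 redraws", call. = FALSE)
      }
    }
    dim(cats) <- c(n - 1L, d)
    cats <- rbind(cats, wt_row)
    colnames(cats) <- reactions
    designs <- lapply(seq_len(nrow(cats)), function(i) {
      design(stats::setNames(cats[i, ], reactions))
    })
    design_batch(designs, includes_wt = TRUE)
  })
}

#' Translate a design into MOMA bound overrides
#'
#' Category 0 (KO) fixes the flux to zero; category 2 (UP) fixes it to twice
#' the wild-type flux of the supplied reference; category 1 (NoMod) leaves
#' the reaction free. Doubling a zero wild-type flux yields the (documented)
#' no-op constraint `0 = 2 * 0`.
#'
#' @param design A [design()].
#' @param wt_flux The wild-type [flux_state()] at the relevant time point.
#' @return A [bound_override()] (possibly empty, for the wild type).
#' @export
design_to_overrides <- function(design, wt_flux) {
  cats <- design$categories
  ids <- names(cats)
  ko <- ids[cats == 0L]
  up <- ids[cats == 2L]
  targets <- c(rep(0, length(ko)), 2 * as.numeric(wt_flux$fluxes[up]))
  fix_flux(c(ko, up), targets)
}

#' Simulated production of a designed strain
#'
#' Runs [run_designed_batch()] with per-time-point overrides recomputed from
#' the wild-type flux of each time point (so the UP category doubles the
#' contemporaneous wild-type flux), and reads off the final extracellular
#' concentration of the target metabolite. A lethal design (MOMA infeasible
#' at the first time point) yields zero production, flagged.
#'
#' @param model A [metabolic_model()].
#' @param wt_series A [run_wt_batch()] series on `model`.
#' @param design A [design()].
#' @param target_metabolite Extracellular target metabolite id (must be
#'   tracked in the series or have an exchange reaction).
#' @param control A [solver_control()].
#' @param overlay_wt Passed to [run_designed_batch()].
#' @return List with `production` (mM), `lethal` flag, and the engineered
#'   `series`.
#' @export
simulate_design_production <- function(model, wt_series, design,
                                       target_metabolite,
                                       control = solver_control(),
                                       overlay_wt = FALSE) {
  if (!(target_metabolite %in%
        colnames(wt_series$concentrations))) {
    stop("target metabolite '", target_metabolite,
         "' is not tracked in the wild-type series; add it to ",
         "initial_concentrations", call. = FALSE)
  }
  series <- run_designed_batch(
    model, wt_series,
    overrides_fn = function(k, wt_flux) design_to_overrides(design, wt_flux),
    control = control, overlay_wt = overlay_wt)
  list(production = final_concentration(series, target_metabolite),
       lethal = series$lethal, series = series)
}

#' Write / read a design batch as CSV
#'
#' One column per target reaction (categories 0/1/2) plus a `line_name`
#' column; the structure the surrogate trains on and the dialect emitted for
#' recommendations.
#'
#' @param batch A [design_batch()].
#' @param path File path.
#' @return `path` (writer) or a [design_batch()] (reader).
#' @export
write_designs_csv <- function(batch, path) {
  mat <- design_matrix(batch)
  df <- data.frame(line_name = rownames(mat), mat, check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_designs_csv
#' @param includes_wt Passed to [design_batch()] on read.
#' @export
read_designs_csv <- function(path, includes_wt = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!("line_name" %in% names(df))) {
    stop("designs CSV must have a line_name column", call. = FALSE)
  }
  rxns <- setdiff(names(df), "line_name")
  designs <- lapply(seq_len(nrow(df)), function(i) {
    design(stats::setNames(as.integer(unlist(df[i, rxns])), rxns),
           label = df$line_name[i])
  })
  design_batch(designs, includes_wt = includes_wt)
}
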