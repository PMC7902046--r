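#' Load a metabolic model from file
#'
#' Reads either the COBRA-style JSON dialect (as written by COBRApy and
#' [write_cobra_json()]) or SBML Level 3 with the `fbc` package (flux bounds
#' and objective). Exchange reactions are auto-detected (single nonzero
#' stoichiometric entry) when not annotated.
#'
#' @param path Path to the model file.
#' @param format `"auto"` (by extension: `.json` vs `.xml`/`.sbml`),
#'   `"cobra-json"` or `"sbml"`.
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "cobra-json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "cobra-json"
              else "sbml"
  }
  switch(format,
         "cobra-json" = read_cobra_json(path),
         "sbml" = read_sbml_model(path))
}

read_cobra_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("COBRA-JSON parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("COBRA-JSON format error: missing 'metabolites' or 'reactions' list",
         call. = FALSE)
  }
  met_ids <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("COBRA-JSON format error: metabolite without id",
                            call. = FALSE)
    m$id
  }, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("COBRA-JSON format error: reaction without id",
                            call. = FALSE)
    r$id
  }, character(1))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  obj <- character(0)
  for (r in doc$reactions) {
    for (met in names(r$metabolites)) {
      if (!(met %in% met_ids)) {
        stop("COBRA-JSON format error: reaction '", r$id,
             "' references unknown metabolite '", met, "'", call. = FALSE)
      }
      S[met, r$id] <- as.numeric(r$metabolites[[met]])
    }
    lb[r$id] <- if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound)
    ub[r$id] <- if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
    oc <- if (is.null(r$objective_coefficient)) 0
          else as.numeric(r$objective_coefficient)
    if (oc != 0) obj <- c(obj, r$id)
  }
  if (length(obj) != 1L) {
    stop("model configuration error: expected exactly one objective ",
         "reaction, found ", length(obj), call. = FALSE)
  }
  metabolic_model(met_ids, rxn_ids, S, lb, ub, objective_id = obj)
}

#' Write a metabolic model as COBRA-style JSON
#'
#' Emits the JSON dialect used by COBRApy (`metabolites`, `reactions` with
#' per-reaction `metabolites` maps, bounds and `objective_coefficient`), so
#' models round-trip through [load_model()] and are readable by external
#' COBRA tooling.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @param id Model id string stored in the file.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(model, path, id = "omgsim_model") {
  mets <- lapply(model$metabolite_ids, function(m) {
    list(id = m, name = m, compartment = sub("^.*_", "", m))
  })
  rxns <- lapply(model$reaction_ids, function(r) {
    nz <- which(model$S[, r] != 0)
    list(id = r,
         name = r,
         metabolites = as.list(stats::setNames(model$S[nz, r],
                                               model$metabolite_ids[nz])),
         lower_bound = unname(model$lb[r]),
         upper_bound = unname(model$ub[r]),
         objective_coefficient = if (r == model$objective_id) 1 else 0,
         gene_reaction_rule = "")
  })
  doc <- list(id = id, version = "1", metabolites = mets, reactions = rxns,
              genes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# SBML Level 3 + fbc reader. Bounds are fbc:lowerFluxBound /
# fbc:upperFluxBound attributes resolving through listOfParameters; the
# objective is the first flux objective of the active fbc objective.
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met_ids <- xml2::xml_attr(species, "id")
  if (!length(met_ids)) {
    stop("SBML format error: no species found (element listOfSpecies)",
         call. = FALSE)
  }
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  resolve_bound <- function(pid, rxn, default) {
    if (is.na(pid)) return(default)
    if (!(pid %in% names(pval))) {
      stop("SBML format error: reaction '", rxn, "' references undefined ",
           "bound parameter '", pid, "'", call. = FALSE)
    }
    pval[[pid]]
  }
  for (i in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[i]]
    rid <- rxn_ids[i]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, paste0("./s:", side, "/s:speciesReference"), ns)
      sgn <- if (side == "listOfReactants") -1 else 1
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(st)) st <- 1
        if (!(sp %in% met_ids)) {
          stop("SBML format error: reaction '", rid,
               "' references unknown species '", sp, "'", call. = FALSE)
        }
        S[sp, rid] <- S[sp, rid] + sgn * st
      }
    }
    lb[rid] <- resolve_bound(xml2::xml_attr(node, "fbc:lowerFluxBound", ns),
                             rid, -1000)
    ub[rid] <- resolve_bound(xml2::xml_attr(node, "fbc:upperFluxBound", ns),
                             rid, 1000)
  }
  fobj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective//fbc:fluxObjective", ns)
  if (inherits(fobj, "xml_missing")) {
    stop("model configuration error: SBML file declares no fbc objective",
         call. = FALSE)
  }
  obj_id <- xml2::xml_attr(fobj, "fbc:reaction", ns)
  metabolic_model(met_ids, rxn_ids, S, lb, ub, objective_id = obj_id)
}

#' Write a metabolic model as SBML Level 3 with fbc
#'
#' Minimal but standards-conformant writer: species, reactions with
#' reactant/product speciesReferences, bound parameters and an active
#' maximization objective. Primarily used so models written here round-trip
#' through [load_model()] and external SBML tooling.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @param id Model id string.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path, id = "omgsim_model") {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(id), '" fbc:strict="true">'),
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '    <listOfSpecies>')
  for (m in model$metabolite_ids) {
    lines <- c(lines, paste0(
      '      <species id="', esc(m), '" compartment="c" ',
      'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"/>'))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (j in seq_along(model$reaction_ids)) {
    r <- model$reaction_ids[j]
    lines <- c(lines,
      paste0('      <parameter id="lb_', j, '" value="', num(model$lb[r]),
             '" constant="true"/>'),
      paste0('      <parameter id="ub_', j, '" value="', num(model$ub[r]),
             '" constant="true"/>'))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_along(model$reaction_ids)) {
    r <- model$reaction_ids[j]
    col <- model$S[, r]
    reactants <- names(col)[col < 0]
    products <- names(col)[col > 0]
    lines <- c(lines, paste0(
      '      <reaction id="', esc(r), '" reversible="',
      tolower(model$lb[r] < 0), '" fast="false" fbc:lowerFluxBound="lb_', j,
      '" fbc:upperFluxBound="ub_', j, '">'))
    if (length(reactants)) {
      lines <- c(lines, '        <listOfReactants>')
      for (m in reactants) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', esc(m),
          '" stoichiometry="', num(-col[m]), '" constant="true"/>'))
      }
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(products)) {
      lines <- c(lines, '        <listOfProducts>')
      for (m in products) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', esc(m),
          '" stoichiometry="', num(col[m]), '" constant="true"/>'))
      }
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    paste0('          <fbc:fluxObjective fbc:reaction="',
           esc(model$objective_id), '" fbc:coefficient="1"/>'),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Download a published genome-scale model (network required)
#'
#' Convenience helper for users who want to re-run the workflow on a real
#' genome-scale reconstruction (e.g. iJO1366 from the BiGG database) instead
#' of the built-in toy network. Requires network access and is never invoked
#' by the test suite; all shipped analyses run on [make_toy_model()].
#'
#' @param url URL of a COBRA-JSON model, default the BiGG iJO1366 entry.
#' @param dest Destination file path.
#' @return `dest`, invisibly.
#' @export
download_genome_scale_model <- function(
    url = "http://bigg.ucsd.edu/static/models/iJO1366.json",
    dest = "iJO1366.json") {
  utils::download.file(url, dest, mode = "wb", quiet = TRUE)
  invisible(dest)
}
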