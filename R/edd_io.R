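#' Closed unit vocabulary of the generic measurement format
#'
#' `FPKM` (transcripts), `proteins/cell` (proteins), `mg/L` and `mM`
#' (metabolites), and the empty string for optical density, which carries no
#' unit.
#'
#' @return Character vector of admissible units.
#' @export
edd_units <- function() c("FPKM", "proteins/cell", "mg/L", "mM", "")

edd_metabolite_units <- function() c("mg/L", "mM")

# Canonical identifier spelling: "CID:715" (colon, no space); parsing is
# tolerant of "CID: 715".
canonical_measurement_id <- function(id) {
  sub("^CID:\\s+", "CID:", id)
}

#' Build and validate generic measurement records
#'
#' The five-column interchange rows: line name, typed measurement identifier
#' (PubChem CID for metabolites, UniProt for proteins, GenBank gene id for
#' transcripts), time in hours, value, and unit from the closed vocabulary
#' ([edd_units()]). CID-typed identifiers may only carry metabolite units.
#'
#' @param line_name Character vector of line (strain/condition) names.
#' @param measurement_id Character vector of typed identifiers.
#' @param time Numeric vector of time points, hours, >= 0.
#' @param value Numeric vector of measured values.
#' @param unit Character vector of units.
#' @return A validated tibble of class `edd_records`.
#' @export
edd_records <- function(line_name, measurement_id, time, value, unit) {
  rec <- tibble::tibble(line_name = as.character(line_name),
                        measurement_id = canonical_measurement_id(
                          as.character(measurement_id)),
                        time = as.numeric(time),
                        value = as.numeric(value),
                        unit = as.character(unit))
  validate_edd_records(rec)
  class(rec) <- c("edd_records", class(rec))
  rec
}

#' @rdname edd_records
#' @param records A tibble/data frame with the five record columns.
#' @export
validate_edd_records <- function(records) {
  bad_unit <- which(!(records$unit %in% edd_units()))
  if (length(bad_unit)) {
    stop("invalid unit(s) outside the closed vocabulary at row(s) ",
         paste(utils::head(bad_unit, 10), collapse = ", "), ": ",
         paste(unique(records$unit[bad_unit]), collapse = ", "),
         call. = FALSE)
  }
  cid <- grepl("^CID:", records$measurement_id)
  bad_pair <- which(cid & !(records$unit %in% edd_metabolite_units()))
  if (length(bad_pair)) {
    stop("CID-typed identifiers require a metabolite unit (mg/L or mM); ",
         "offending row(s): ",
         paste(utils::head(bad_pair, 10), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  invisible(records)
}

edd_default_headers <- function() {
  c("Line Name", "Measurement Type", "Time", "Value", "Units")
}

#' Write the generic five-column measurement CSV
#'
#' Columns in the interchange order (line, measurement id, time, value,
#' unit), one header row, UTF-8, rows sorted by (line, measurement id, time)
#' for stable output.
#'
#' @param records An [edd_records()] tibble.
#' @param path Output file path.
#' @param headers Header strings for the five columns; instances of the data
#'   depot differ, so they are configurable. Default
#'   `c("Line Name", "Measurement Type", "Time", "Value", "Units")`.
#' @return `path`, invisibly.
#' @export
write_edd_generic <- function(records, path,
                              headers = edd_default_headers()) {
  validate_edd_records(records)
  ord <- order(records$line_name, records$measurement_id, records$time)
  out <- records[ord, c("line_name", "measurement_id", "time", "value",
                        "unit")]
  names(out) <- headers
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read the generic five-column measurement CSV
#'
#' Strict parse: exactly five columns, numeric time and value, units from the
#' closed vocabulary, identifier/unit pairing enforced. Errors cite the
#' offending data row.
#'
#' @param path File path.
#' @return A validated [edd_records()] tibble.
#' @export
read_edd_generic <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), na = character())
  if (ncol(raw) != 5) {
    stop("generic measurement file must have exactly 5 columns (found ",
         ncol(raw), ")", call. = FALSE)
  }
  names(raw) <- c("line_name", "measurement_id", "time", "value", "unit")
  time <- suppressWarnings(as.numeric(raw$time))
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(time) | is.na(value))
  if (length(bad)) {
    stop("unparseable time/value at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  edd_records(raw$line_name, raw$measurement_id, time, value, raw$unit)
}

#' Write an experiment-description CSV
#'
#' One row per line: line name, part id (strain-registry accession), then any
#' metadata columns (temperature, shaking speed, ...), in a deterministic
#' column order. Contains no measurement values by design.
#'
#' @param lines A data frame with columns `line_name`, `part_id`, and
#'   optional metadata columns; line names must be unique.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_description <- function(lines, path) {
  if (!all(c("line_name", "part_id") %in% names(lines))) {
    stop("experiment description needs line_name and part_id columns",
         call. = FALSE)
  }
  if (anyDuplicated(lines$line_name)) {
    stop("duplicate line names: ",
         paste(unique(lines$line_name[duplicated(lines$line_name)]),
               collapse = ", "), call. = FALSE)
  }
  meta <- sort(setdiff(names(lines), c("line_name", "part_id")))
  out <- lines[, c("line_name", "part_id", meta), drop = FALSE]
  names(out)[1:2] <- c("Line Name", "Part ID")
  readr::write_csv(tibble::as_tibble(out), path, na = "")
  invisible(path)
}

#' Read an experiment-description CSV
#'
#' @param path File path.
#' @return A tibble with columns `line_name`, `part_id` and any metadata
#'   columns.
#' @export
read_experiment_description <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = character())
  if (ncol(raw) < 2) {
    stop("experiment description needs at least line-name and part-id ",
         "columns", call. = FALSE)
  }
  names(raw)[1:2] <- c("line_name", "part_id")
  if (anyDuplicated(raw$line_name)) {
    stop("duplicate line names in ", path, call. = FALSE)
  }
  raw
}

#' Convert a batch series and its omics tables into measurement records
#'
#' Maps a simulated batch run to the generic interchange rows: optical
#' density from cell density (unitless), extracellular metabolite
#' concentrations in mM, and optionally the proteomics / transcriptomics /
#' metabolomics tables from [omics_from_series()].
#'
#' @param series A `batch_time_series`.
#' @param line_name Line name attached to every record.
#' @param od_per_gdw Conversion from cell density (gDW/L) to optical
#'   density. Default 1/0.65 (a dry weight per OD of 0.65 g/L).
#' @param omics Optional list of omics tibbles (as returned by
#'   [omics_from_series()]) to append.
#' @return An [edd_records()] tibble.
#' @export
edd_records_from_series <- function(series, line_name = "WT",
                                    od_per_gdw = 1 / 0.65, omics = NULL) {
  K <- length(series$times)
  mets <- colnames(series$concentrations)
  rec <- tibble::tibble(
    line_name = line_name,
    measurement_id = c(rep("OD", K),
                       rep(mets, each = K)),
    time = c(series$times, rep(series$times, length(mets))),
    value = c(series$cell_density * od_per_gdw,
              as.numeric(series$concentrations)),
    unit = c(rep("", K), rep("mM", K * length(mets))))
  if (!is.null(omics)) {
    for (tab in omics) {
      if (is.null(tab)) next
      rec <- rbind(rec, tibble::tibble(
        line_name = line_name, measurement_id = tab$feature_id,
        time = tab$time, value = tab$value, unit = tab$unit))
    }
  }
  edd_records(rec$line_name, rec$measurement_id, rec$time, rec$value,
              rec$unit)
}
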