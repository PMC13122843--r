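# The rule engine. Each rule is a closure over a trait_dataset returning a
# data.frame of issues; severities are fixed per rule (violations that destroy
# machine reusability are ERROR, stylistic/heuristic findings are WARNING).
# Rules with a trigger only run when the dataset's metadata carries the
# corresponding condition tag.

issue_row <- function(rule_id, severity, message, field = NA_character_,
                      row_index = NA_integer_) {
  data.frame(rule_id = rule_id, severity = severity, field = field,
             row_index = as.integer(row_index), message = message,
             stringsAsFactors = FALSE)
}

empty_issues <- function() {
  data.frame(rule_id = character(), severity = character(),
             field = character(), row_index = integer(),
             message = character(), stringsAsFactors = FALSE)
}

has_tag <- function(dataset, tag) tag %in% dataset$metadata$condition_tags

col_or_empty <- function(dataset, field) {
  if (field %in% names(dataset$rows)) dataset$rows[[field]]
  else rep("", nrow(dataset$rows))
}

fields_of_kind <- function(dataset, kinds) {
  fs <- dataset$schema$fields
  names(fs)[vapply(fs, function(f) f$value_kind %in% kinds, NA)]
}

# --- individual rules ------------------------------------------------------

rule_required_field_missing <- function(d) {
  out <- list()
  # trait_unit has its own rule; conditional fields have dedicated trigger rules
  fs <- d$schema$fields
  req <- names(fs)[vapply(fs, function(f) f$requirement == "required", NA)]
  req <- setdiff(req, "trait_unit")
  for (fld in req) {
    miss <- which(is_missing_cell(col_or_empty(d, fld)))
    for (i in miss)
      out[[length(out) + 1L]] <- issue_row(
        "REQUIRED_FIELD_MISSING", "ERROR",
        sprintf("required field '%s' is empty in row %d", fld, i), fld, i)
  }
  do.call(rbind, c(list(empty_issues()), out))
}

rule_units_missing <- function(d) {
  val <- col_or_empty(d, "trait_value")
  unit <- col_or_empty(d, "trait_unit")
  bad <- which(!is_missing_cell(val) & is_missing_cell(unit))
  do.call(rbind, c(list(empty_issues()), lapply(bad, function(i)
    issue_row("UNITS_MISSING", "ERROR",
              sprintf("trait_value present without trait_unit in row %d", i),
              "trait_unit", i))))
}

rule_units_not_separated <- function(d) {
  val <- col_or_empty(d, "trait_value")
  bad <- which(!is_missing_cell(val) & is.na(parse_number(val)))
  do.call(rbind, c(list(empty_issues()), lapply(bad, function(i)
    issue_row("UNITS_NOT_SEPARATED", "ERROR",
              sprintf("trait_value '%s' in row %d is not a bare number; units belong in their own field",
                      val[i], i), "trait_value", i))))
}

rule_value_not_numeric <- function(d) {
  flds <- setdiff(fields_of_kind(d, c("numeric", "integer")), "trait_value")
  out <- list()
  for (fld in flds) {
    cells <- col_or_empty(d, fld)
    bad <- which(!is_missing_cell(cells) & is.na(parse_number(cells)))
    for (i in bad)
      out[[length(out) + 1L]] <- issue_row(
        "VALUE_NOT_NUMERIC", "ERROR",
        sprintf("field '%s' declared numeric but row %d holds '%s'", fld, i,
                cells[i]), fld, i)
  }
  do.call(rbind, c(list(empty_issues()), out))
}

date_rule <- function(d, want_reason, rule_id, severity) {
  out <- list()
  for (fld in fields_of_kind(d, "date")) {
    cells <- col_or_empty(d, fld)
    for (i in which(!is_missing_cell(cells))) {
      p <- parse_iso_date(cells[i])
      if (!p$ok && p$reason == want_reason)
        out[[length(out) + 1L]] <- issue_row(
          rule_id, severity,
          sprintf("date '%s' in field '%s', row %d is %s (use YYYY-MM-DD)",
                  cells[i], fld, i,
                  if (want_reason == "non_iso_parseable") "not ISO 8601"
                  else "unparseable"), fld, i)
    }
  }
  do.call(rbind, c(list(empty_issues()), out))
}

rule_date_not_iso <- function(d) date_rule(d, "non_iso_parseable", "DATE_NOT_ISO", "WARNING")
rule_date_unparseable <- function(d) date_rule(d, "unparseable", "DATE_UNPARSEABLE", "ERROR")

text_scan_rule <- function(d, want_code, severity) {
  out <- list()
  flds <- fields_of_kind(d, c("text", "identifier", "unit"))
  # field names themselves must also be clean
  for (fld in names(d$schema$fields)) {
    for (f in scan_text_issues(fld)) {
      if (f$code == want_code)
        out[[length(out) + 1L]] <- issue_row(
          want_code, severity,
          sprintf("field name '%s' contains %s '%s'", fld,
                  tolower(gsub("_", " ", want_code)), f$detail), fld, NA)
    }
  }
  for (fld in flds) {
    cells <- col_or_empty(d, fld)
    for (i in which(!is_missing_cell(cells))) {
      for (f in scan_text_issues(cells[i])) {
        if (f$code == want_code)
          out[[length(out) + 1L]] <- issue_row(
            want_code, severity,
            sprintf("cell '%s' (field '%s', row %d) contains %s '%s'",
                    cells[i], fld, i, tolower(gsub("_", " ", want_code)),
                    f$detail), fld, i)
      }
    }
  }
  do.call(rbind, c(list(empty_issues()), out))
}

rule_non_ascii <- function(d) text_scan_rule(d, "NON_ASCII", "WARNING")
rule_abbreviation <- function(d) text_scan_rule(d, "ABBREVIATION_SUSPECT", "WARNING")

rule_proportion_denominator <- function(d) {
  unit <- col_or_empty(d, "trait_unit")
  num <- col_or_empty(d, "numerator")
  den <- col_or_empty(d, "denominator")
  prop <- grepl("percent|%|proportion", unit, ignore.case = TRUE)
  bad <- which(prop & (is_missing_cell(num) | is_missing_cell(den)))
  do.call(rbind, c(list(empty_issues()), lapply(bad, function(i)
    issue_row("PROPORTION_DENOMINATOR_MISSING", "ERROR",
              sprintf("row %d reports a proportion ('%s') without numerator and denominator counts",
                      i, unit[i]), "denominator", i))))
}

rule_duplicate_identifier <- function(d) {
  ids <- col_or_empty(d, "unique_identifier")
  axes <- paste0("axis_", seq_len(d$schema$n_axes), "_value")
  key <- ids
  for (a in axes) key <- paste(key, col_or_empty(d, a), sep = "\r")
  out <- list()
  use <- which(!is_missing_cell(ids))
  dup <- use[duplicated(key[use])]
  for (i in dup)
    out[[length(out) + 1L]] <- issue_row(
      "DUPLICATE_IDENTIFIER", "WARNING",
      sprintf("row %d repeats identifier '%s' with identical values on every axis (exact duplicate suspected)",
              i, ids[i]), "unique_identifier", i)
  do.call(rbind, c(list(empty_issues()), out))
}

rule_latlong_range <- function(d) {
  out <- list()
  specs <- list(location_latitude = c(-90, 90), location_longitude = c(-180, 180))
  for (fld in names(specs)) {
    cells <- col_or_empty(d, fld)
    rng <- specs[[fld]]
    for (i in which(!is_missing_cell(cells))) {
      v <- parse_number(cells[i])
      if (is.na(v) || v < rng[1] || v > rng[2])
        out[[length(out) + 1L]] <- issue_row(
          "LATLONG_OUT_OF_RANGE", "ERROR",
          sprintf("%s '%s' in row %d is outside [%g, %g]", fld, cells[i], i,
                  rng[1], rng[2]), fld, i)
    }
  }
  do.call(rbind, c(list(empty_issues()), out))
}

rule_location_missing <- function(d) {
  if (!has_tag(d, "field_study")) return(empty_issues())
  lat <- col_or_empty(d, "location_latitude")
  lon <- col_or_empty(d, "location_longitude")
  bad <- which(is_missing_cell(lat) | is_missing_cell(lon))
  do.call(rbind, c(list(empty_issues()), lapply(bad, function(i)
    issue_row("LOCATION_MISSING", "WARNING",
              sprintf("field study without latitude/longitude in row %d", i),
              "location_latitude", i))))
}

rule_citation_missing <- function(d) {
  if (is_missing_cell(d$metadata$citation))
    issue_row("CITATION_MISSING", "ERROR",
              "metadata lacks a full citation of the data source")
  else empty_issues()
}

rule_submitter_missing <- function(d) {
  if (is_missing_cell(d$metadata$submitter_name) ||
      is_missing_cell(d$metadata$submitter_contact))
    issue_row("SUBMITTER_MISSING", "ERROR",
              "metadata lacks the submitter's name and contact")
  else empty_issues()
}

rule_embargo_malformed <- function(d) {
  e <- d$metadata$embargo_date
  if (!is_missing_cell(e) && !parse_iso_date(e)$ok)
    issue_row("EMBARGO_MALFORMED", "ERROR",
              sprintf("embargo date '%s' is not an ISO 8601 calendar date", e))
  else empty_issues()
}

rule_aggregation_incomplete <- function(d) {
  if (!has_tag(d, "aggregated_data")) return(empty_issues())
  val <- col_or_empty(d, "trait_value")
  n <- col_or_empty(d, "sample_size")
  vm <- col_or_empty(d, "variability_metric")
  vv <- col_or_empty(d, "variability_value")
  bad <- which(!is_missing_cell(val) &
                 (is_missing_cell(n) | is_missing_cell(vm) | is_missing_cell(vv)))
  do.call(rbind, c(list(empty_issues()), lapply(bad, function(i)
    issue_row("AGGREGATION_INCOMPLETE", "ERROR",
              sprintf("aggregated value in row %d lacks sample size and/or variability metric",
                      i), "sample_size", i))))
}

rule_aggregated_discouraged <- function(d) {
  if (has_tag(d, "aggregated_data"))
    issue_row("AGGREGATED_DISCOURAGED", "WARNING",
              "dataset is aggregated; the least-processed, per-organism form is more reusable")
  else empty_issues()
}

rule_pathogen_missing <- function(d) {
  if (!has_tag(d, "transmission_study")) return(empty_issues())
  pt <- col_or_empty(d, "pathogen_taxonomy")
  bad <- which(is_missing_cell(pt))
  do.call(rbind, c(list(empty_issues()), lapply(bad, function(i)
    issue_row("PATHOGEN_MISSING", "ERROR",
              sprintf("transmission study without pathogen taxonomy in row %d", i),
              "pathogen_taxonomy", i))))
}

# --- registry --------------------------------------------------------------

RULE_REGISTRY <- list(
  REQUIRED_FIELD_MISSING = list(
    severity = "ERROR", fun = rule_required_field_missing,
    anchor = "Table 1: minimum descriptor fields must be reported"),
  UNITS_MISSING = list(
    severity = "ERROR", fun = rule_units_missing,
    anchor = "Trait description: the units of measurement used, and the frequency of observations"),
  UNITS_NOT_SEPARATED = list(
    severity = "ERROR", fun = rule_units_not_separated,
    anchor = "Box 1: numerical data should be separated from its units into different fields"),
  VALUE_NOT_NUMERIC = list(
    severity = "ERROR", fun = rule_value_not_numeric,
    anchor = "Box 1: provide data that are machine readable"),
  DATE_NOT_ISO = list(
    severity = "WARNING", fun = rule_date_not_iso,
    anchor = "Box 1: use numeric dates, preferably ISO 8601 format (e.g., YYYY-MM-DD)"),
  DATE_UNPARSEABLE = list(
    severity = "ERROR", fun = rule_date_unparseable,
    anchor = "Box 1: use numeric dates, preferably ISO 8601 format (e.g., YYYY-MM-DD)"),
  NON_ASCII = list(
    severity = "WARNING", fun = rule_non_ascii,
    anchor = "Box 1: avoid diacritics (accent marks) and other special characters"),
  ABBREVIATION_SUSPECT = list(
    severity = "WARNING", fun = rule_abbreviation,
    anchor = "Box 1: do not use abbreviations in data fields"),
  PROPORTION_DENOMINATOR_MISSING = list(
    severity = "ERROR", fun = rule_proportion_denominator,
    anchor = "Table 1 Units: for percentages or proportions, record the numerator and denominator"),
  DUPLICATE_IDENTIFIER = list(
    severity = "WARNING", fun = rule_duplicate_identifier,
    anchor = "Table 1 Unique identifier: designation of individuals or replicates"),
  LATLONG_OUT_OF_RANGE = list(
    severity = "ERROR", fun = rule_latlong_range,
    anchor = "Box 1: latitude and longitude are preferred, if available"),
  LOCATION_MISSING = list(
    severity = "WARNING", fun = rule_location_missing,
    anchor = "Box 1: latitude and longitude are preferred, if available"),
  CITATION_MISSING = list(
    severity = "ERROR", fun = rule_citation_missing,
    anchor = "Metadata: a full citation of the data source"),
  SUBMITTER_MISSING = list(
    severity = "ERROR", fun = rule_submitter_missing,
    anchor = "Metadata: name and contact of the person uploading the dataset"),
  EMBARGO_MALFORMED = list(
    severity = "ERROR", fun = rule_embargo_malformed,
    anchor = "Metadata: the date on which any embargo on the dataset is lifted"),
  AGGREGATION_INCOMPLETE = list(
    severity = "ERROR", fun = rule_aggregation_incomplete,
    anchor = "Trait description: metrics of variability (e.g., standard error) and sample sizes must accompany summaries"),
  AGGREGATED_DISCOURAGED = list(
    severity = "WARNING", fun = rule_aggregated_discouraged,
    anchor = "Box 1: the less processed the data are, the more reusable the data will be"),
  PATHOGEN_MISSING = list(
    severity = "ERROR", fun = rule_pathogen_missing,
    anchor = "Organism: species or strain of pathogen must also be reported"))

#' List registered validation rule identifiers
#' @return Character vector of rule ids in registry order.
#' @export
rule_ids <- function() names(RULE_REGISTRY)

#' Severity of each registered rule
#' @return Named character vector (`"ERROR"` or `"WARNING"`).
#' @export
rule_severities <- function() {
  vapply(RULE_REGISTRY, `[[`, "", "severity")
}

finalize_issues <- function(issues, registry = RULE_REGISTRY) {
  if (nrow(issues) == 0L) {
    issues$anchor <- character(0)
    return(issues)
  }
  issues$anchor <- vapply(issues$rule_id, function(id) registry[[id]]$anchor, "")
  # deterministic ordering: dataset-level first, then row-major, rule id ties
  key_row <- ifelse(is.na(issues$row_index), -1L, issues$row_index)
  issues[order(key_row, issues$rule_id, issues$field, method = "radix"), ,
         drop = FALSE]
}

#' Validate a trait dataset against the standard
#'
#' Runs every registered rule (see [rule_ids()]) over the dataset's cells and
#' metadata and returns a report. A dataset is *compliant* when it has no
#' ERROR-level findings; WARNINGs (heuristic or stylistic findings) do not
#' affect compliance.
#'
#' @param dataset A `trait_dataset`.
#' @return A `validation_report`: list with `dataset_label`, `issues` (a
#'   data.frame with `rule_id`, `severity`, `field`, `row_index` (1-based data
#'   row, `NA` for dataset-level findings), `message`, `anchor`), `n_errors`,
#'   `n_warnings` and `compliant`.
#' @examples
#' d <- simulate_individual_dataset(simulation_config(n_per_temp = 2, seed = 1))
#' validate_dataset(d)$compliant
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "trait_dataset"))
  issues <- do.call(rbind, c(list(empty_issues()),
                             lapply(RULE_REGISTRY, function(r) r$fun(dataset))))
  rownames(issues) <- NULL
  issues <- finalize_issues(issues)
  rownames(issues) <- NULL
  new_validation_report(dataset$label, issues)
}

new_validation_report <- function(label, issues) {
  n_err <- sum(issues$severity == "ERROR")
  n_warn <- sum(issues$severity == "WARNING")
  structure(list(dataset_label = label, issues = issues, n_errors = n_err,
                 n_warnings = n_warn, compliant = n_err == 0L),
            class = "validation_report")
}

#' Evaluate a single rule
#'
#' @param rule_id One of [rule_ids()].
#' @param dataset A `trait_dataset`.
#' @return The issue data.frame for that rule only (same columns as in
#'   [validate_dataset()] reports). `validate_dataset()` is exactly the
#'   concatenation of `check_rule()` over all registered rules.
#' @export
check_rule <- function(rule_id, dataset) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (!rule_id %in% names(RULE_REGISTRY))
    stop("unknown rule id '", rule_id, "'; registered rules: ",
         paste(rule_ids(), collapse = ", "))
  issues <- RULE_REGISTRY[[rule_id]]$fun(dataset)
  rownames(issues) <- NULL
  out <- finalize_issues(issues)
  rownames(out) <- NULL
  out
}

#' Render a validation report
#'
#' @param report A `validation_report`.
#' @param format `"text"` for a human-readable summary grouped by severity,
#'   or `"json"` for a stable machine-readable document
#'   (`report_version` 1) suitable for CI pipelines.
#' @return A single character string; rendering is deterministic.
#' @export
render_report <- function(report, format = c("text", "json")) {
  stopifnot(inherits(report, "validation_report"))
  format <- match.arg(format)
  if (format == "json") {
    iss <- report$issues
    issues_list <- lapply(seq_len(nrow(iss)), function(i) {
      list(rule_id = iss$rule_id[i], severity = iss$severity[i],
           field = if (is.na(iss$field[i])) NULL else iss$field[i],
           row_index = if (is.na(iss$row_index[i])) NULL else iss$row_index[i],
           message = iss$message[i], anchor = iss$anchor[i])
    })
    doc <- list(report_version = 1L, dataset_label = report$dataset_label,
                compliant = report$compliant, n_errors = report$n_errors,
                n_warnings = report$n_warnings, issues = issues_list)
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                         null = "null", pretty = TRUE)))
  }
  lines <- c(sprintf("Validation report for '%s'", report$dataset_label),
             sprintf("Status: %s (%d error(s), %d warning(s))",
                     if (report$compliant) "COMPLIANT" else "NOT COMPLIANT",
                     report$n_errors, report$n_warnings))
  for (sev in c("ERROR", "WARNING")) {
    sub <- report$issues[report$issues$severity == sev, , drop = FALSE]
    if (nrow(sub) == 0L) next
    lines <- c(lines, "", paste0(sev, "S:"))
    lines <- c(lines, vapply(seq_len(nrow(sub)), function(i) {
      sprintf("  [%s] %s  <%s>", sub$rule_id[i], sub$message[i], sub$anchor[i])
    }, ""))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
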