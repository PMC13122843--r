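# CSV input/output with the formatting discipline of the standard: UTF-8,
# RFC 4180 dialect, header-bound columns, verbatim cells. All cells are kept
# as character; typing happens downstream (validation, aggregation, fitting).

#' Dataset-level metadata
#'
#' The metadata the standard requires alongside the data: a full citation of
#' the source, the submitter's name and contact, and (optionally) a DOI, an
#' embargo-lift date and a license label. `condition_tags` records which
#' conditional blocks of the schema apply to this study
#' (`"transmission_study"`, `"field_study"`, `"aggregated_data"`,
#' `"proportion_trait"`); the triggers are not machine-decidable from the
#' data alone, so they travel as explicit metadata.
#'
#' @param citation Full citation of the data source.
#' @param submitter_name,submitter_contact Who deposited the data and how to
#'   reach them.
#' @param doi,embargo_date,license_label Optional; `embargo_date` must be an
#'   ISO 8601 calendar date (`YYYY-MM-DD`) to be considered well-formed.
#' @param condition_tags Character vector of active condition tags.
#' @return An object of class `dataset_metadata`.
#' @export
dataset_metadata <- function(citation = "", submitter_name = "",
                             submitter_contact = "", doi = "",
                             embargo_date = "", condition_tags = character(),
                             license_label = "") {
  structure(list(citation = citation, doi = doi,
                 submitter_name = submitter_name,
                 submitter_contact = submitter_contact,
                 embargo_date = embargo_date,
                 condition_tags = unique(as.character(condition_tags)),
                 license_label = license_label),
            class = "dataset_metadata")
}

#' Construct a trait dataset
#'
#' Couples a rectangular table of verbatim text cells to a schema and
#' metadata. Columns named in the schema but absent from `rows` are
#' materialised as empty strings (empty cell = missing value); columns in
#' `rows` but not in the schema are retained and registered as
#' `descriptor = "other"` fields, since the standard allows extra columns.
#'
#' @param rows A data.frame of character cells (coerced).
#' @param schema A `trait_schema` (default [default_mirevtd_schema()]).
#' @param metadata A `dataset_metadata`.
#' @param label Short label used in reports.
#' @return An object of class `trait_dataset`.
#' @export
trait_dataset <- function(rows, schema = default_mirevtd_schema(),
                          metadata = dataset_metadata(), label = "dataset") {
  stopifnot(is.data.frame(rows), inherits(schema, "trait_schema"),
            inherits(metadata, "dataset_metadata"))
  rows <- as.data.frame(lapply(rows, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  }), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  extra <- setdiff(names(rows), schema_field_names(schema))
  for (nm in extra) {
    schema$fields[[nm]] <- field_spec(nm, "other", "recommended", "text")
  }
  for (nm in setdiff(schema_field_names(schema), names(rows)))
    rows[[nm]] <- rep("", max(nrow(rows), 0L))
  rows <- rows[, schema_field_names(schema), drop = FALSE]
  structure(list(metadata = metadata, schema = schema, rows = rows,
                 label = label),
            class = "trait_dataset")
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat(sprintf("<trait_dataset> '%s': %d rows x %d fields (%s)\n", x$label,
              nrow(x$rows), ncol(x$rows), x$schema$version_label))
  if (nzchar(x$metadata$citation))
    cat("  citation:", substr(x$metadata$citation, 1, 70), "\n")
  if (length(x$metadata$condition_tags))
    cat("  tags:", paste(x$metadata$condition_tags, collapse = ", "), "\n")
  invisible(x)
}

default_metadata_path <- function(csv_path) {
  paste0(sub("\\.csv$", "", csv_path), ".metadata.json")
}

#' Write dataset metadata as a JSON sidecar
#' @param metadata A `dataset_metadata`.
#' @param path Destination file.
#' @param label Dataset label stored alongside.
#' @export
write_metadata_json <- function(metadata, path, label = "dataset") {
  doc <- unclass(metadata)
  doc$condition_tags <- as.list(doc$condition_tags)
  doc$dataset_label <- label
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_metadata_json
#' @export
read_metadata_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  md <- dataset_metadata(
    citation = doc$citation %||% "", submitter_name = doc$submitter_name %||% "",
    submitter_contact = doc$submitter_contact %||% "", doi = doc$doi %||% "",
    embargo_date = doc$embargo_date %||% "",
    condition_tags = unlist(doc$condition_tags) %||% character(),
    license_label = doc$license_label %||% "")
  attr(md, "dataset_label") <- doc$dataset_label %||% "dataset"
  md
}

#' Read a trait dataset from CSV
#'
#' Strict reader for the standard's exchange format: UTF-8, comma-separated,
#' RFC 4180 quoting, first record a header. Header names are bound to schema
#' fields by exact match first, then through `alias_map`; unbound columns are
#' retained as `descriptor = "other"` fields. Cells are stored verbatim.
#'
#' @param path CSV file path.
#' @param schema Target `trait_schema`.
#' @param alias_map Named character vector mapping foreign header names to
#'   canonical field names, e.g. `c(DaysAlive = "trait_value")`.
#' @param metadata Either a `dataset_metadata`, a path to a metadata JSON
#'   sidecar, or `NULL` to auto-detect `<path-sans-.csv>.metadata.json`.
#' @param label Dataset label (defaults to the sidecar's label or the file
#'   name).
#' @return A `trait_dataset`.
#' @seealso [write_trait_dataset()]
#' @export
read_trait_dataset <- function(path, schema = default_mirevtd_schema(),
                               alias_map = NULL, metadata = NULL,
                               label = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  if (!all(validUTF8(txt)))
    stop("encoding error: '", path, "' is not valid UTF-8")
  Encoding(txt) <- "UTF-8"
  con <- textConnection(txt)
  on.exit(close(con), add = TRUE)
  nf <- count.fields(con, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  # a final newline is part of the dialect, not an empty record
  while (length(nf) > 1L && nf[length(nf)] == 0L) nf <- nf[-length(nf)]
  if (length(nf) == 0L) stop("structural error: '", path, "' is empty")
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop("structural error: row ", bad - 1L, " has ", nf[bad],
         " cells, expected ", nf[1L], " (header width)")
  }
  # interior blank lines were already rejected as ragged rows above
  tab <- read.csv(text = txt, colClasses = "character", check.names = FALSE,
                  na.strings = character())
  hdr <- names(tab)
  if (anyDuplicated(hdr))
    stop("structural error: duplicate header names: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  canon <- schema_field_names(schema)
  bound <- ifelse(hdr %in% canon, hdr,
                  ifelse(hdr %in% names(alias_map), unname(alias_map[hdr]), hdr))
  if (anyDuplicated(bound))
    stop("structural error: alias binding maps two headers to the same field: ",
         paste(unique(bound[duplicated(bound)]), collapse = ", "))
  names(tab) <- bound

  md <- dataset_metadata()
  md_label <- NULL
  if (inherits(metadata, "dataset_metadata")) {
    md <- metadata
  } else {
    md_path <- if (is.character(metadata)) metadata else default_metadata_path(path)
    if (file.exists(md_path)) {
      md <- read_metadata_json(md_path)
      md_label <- attr(md, "dataset_label")
    }
  }
  trait_dataset(tab, schema = schema, metadata = md,
                label = label %||% md_label %||% basename(path))
}

rfc4180_line <- function(cells) {
  needs <- grepl('[",\n\r]', cells)
  cells[needs] <- paste0('"', gsub('"', '""', cells[needs], fixed = TRUE), '"')
  paste(cells, collapse = ",")
}

#' Write a trait dataset to CSV
#'
#' Emits RFC 4180 CSV in UTF-8 with the canonical header, quoting cells only
#' when they contain a comma, quote or newline. `read_trait_dataset()` on the
#' result reproduces the dataset cell-for-cell. Metadata is written to a JSON
#' sidecar (`<path-sans-.csv>.metadata.json`) unless `metadata_path = NA`.
#'
#' @param dataset A `trait_dataset`.
#' @param path Destination CSV path.
#' @param metadata_path Sidecar path, or `NA` to skip the sidecar.
#' @return `path`, invisibly.
#' @export
write_trait_dataset <- function(dataset, path,
                                metadata_path = default_metadata_path(path)) {
  stopifnot(inherits(dataset, "trait_dataset"))
  rows <- dataset$rows
  lines <- c(rfc4180_line(names(rows)),
             if (nrow(rows) > 0L)
               vapply(seq_len(nrow(rows)),
                      function(i) rfc4180_line(as.character(unlist(rows[i, ], use.names = FALSE))),
                      ""))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, useBytes = TRUE)
  if (!is.na(metadata_path))
    write_metadata_json(dataset$metadata, metadata_path, label = dataset$label)
  invisible(path)
}

#' Parse a strictly ISO 8601 calendar date
#'
#' Accepts exactly `YYYY-MM-DD` for a real calendar date. Recognisable
#' non-ISO forms (slash- or dot-separated day/month orderings, `YYYY/MM/DD`)
#' are distinguished from garbage so the validator can warn rather than
#' error on interpretable-but-ambiguous dates.
#'
#' @param cell A single character string.
#' @return A list: `ok = TRUE` with a `Date` in `$date`, or `ok = FALSE` with
#'   `$reason` one of `"non_iso_parseable"`, `"unparseable"`.
#' @examples
#' parse_iso_date("2022-03-01")$ok
#' parse_iso_date("03/01/2022")$reason
#' @export
parse_iso_date <- function(cell) {
  stopifnot(is.character(cell), length(cell) == 1L)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", cell)) {
    d <- as.Date(cell, format = "%Y-%m-%d")
    if (!is.na(d) && format(d, "%Y-%m-%d") == cell)
      return(list(ok = TRUE, date = d))
    return(list(ok = FALSE, reason = "unparseable"))
  }
  non_iso <- c("^\\d{1,2}/\\d{1,2}/\\d{4}$", "^\\d{4}/\\d{1,2}/\\d{1,2}$",
               "^\\d{1,2}\\.\\d{1,2}\\.\\d{4}$", "^\\d{1,2}-\\d{1,2}-\\d{4}$",
               "^\\d{8}$")
  if (any(vapply(non_iso, grepl, NA, x = cell)))
    return(list(ok = FALSE, reason = "non_iso_parseable"))
  list(ok = FALSE, reason = "unparseable")
}

ABBREVIATION_BLACKLIST <- c("spp.", "sp.", "temp.", "RH", "dpi", "avg.", "no.")

#' Scan a text cell for reuse-hostile content
#'
#' Flags the two formatting hazards the standard calls out for free-text
#' cells: non-ASCII characters (diacritics and other special characters that
#' break naive encodings) and abbreviation-like tokens (which introduce
#' uncertainty). Abbreviation detection is a heuristic: a token is suspect if
#' it is on a short blacklist (`spp.`, `sp.`, `temp.`, `RH`, `dpi`, `avg.`,
#' `no.`) or is at most three letters followed by a period.
#'
#' @param cell A single character string.
#' @return A list of findings, each `list(code =, detail =)` with code
#'   `"NON_ASCII"` or `"ABBREVIATION_SUSPECT"`; empty list when clean.
#' @examples
#' scan_text_issues("Aedes aegypti")
#' scan_text_issues("Culex spp.")
#' @export
scan_text_issues <- function(cell) {
  stopifnot(is.character(cell), length(cell) == 1L)
  out <- list()
  cps <- utf8ToInt(enc2utf8(cell))
  if (any(cps > 127L)) {
    for (ch in unique(intToUtf8(cps[cps > 127L], multiple = TRUE)))
      out[[length(out) + 1L]] <- list(code = "NON_ASCII", detail = ch)
  }
  tokens <- strsplit(cell, "[[:space:]]+")[[1L]]
  for (tok in tokens) {
    if (tok %in% ABBREVIATION_BLACKLIST ||
        grepl("^[A-Za-z]{1,3}\\.$", tok))
      out[[length(out) + 1L]] <- list(code = "ABBREVIATION_SUSPECT", detail = tok)
  }
  out
}
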