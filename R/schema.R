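# Machine-readable encoding of the minimum descriptors: every dataset is
# checked against a trait_schema, an ordered list of field_spec objects with
# requirement levels (required / conditional / recommended) and conditional
# trigger tags supplied through dataset metadata.

FIELD_DESCRIPTORS <- c("organism", "trait", "axis", "metadata", "other")
FIELD_REQUIREMENTS <- c("required", "conditional", "recommended")
FIELD_VALUE_KINDS <- c("text", "numeric", "integer", "date", "latitude",
                       "longitude", "identifier", "unit")
MAX_CELL_LENGTH <- 255L

#' Describe one data field of the standard
#'
#' A field specification records what a column means (its descriptor
#' category), how strongly the standard requires it, what kind of value it
#' holds, and - for conditional fields - the metadata tag that activates it.
#'
#' @param name Field name: non-empty ASCII, snake_case by convention, at most
#'   255 characters, no abbreviation-style tokens (e.g. "temp.").
#' @param descriptor One of `"organism"`, `"trait"`, `"axis"`, `"metadata"`,
#'   `"other"`.
#' @param requirement One of `"required"`, `"conditional"`, `"recommended"`.
#' @param value_kind One of `"text"`, `"numeric"`, `"integer"`, `"date"`,
#'   `"latitude"`, `"longitude"`, `"identifier"`, `"unit"`.
#' @param condition_tag Tag naming the study condition that makes a
#'   conditional field required (e.g. `"transmission_study"`). Mandatory when
#'   `requirement = "conditional"`.
#' @param example_values Character vector of illustrative values.
#' @return An object of class `field_spec`.
#' @examples
#' field_spec("wing_length", "trait", "recommended", "numeric")
#' @export
field_spec <- function(name, descriptor, requirement, value_kind,
                       condition_tag = NULL, example_values = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("field name must be non-empty")
  if (nchar(name, type = "bytes") > MAX_CELL_LENGTH)
    stop("field name longer than ", MAX_CELL_LENGTH, " characters: ", name)
  if (any(utf8ToInt(name) > 127L))
    stop("field name must be ASCII: ", name)
  if (length(scan_text_issues(name)) > 0L)
    stop("field name must be plain ASCII without abbreviation tokens: ", name)
  descriptor <- match.arg(descriptor, FIELD_DESCRIPTORS)
  requirement <- match.arg(requirement, FIELD_REQUIREMENTS)
  value_kind <- match.arg(value_kind, FIELD_VALUE_KINDS)
  if (requirement == "conditional" && (is.null(condition_tag) || !nzchar(condition_tag)))
    stop("conditional field '", name, "' needs a condition_tag")
  structure(
    list(name = name, descriptor = descriptor, requirement = requirement,
         value_kind = value_kind,
         condition_tag = if (is.null(condition_tag)) NA_character_ else condition_tag,
         example_values = as.character(example_values)),
    class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %s [%s/%s, %s]%s\n", x$name, x$descriptor,
              x$requirement, x$value_kind,
              if (!is.na(x$condition_tag)) paste0(" when ", x$condition_tag) else ""))
  invisible(x)
}

new_trait_schema <- function(fields, n_axes, n_interactors, version_label,
                             axis_labels) {
  names(fields) <- vapply(fields, `[[`, "", "name")
  sch <- structure(
    list(fields = fields, n_axes = as.integer(n_axes),
         n_interactors = as.integer(n_interactors),
         version_label = version_label, axis_labels = axis_labels),
    class = "trait_schema")
  check_trait_schema(sch)
  sch
}

check_trait_schema <- function(schema) {
  nm <- names(schema$fields)
  if (anyDuplicated(nm)) stop("duplicate field names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  descs <- vapply(schema$fields, `[[`, "", "descriptor")
  kinds <- vapply(schema$fields, `[[`, "", "value_kind")
  if (!any(descs == "organism"))
    stop("schema needs at least one organism-descriptor field")
  if (sum(nm == "trait_value") != 1L || kinds[["trait_value"]] != "numeric")
    stop("schema needs exactly one numeric trait_value field")
  if (!any(kinds == "unit")) stop("schema needs at least one unit field")
  if (schema$n_axes < 1L) stop("schema needs at least one axis of variation")
  for (k in seq_len(schema$n_axes)) {
    pair <- paste0("axis_", k, c("_value", "_unit"))
    if (!all(pair %in% nm))
      stop("axis ", k, " must appear as a (value, unit) field pair")
  }
  invisible(schema)
}

schema_field_names <- function(schema) names(schema$fields)

#' The default MIReVTD schema
#'
#' Canonical snake_case encoding of the standard's minimum descriptors: the
#' organism block (vector taxonomy, unique identifier, life stage, sex, and a
#' conditional pathogen block for transmission studies), the trait-description
#' block (trait name, numeric value, unit, conditional numerator/denominator
#' for proportion traits, conditional sample size and variability fields for
#' aggregated data, an optional ISO-8601 observation date, and conditional
#' latitude/longitude for field studies), and one axis-of-variation block
#' (`axis_1_name`, `axis_1_value`, `axis_1_unit`).
#'
#' The standard itself deliberately fixes no field names; this schema is the
#' toolkit's one canonical naming, and [read_trait_dataset()]'s `alias_map`
#' binds other headers (e.g. database-style CamelCase names) onto it.
#'
#' @return A `trait_schema` with `n_axes = 1` and `n_interactors = 1`.
#' @examples
#' sch <- default_mirevtd_schema()
#' names(sch$fields)
#' @export
default_mirevtd_schema <- function() {
  f <- list(
    field_spec("vector_taxonomy", "organism", "required", "text",
               example_values = c("Aedes aegypti",
                                  "Culex quinquefasciatus Sebring colony",
                                  "Delphacodes kuscheli")),
    field_spec("unique_identifier", "organism", "recommended", "identifier",
               example_values = c("Mosquito1", "tick 45")),
    field_spec("life_stage", "organism", "required", "text",
               example_values = c("L1 larvae",
                                  "3-4 day old post eclosion adults", "nymphs")),
    field_spec("sex", "organism", "required", "text",
               example_values = c("males", "unknown", "mixed")),
    field_spec("pathogen_taxonomy", "organism", "conditional", "text",
               condition_tag = "transmission_study",
               example_values = c("Plasmodium falciparum (N54 strain)",
                                  "West Nile virus",
                                  "Dengue virus DENV-4 (strain H241)")),
    field_spec("trait_name", "trait", "required", "text",
               example_values = c("mortality", "lifespan", "Fecundity",
                                  "development time - hatch to adult")),
    field_spec("trait_value", "trait", "required", "numeric",
               example_values = c("45", "170.25")),
    field_spec("trait_unit", "trait", "required", "unit",
               example_values = c("days", "eggs laid", "percent mortality",
                                  "LT50")),
    field_spec("numerator", "trait", "conditional", "integer",
               condition_tag = "proportion_trait"),
    field_spec("denominator", "trait", "conditional", "integer",
               condition_tag = "proportion_trait"),
    field_spec("sample_size", "trait", "conditional", "integer",
               condition_tag = "aggregated_data"),
    field_spec("variability_metric", "trait", "conditional", "text",
               condition_tag = "aggregated_data",
               example_values = "standard error of the mean"),
    field_spec("variability_value", "trait", "conditional", "numeric",
               condition_tag = "aggregated_data"),
    field_spec("observation_date", "trait", "recommended", "date",
               example_values = "2022-03-01"),
    field_spec("location_latitude", "trait", "conditional", "latitude",
               condition_tag = "field_study"),
    field_spec("location_longitude", "trait", "conditional", "longitude",
               condition_tag = "field_study"),
    field_spec("axis_1_name", "axis", "required", "text",
               example_values = c("temperature", "relative humidity",
                                  "photoperiod")),
    field_spec("axis_1_value", "axis", "required", "numeric"),
    field_spec("axis_1_unit", "axis", "required", "unit",
               example_values = c("Degrees celsius",
                                  "Age, days post emergence")))
  new_trait_schema(f, n_axes = 1L, n_interactors = 1L,
                   version_label = "mirevtd-1.0",
                   axis_labels = NA_character_)
}

#' Add an axis of variation to a schema
#'
#' Each additional experimental gradient (e.g. a second stressor such as
#' resource concentration alongside temperature) gets its own
#' `(name, value, unit)` column triple, per the standard's "separate
#' different axes of variation into different columns" recommendation.
#'
#' @param schema A `trait_schema`.
#' @param axis_name Label of the new axis (e.g. `"temperature"`); must not
#'   collide with a previously added axis label.
#' @param axis_unit Unit string for the axis (e.g. `"Degrees celsius"`).
#' @return A new `trait_schema` with `n_axes` incremented; `schema` is
#'   unmodified.
#' @examples
#' s2 <- extend_with_axis(default_mirevtd_schema(),
#'                        "initial resource concentration", "mg per larva")
#' s2$n_axes
#' @export
extend_with_axis <- function(schema, axis_name, axis_unit) {
  stopifnot(inherits(schema, "trait_schema"),
            is.character(axis_name), nzchar(axis_name))
  known <- schema$axis_labels[!is.na(schema$axis_labels)]
  if (axis_name %in% known)
    stop("axis name collision: '", axis_name, "' is already an axis of this schema")
  k <- schema$n_axes + 1L
  add <- list(
    field_spec(paste0("axis_", k, "_name"), "axis", "required", "text",
               example_values = axis_name),
    field_spec(paste0("axis_", k, "_value"), "axis", "required", "numeric"),
    field_spec(paste0("axis_", k, "_unit"), "axis", "required", "unit",
               example_values = axis_unit))
  new_trait_schema(c(schema$fields, add), n_axes = k,
                   n_interactors = schema$n_interactors,
                   version_label = schema$version_label,
                   axis_labels = c(schema$axis_labels, axis_name))
}

#' Add an interactor (pathogen) block to a schema
#'
#' Transmission and vector-competence studies must report the pathogen's
#' taxonomy and strain; this adds a conditional pathogen block (activated by
#' the `transmission_study` metadata tag) and increments the interactor
#' counter. Repeated calls add suffix-numbered blocks.
#'
#' @param schema A `trait_schema`.
#' @return A new `trait_schema`; `schema` is unmodified.
#' @export
extend_with_interactor <- function(schema) {
  stopifnot(inherits(schema, "trait_schema"))
  k <- schema$n_interactors + 1L
  ex_tax <- c("Plasmodium falciparum (N54 strain)", "West Nile virus")
  nm <- schema_field_names(schema)
  if (!"pathogen_taxonomy" %in% nm) {
    add <- list(field_spec("pathogen_taxonomy", "organism", "conditional",
                           "text", "transmission_study", ex_tax))
  } else {
    add <- list()
  }
  if (!"pathogen_strain" %in% nm) {
    add <- c(add, list(field_spec("pathogen_strain", "organism", "conditional",
                                  "text", "transmission_study",
                                  "Strain CDC")))
  } else {
    base <- paste0("pathogen_", k)
    add <- c(add, list(
      field_spec(paste0(base, "_taxonomy"), "organism", "conditional", "text",
                 "transmission_study", ex_tax),
      field_spec(paste0(base, "_strain"), "organism", "conditional", "text",
                 "transmission_study")))
  }
  new_trait_schema(c(schema$fields, add), n_axes = schema$n_axes,
                   n_interactors = k,
                   version_label = schema$version_label,
                   axis_labels = schema$axis_labels)
}

#' Serialize a schema to JSON
#'
#' Writes the full field list (names, descriptors, requirement levels,
#' condition tags, value kinds, examples) so extended schemas can be shared
#' and re-loaded with [schema_from_json()].
#'
#' @param schema A `trait_schema`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
schema_to_json <- function(schema, path = NULL) {
  stopifnot(inherits(schema, "trait_schema"))
  doc <- list(
    version_label = schema$version_label,
    n_axes = schema$n_axes,
    n_interactors = schema$n_interactors,
    axis_labels = as.list(schema$axis_labels),
    fields = lapply(unname(schema$fields), function(f) {
      list(name = f$name, descriptor = f$descriptor,
           requirement = f$requirement, value_kind = f$value_kind,
           condition_tag = f$condition_tag,
           example_values = as.list(f$example_values))
    }))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", na = "null",
                          pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname schema_to_json
#' @param json A file path or JSON string produced by [schema_to_json()].
#' @export
schema_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fields <- lapply(doc$fields, function(f) {
    field_spec(f$name, f$descriptor, f$requirement, f$value_kind,
               condition_tag = if (is.null(f$condition_tag)) NULL else f$condition_tag,
               example_values = unlist(f$example_values) %||% character())
  })
  new_trait_schema(fields, n_axes = doc$n_axes,
                   n_interactors = doc$n_interactors,
                   version_label = doc$version_label,
                   axis_labels = vapply(doc$axis_labels,
                                        function(x) x %||% NA_character_, ""))
}

#' @export
print.trait_schema <- function(x, ...) {
  cat(sprintf("<trait_schema> %s: %d fields, %d axis(es), %d interactor(s)\n",
              x$version_label, length(x$fields), x$n_axes, x$n_interactors))
  for (f in x$fields)
    cat(sprintf("  %-22s %-9s %-12s %s\n", f$name, f$descriptor,
                f$requirement, f$value_kind))
  invisible(x)
}
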