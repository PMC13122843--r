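# Conversions between individual-level and aggregated representations.
# Aggregation is one-way by design: the whole point of the least-aggregated
# mandate is that collapsing individuals to means irreversibly loses
# information for mechanistic inference.

#' Aggregate individual observations along an axis
#'
#' Collapses a per-individual dataset to one group per distinct axis value,
#' reporting the group mean, the standard error of the mean (sample SD with
#' the n-1 denominator divided by sqrt(n)), and the sample size. Groups of a
#' single observation get `se = NA`: an undefined standard error is reported
#' as such, never silently as zero.
#'
#' @param dataset A `trait_dataset` whose `trait_value` and `axis_field`
#'   columns parse as numbers in every row.
#' @param axis_field Name of the numeric axis column (default
#'   `"axis_1_value"`). Grouping compares parsed values exactly.
#' @return A data.frame of class `aggregated_groups` with columns
#'   `axis_value`, `mean`, `se`, `n`, ordered by ascending axis value, and
#'   attributes `axis_field`, `axis_name`, `axis_unit`, `trait_unit` carried
#'   from the source rows.
#' @examples
#' d <- simulate_individual_dataset(simulation_config(n_per_temp = 3, seed = 1))
#' aggregate_by_axis(d)
#' @export
aggregate_by_axis <- function(dataset, axis_field = "axis_1_value") {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (nrow(dataset$rows) == 0L) stop("cannot aggregate an empty dataset")
  if (!axis_field %in% names(dataset$rows))
    stop("axis field '", axis_field, "' not present in dataset")
  y <- parse_number(dataset$rows$trait_value)
  x <- parse_number(dataset$rows[[axis_field]])
  if (anyNA(y)) stop("trait_value is not numeric in row ", which(is.na(y))[1L])
  if (anyNA(x)) stop("'", axis_field, "' is not numeric in row ",
                     which(is.na(x))[1L])
  lev <- sort(unique(x))
  out <- data.frame(
    axis_value = lev,
    mean = vapply(lev, function(v) mean(y[x == v]), 0),
    se = vapply(lev, function(v) {
      yy <- y[x == v]
      if (length(yy) < 2L) NA_real_ else sd(yy) / sqrt(length(yy))
    }, 0),
    n = vapply(lev, function(v) sum(x == v), 0L))
  prefix <- sub("_value$", "", axis_field)
  name_col <- paste0(prefix, "_name")
  unit_col <- paste0(prefix, "_unit")
  structure(out, class = c("aggregated_groups", "data.frame"),
            axis_field = axis_field,
            axis_name = if (name_col %in% names(dataset$rows))
              dataset$rows[[name_col]][1L] else NA_character_,
            axis_unit = if (unit_col %in% names(dataset$rows))
              dataset$rows[[unit_col]][1L] else NA_character_,
            trait_unit = dataset$rows$trait_unit[1L])
}

#' Build an aggregated trait dataset from group summaries
#'
#' Produces the standard-compliant way of reporting summaries: one row per
#' group with `trait_value` = group mean, plus `sample_size`,
#' `variability_metric` (`"standard error of the mean"`) and
#' `variability_value` columns, and the `aggregated_data` condition tag set
#' in the metadata. The result validates with the `AGGREGATED_DISCOURAGED`
#' warning; it only carries an `AGGREGATION_INCOMPLETE` error if a group's
#' standard error is undefined (n = 1).
#'
#' @param groups An `aggregated_groups` data.frame from
#'   [aggregate_by_axis()].
#' @param template The individual-level `trait_dataset` the groups came
#'   from; organism and trait descriptor cells are copied from its first row.
#' @return A `trait_dataset`.
#' @export
to_aggregated_dataset <- function(groups, template) {
  stopifnot(inherits(groups, "aggregated_groups"),
            inherits(template, "trait_dataset"))
  if (nrow(groups) == 0L) stop("no groups to convert")
  axis_field <- attr(groups, "axis_field")
  prefix <- sub("_value$", "", axis_field)
  first <- template$rows[1L, , drop = FALSE]
  n_g <- nrow(groups)
  rows <- first[rep(1L, n_g), , drop = FALSE]
  rownames(rows) <- NULL
  rows$unique_identifier <- rep("", n_g)
  rows$trait_value <- num_to_cell(groups$mean)
  rows$sample_size <- as.character(groups$n)
  rows$variability_metric <- rep("standard error of the mean", n_g)
  rows$variability_value <- ifelse(is.na(groups$se), "", num_to_cell(groups$se))
  rows[[axis_field]] <- num_to_cell(groups$axis_value)
  md <- template$metadata
  md$condition_tags <- unique(c(md$condition_tags, "aggregated_data"))
  trait_dataset(rows, schema = template$schema, metadata = md,
                label = paste0(template$label, " (aggregated by ", prefix, ")"))
}

#' Classify a dataset's aggregation status
#'
#' @param dataset A `trait_dataset`.
#' @return `"aggregated"` when the `aggregated_data` tag is set or any
#'   sample-size/variability cell is populated; `"individual"` when unique
#'   identifiers are present and no variability fields are populated;
#'   `"ambiguous"` otherwise.
#' @export
disaggregation_status <- function(dataset) {
  stopifnot(inherits(dataset, "trait_dataset"))
  var_cells <- c(col_or_empty(dataset, "sample_size"),
                 col_or_empty(dataset, "variability_metric"),
                 col_or_empty(dataset, "variability_value"))
  has_var <- any(!is_missing_cell(var_cells))
  if (has_tag(dataset, "aggregated_data") || has_var) return("aggregated")
  ids <- col_or_empty(dataset, "unique_identifier")
  if (length(ids) > 0L && any(!is_missing_cell(ids))) return("individual")
  "ambiguous"
}
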