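# Compliant-by-construction synthetic datasets with known TPC ground truth,
# emulating an Aedes aegypti juvenile development-rate (or lifespan) design
# across a temperature gradient, optionally crossed with a resource-level
# gradient; plus minimal perturbations that plant exactly one rule violation
# for validator testing.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a laboratory thermal-gradient experiment on *Aedes
#' aegypti* juveniles: 8 rearing temperatures between 12 and 36 degrees
#' Celsius, 20 individuals per temperature, and a Briere-1 development-rate
#' truth with thermal limits 10 and 38 degrees Celsius, peak rate around
#' 0.10 per day, and additive Gaussian observation noise of SD 0.015
#' (roughly 15% of the peak - moderate noise for this kind of assay).
#'
#' @param trait `"development_rate"` (per-day rates) or
#'   `"juvenile_lifespan"` (rounded day counts, generated as the reciprocal
#'   of the development rate - an approximation, see the package vignette).
#' @param tpc_truth A [tpc_model()] giving the generating curve and noise SD.
#' @param temperatures Degrees Celsius; at least some must fall strictly
#'   inside `(t_min, t_max)` or every trait value would be noise around 0.
#' @param n_per_temp Individuals per temperature (and per resource level).
#' @param resource_levels Optional numeric vector adding a second axis of
#'   variation (initial resource concentration, mg per larva); rates scale
#'   proportionally with level / max(level).
#' @param seed Integer seed; a fixed seed makes the output fully
#'   reproducible, byte-for-byte.
#' @param organism_label Vector taxonomy string.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(trait = c("development_rate", "juvenile_lifespan"),
                              tpc_truth = tpc_model(q = 6e-5, t_min = 10,
                                                    t_max = 38, sigma = 0.015),
                              temperatures = c(12, 16, 20, 24, 28, 32, 34, 36),
                              n_per_temp = 20L,
                              resource_levels = NULL, seed = 1L,
                              organism_label = "Aedes aegypti") {
  trait <- match.arg(trait)
  stopifnot(inherits(tpc_truth, "tpc_model"), n_per_temp >= 1L,
            length(temperatures) >= 1L)
  if (!any(temperatures > tpc_truth$t_min & temperatures < tpc_truth$t_max))
    stop("no temperature lies inside (t_min, t_max); all traits would be zero")
  structure(list(trait = trait, tpc_truth = tpc_truth,
                 temperatures = temperatures,
                 n_per_temp = as.integer(n_per_temp),
                 resource_levels = resource_levels, seed = as.integer(seed),
                 organism_label = organism_label),
            class = "simulation_config")
}

#' Generate a compliant individual-level trait dataset
#'
#' One row per individual with a unique identifier (`mosquito_0001`, ...),
#' organism descriptors filled from the standard's example vocabulary, the
#' trait value drawn as `max(briere(t) + Normal(0, sigma), 1e-6)` (or its
#' reciprocal rounded to whole days for lifespan), a temperature axis (and a
#' resource axis when configured), and placeholder citation/submitter
#' metadata. The output passes [validate_dataset()] with zero errors for
#' every seed and configuration.
#'
#' @param config A [simulation_config()].
#' @return A `trait_dataset`.
#' @examples
#' d <- simulate_individual_dataset(simulation_config(n_per_temp = 2, seed = 3))
#' nrow(d$rows)
#' @export
simulate_individual_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  tr <- config$tpc_truth
  levels <- config$resource_levels
  schema <- default_mirevtd_schema()
  if (!is.null(levels))
    schema <- extend_with_axis(schema, "initial resource concentration",
                               "mg per larva")
  grid <- expand.grid(rep_i = seq_len(config$n_per_temp),
                      temp = config$temperatures,
                      resource = if (is.null(levels)) NA_real_ else levels)
  n <- nrow(grid)
  set.seed(config$seed)
  rate_mu <- briere(grid$temp, tr$q, tr$t_min, tr$t_max)
  if (!is.null(levels)) rate_mu <- rate_mu * grid$resource / max(levels)
  rate <- pmax(rate_mu + rnorm(n, 0, tr$sigma), 1e-6)
  if (config$trait == "development_rate") {
    value <- num_to_cell(rate)
    trait_name <- "juvenile development rate"
    trait_unit <- "per day"
  } else {
    value <- as.character(pmax(round(1 / rate), 1))
    trait_name <- "juvenile lifespan"
    trait_unit <- "days"
  }
  rows <- data.frame(
    vector_taxonomy = config$organism_label,
    unique_identifier = sprintf("mosquito_%04d", seq_len(n)),
    life_stage = "larvae",
    sex = "mixed",
    trait_name = trait_name,
    trait_value = value,
    trait_unit = trait_unit,
    observation_date = "2022-03-01",
    axis_1_name = "temperature",
    axis_1_value = num_to_cell(grid$temp),
    axis_1_unit = "Degrees celsius",
    stringsAsFactors = FALSE)
  if (!is.null(levels)) {
    rows$axis_2_name <- "initial resource concentration"
    rows$axis_2_value <- num_to_cell(grid$resource)
    rows$axis_2_unit <- "mg per larva"
  }
  md <- dataset_metadata(
    citation = paste("Synthetic dataset generated by the mirevtd package;",
                     "emulates a juvenile life-history assay on Aedes aegypti",
                     "across a temperature gradient."),
    doi = "10.0000/synthetic.example",
    submitter_name = "mirevtd generator",
    submitter_contact = "maintainer@example.org")
  trait_dataset(rows, schema = schema, metadata = md,
                label = sprintf("synthetic %s (seed %d)", config$trait,
                                config$seed))
}

#' Plant exactly one rule violation in a compliant dataset
#'
#' Returns a minimally modified copy of `dataset` that triggers the named
#' rule and no other ERROR-level rule (co-occurring WARNINGs are possible
#' and documented per rule). The modification is recorded in the returned
#' dataset's label. Used to build the validator's pairwise pass/fail
#' fixtures.
#'
#' @param dataset A compliant `trait_dataset` (typically from
#'   [simulate_individual_dataset()]).
#' @param violation One of [rule_ids()].
#' @return A perturbed `trait_dataset`.
#' @export
perturb_for_fixture <- function(dataset, violation) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (!violation %in% rule_ids())
    stop("unknown rule id '", violation, "'; registered rules: ",
         paste(rule_ids(), collapse = ", "))
  d <- dataset
  if (nrow(d$rows) < 2L)
    stop("cannot plant '", violation, "': need at least 2 rows to perturb safely")
  note <- function(what) {
    d$label <<- paste0(dataset$label, " [", violation, ": ", what, "]")
  }
  add_tag <- function(tag) {
    d$metadata$condition_tags <<- unique(c(d$metadata$condition_tags, tag))
  }
  switch(violation,
    REQUIRED_FIELD_MISSING = {
      d$rows$sex[1L] <- ""
      note("sex blanked in row 1")
    },
    UNITS_MISSING = {
      d$rows$trait_unit[1L] <- ""
      note("trait_unit blanked in row 1")
    },
    UNITS_NOT_SEPARATED = {
      d$rows$trait_value[1L] <- paste(d$rows$trait_value[1L], "days")
      note("unit appended to trait_value in row 1")
    },
    VALUE_NOT_NUMERIC = {
      d$rows$axis_1_value[1L] <- "twenty"
      note("axis_1_value spelled out in row 1")
    },
    DATE_NOT_ISO = {
      d$rows$observation_date[1L] <- "01/03/2022"
      note("observation_date flipped to DD/MM/YYYY in row 1")
    },
    DATE_UNPARSEABLE = {
      d$rows$observation_date[1L] <- "yesterday"
      note("observation_date garbled in row 1")
    },
    NON_ASCII = {
      d$rows$vector_taxonomy[1L] <- "A\u00ebdes aegypti"
      note("diacritic introduced in vector_taxonomy, row 1")
    },
    ABBREVIATION_SUSPECT = {
      d$rows$vector_taxonomy[1L] <- "Culex spp."
      note("abbreviated taxon in vector_taxonomy, row 1")
    },
    PROPORTION_DENOMINATOR_MISSING = {
      d$rows$trait_unit[1L] <- "percent mortality"
      d$rows$numerator[1L] <- "45"
      d$rows$denominator[1L] <- ""
      note("proportion unit without denominator in row 1")
    },
    DUPLICATE_IDENTIFIER = {
      d$rows$unique_identifier[2L] <- d$rows$unique_identifier[1L]
      for (a in paste0("axis_", seq_len(d$schema$n_axes), "_value"))
        d$rows[[a]][2L] <- d$rows[[a]][1L]
      note("row 2 duplicates row 1's identifier and axis values")
    },
    LATLONG_OUT_OF_RANGE = {
      add_tag("field_study")
      d$rows$location_latitude <- rep("26.64", nrow(d$rows))
      d$rows$location_longitude <- rep("-81.87", nrow(d$rows))
      d$rows$location_latitude[1L] <- "123.4"
      note("latitude 123.4 out of range in row 1")
    },
    LOCATION_MISSING = {
      add_tag("field_study")
      note("field_study tag set with empty latitude/longitude")
    },
    CITATION_MISSING = {
      d$metadata$citation <- ""
      note("citation blanked")
    },
    SUBMITTER_MISSING = {
      d$metadata$submitter_name <- ""
      note("submitter name blanked")
    },
    EMBARGO_MALFORMED = {
      d$metadata$embargo_date <- "March 2022"
      note("embargo date not ISO 8601")
    },
    AGGREGATION_INCOMPLETE = {
      add_tag("aggregated_data")
      note("aggregated_data tag set without sample sizes or variability")
    },
    AGGREGATED_DISCOURAGED = {
      add_tag("aggregated_data")
      d$rows$sample_size <- rep("10", nrow(d$rows))
      d$rows$variability_metric <- rep("standard error of the mean", nrow(d$rows))
      d$rows$variability_value <- rep("0.01", nrow(d$rows))
      note("aggregated_data tag set with complete variability fields")
    },
    PATHOGEN_MISSING = {
      add_tag("transmission_study")
      note("transmission_study tag set with empty pathogen_taxonomy")
    })
  d
}
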