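test_that("the default schema carries the minimum descriptors", {
  sch <- default_mirevtd_schema()
  nm <- names(sch$fields)
  expect_true(all(c("vector_taxonomy", "unique_identifier", "life_stage",
                    "sex", "trait_name", "trait_value", "trait_unit",
                    "axis_1_name", "axis_1_value", "axis_1_unit",
                    "pathogen_taxonomy", "numerator", "denominator",
                    "sample_size", "variability_metric",
                    "location_latitude", "location_longitude") %in% nm))
  expect_identical(sch$n_axes, 1L)
  # printed example vocabulary travels with the field specs
  expect_true("Aedes aegypti" %in% sch$fields$vector_taxonomy$example_values)
  expect_true(all(c("days", "eggs laid") %in%
                    sch$fields$trait_unit$example_values))
  # every descriptor category is represented by a required field
  req <- Filter(function(f) f$requirement == "required", sch$fields)
  expect_true(all(c("organism", "trait", "axis") %in%
                    vapply(req, `[[`, "", "descriptor")))
  # conditional fields name their trigger
  cond <- Filter(function(f) f$requirement == "conditional", sch$fields)
  expect_true(all(!is.na(vapply(cond, `[[`, "", "condition_tag"))))
})

test_that("field_spec rejects malformed definitions", {
  expect_error(field_spec("", "trait", "required", "text"), "non-empty")
  expect_error(field_spec("temp.", "axis", "required", "numeric"),
               "abbreviation")
  expect_error(field_spec("caf\u00e9", "trait", "required", "text"), "ASCII")
  expect_error(field_spec("pathogen", "organism", "conditional", "text"),
               "condition_tag")
})

test_that("extending with an axis adds a value/unit pair and is pure", {
  base <- default_mirevtd_schema()
  s2 <- extend_with_axis(base, "temperature", "Degrees celsius")
  expect_identical(s2$n_axes, 2L)
  expect_true(all(c("axis_2_name", "axis_2_value", "axis_2_unit") %in%
                    names(s2$fields)))
  s3 <- extend_with_axis(base, "initial resource concentration",
                         "mg per larva")
  expect_identical(s3$n_axes, 2L)
  expect_identical(base$n_axes, 1L) # input untouched
  expect_error(extend_with_axis(s2, "temperature", "Degrees celsius"),
               "collision")
})

test_that("interactor extension numbers pathogen blocks distinctly", {
  base <- default_mirevtd_schema()
  s2 <- extend_with_interactor(base)
  expect_identical(s2$n_interactors, 2L)
  expect_true("Plasmodium falciparum (N54 strain)" %in%
                s2$fields$pathogen_taxonomy$example_values)
  s3 <- extend_with_interactor(s2)
  expect_identical(s3$n_interactors, 3L)
  expect_false(anyDuplicated(names(s3$fields)) > 0)
  expect_identical(base$n_interactors, 1L)
})

test_that("schemas survive a JSON round trip", {
  sch <- extend_with_axis(default_mirevtd_schema(), "relative humidity",
                          "percent")
  path <- withr::local_tempfile(fileext = ".json")
  schema_to_json(sch, path)
  back <- schema_from_json(path)
  expect_identical(names(back$fields), names(sch$fields))
  expect_identical(back$n_axes, sch$n_axes)
  expect_identical(back$axis_labels, sch$axis_labels)
  expect_equal(back$fields$trait_unit$example_values,
               sch$fields$trait_unit$example_values)
})
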