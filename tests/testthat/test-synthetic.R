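test_that("the generator produces the configured design", {
  d <- simulate_individual_dataset(
    simulation_config(temperatures = c(15, 20, 25, 30, 35), n_per_temp = 10,
                      seed = 40))
  expect_identical(nrow(d$rows), 50L)
  expect_identical(length(unique(d$rows$unique_identifier)), 50L)
  expect_identical(unique(d$rows$axis_1_unit), "Degrees celsius")
  expect_identical(unique(d$rows$vector_taxonomy), "Aedes aegypti")
  expect_true(parse_iso_date(d$rows$observation_date[1])$ok)
})

test_that("a fixed seed reproduces the CSV byte-for-byte", {
  cfg <- simulation_config(n_per_temp = 3, seed = 99)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trait_dataset(simulate_individual_dataset(cfg), p1)
  write_trait_dataset(simulate_individual_dataset(cfg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("two-stressor designs add a resource axis of variation", {
  d <- simulate_individual_dataset(
    simulation_config(n_per_temp = 2, resource_levels = c(0.1, 1), seed = 41))
  expect_identical(d$schema$n_axes, 2L)
  expect_true(all(c("axis_2_name", "axis_2_value", "axis_2_unit") %in%
                    names(d$rows)))
  expect_identical(unique(d$rows$axis_2_unit), "mg per larva")
  expect_identical(validate_dataset(d)$n_errors, 0L)
})

test_that("lifespan datasets report whole positive day counts", {
  d <- simulate_individual_dataset(
    simulation_config(trait = "juvenile_lifespan", n_per_temp = 3, seed = 42))
  days <- as.numeric(d$rows$trait_value)
  expect_true(all(days == round(days)))
  expect_true(all(days >= 1))
  expect_identical(unique(d$rows$trait_unit), "days")
  expect_identical(validate_dataset(d)$n_errors, 0L)
})

test_that("per-temperature means converge to the generating curve", {
  truth <- tpc_model(6e-5, 10, 38, 0.015)
  cfg <- simulation_config(tpc_truth = truth,
                           temperatures = c(24, 28, 32), n_per_temp = 1000,
                           seed = 43)
  d <- simulate_individual_dataset(cfg)
  g <- aggregate_by_axis(d)
  expected <- briere(g$axis_value, truth$q, truth$t_min, truth$t_max)
  # SE of a mean of 1000 draws at sigma 0.015 is ~5e-4
  expect_true(all(abs(g$mean - expected) < 3e-3))
})

test_that("misconfigured simulations are rejected", {
  expect_error(simulation_config(temperatures = c(1, 5), n_per_temp = 3),
               "inside")
  expect_error(simulation_config(n_per_temp = 0), "n_per_temp")
})

test_that("perturbations reject unknown rules and tiny datasets", {
  d <- quick_sim(n_per_temp = 2, seed = 44)
  expect_error(perturb_for_fixture(d, "NOT_A_RULE"), "unknown rule")
  one <- d
  one$rows <- one$rows[1, , drop = FALSE]
  expect_error(perturb_for_fixture(one, "UNITS_MISSING"), "2 rows")
})

test_that("each perturbation labels itself and hits its target", {
  d <- quick_sim(n_per_temp = 2, seed = 45)
  for (rid in c("UNITS_MISSING", "NON_ASCII", "PROPORTION_DENOMINATOR_MISSING")) {
    p <- perturb_for_fixture(d, rid)
    expect_match(p$label, rid, fixed = TRUE)
    expect_true(rid %in% validate_dataset(p)$issues$rule_id)
  }
  # the proportion fixture uses the printed example unit
  p <- perturb_for_fixture(d, "PROPORTION_DENOMINATOR_MISSING")
  expect_identical(p$rows$trait_unit[1], "percent mortality")
})
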