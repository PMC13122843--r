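test_that("generator output is compliant and deleting units breaks it", {
  d <- quick_sim(n_per_temp = 3, seed = 4)
  rep0 <- validate_dataset(d)
  expect_true(rep0$compliant)
  expect_identical(rep0$n_errors, 0L)
  # drop the unit column entirely: one UNITS_MISSING error per row
  d2 <- d
  d2$rows$trait_unit <- rep("", nrow(d2$rows))
  rep2 <- validate_dataset(d2)
  expect_false(rep2$compliant)
  units_missing <- rep2$issues[rep2$issues$rule_id == "UNITS_MISSING", ]
  expect_identical(nrow(units_missing), nrow(d2$rows))
  expect_identical(error_rule_ids(rep2), "UNITS_MISSING")
})

test_that("a value cell carrying its unit is pinned to its row", {
  d <- quick_sim(n_per_temp = 2, seed = 5)
  d$rows$trait_value[3] <- "45 days"
  rep <- validate_dataset(d)
  hit <- rep$issues[rep$issues$rule_id == "UNITS_NOT_SEPARATED", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$row_index, 3L)
  expect_identical(hit$severity, "ERROR")
})

test_that("check_rule isolates a single rule and rejects unknown ids", {
  d <- quick_sim(n_per_temp = 2, seed = 6)
  d$rows$observation_date[1] <- "03/01/2022"
  hit <- check_rule("DATE_NOT_ISO", d)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$severity, "WARNING")
  expect_identical(nrow(check_rule("NON_ASCII", d)), 0L)
  expect_error(check_rule("UNKNOWN", d), "registered rules")
})

test_that("validate equals the concatenation of per-rule checks", {
  d <- quick_sim(n_per_temp = 2, seed = 7)
  # plant a mixture of findings
  d$rows$sex[1] <- ""
  d$rows$observation_date[2] <- "01/03/2022"
  d$metadata$embargo_date <- "soon"
  full <- validate_dataset(d)$issues
  parts <- do.call(rbind, lapply(rule_ids(), check_rule, dataset = d))
  key_row <- ifelse(is.na(parts$row_index), -1L, parts$row_index)
  parts <- parts[order(key_row, parts$rule_id, parts$field, method = "radix"), ]
  rownames(parts) <- NULL
  expect_identical(full, parts)
})

test_that("repeat measures are legitimate but exact duplicates are flagged", {
  d <- quick_sim(n_per_temp = 2, seed = 8)
  # rows 1 and 3 sit at different temperatures: a shared identifier there is
  # a legitimate repeat measure across axis levels
  d$rows$unique_identifier[3] <- d$rows$unique_identifier[1]
  expect_identical(nrow(check_rule("DUPLICATE_IDENTIFIER", d)), 0L)
  # now identical on the axis too: flagged
  d$rows$axis_1_value[3] <- d$rows$axis_1_value[1]
  expect_identical(nrow(check_rule("DUPLICATE_IDENTIFIER", d)), 1L)
})

test_that("conditional rules only fire when their tag is active", {
  d <- quick_sim(n_per_temp = 2, seed = 9)
  expect_identical(nrow(check_rule("PATHOGEN_MISSING", d)), 0L)
  d$metadata$condition_tags <- "transmission_study"
  expect_identical(nrow(check_rule("PATHOGEN_MISSING", d)), nrow(d$rows))
  d$rows$pathogen_taxonomy <- rep("West Nile virus", nrow(d$rows))
  expect_identical(nrow(check_rule("PATHOGEN_MISSING", d)), 0L)
})

test_that("adding a violating row never decreases the error count", {
  d <- quick_sim(n_per_temp = 2, seed = 10)
  base_errors <- validate_dataset(d)$n_errors
  bad <- d$rows[1, , drop = FALSE]
  bad$trait_value <- "fast"
  bad$unique_identifier <- "mosquito_9999"
  d$rows <- rbind(d$rows, bad)
  expect_gt(validate_dataset(d)$n_errors, base_errors)
})

test_that("reports render deterministically in both formats", {
  d <- quick_sim(n_per_temp = 2, seed = 11)
  d$rows$sex[1] <- ""
  rep <- validate_dataset(d)
  txt <- render_report(rep, "text")
  expect_identical(txt, render_report(rep, "text"))
  expect_match(txt, "REQUIRED_FIELD_MISSING")
  expect_match(txt, "Table 1", fixed = TRUE)
  js <- jsonlite::fromJSON(render_report(rep, "json"))
  expect_identical(js$report_version, 1L)
  expect_false(js$compliant)
  expect_identical(nrow(js$issues), nrow(rep$issues))
  # empty report
  clean <- validate_dataset(quick_sim(seed = 11))
  js0 <- jsonlite::fromJSON(render_report(clean, "json"))
  expect_true(js0$compliant)
  expect_length(js0$issues, 0L)
  expect_error(render_report(rep, "yaml"))
})

test_that("report invariants hold: compliance and issue accounting", {
  for (seed in 1:5) {
    d <- quick_sim(n_per_temp = 2, seed = seed)
    if (seed %% 2 == 0) d$rows$sex[1] <- ""
    rep <- validate_dataset(d)
    expect_identical(rep$n_errors + rep$n_warnings, nrow(rep$issues))
    expect_identical(rep$compliant, rep$n_errors == 0L)
  }
})
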