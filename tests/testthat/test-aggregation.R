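make_numeric_dataset <- function(y, x) {
  d <- quick_sim(n_per_temp = 2, seed = 1)
  rows <- d$rows[rep(1L, length(y)), , drop = FALSE]
  rownames(rows) <- NULL
  rows$unique_identifier <- sprintf("mosquito_%04d", seq_along(y))
  rows$trait_value <- as.character(y)
  rows$axis_1_value <- as.character(x)
  trait_dataset(rows, d$schema, d$metadata, label = "hand-built")
}

test_that("group mean, SE and n match hand computation", {
  d <- make_numeric_dataset(c(1, 2, 3, 5, 4, 4), c(20, 20, 20, 25, 30, 30))
  g <- aggregate_by_axis(d)
  expect_equal(g$axis_value, c(20, 25, 30))
  expect_equal(g$mean, c(2, 5, 4))
  expect_equal(g$se[1], 1 / sqrt(3), tolerance = 1e-12) # sd({1,2,3}) = 1
  expect_true(is.na(g$se[2]))                           # n = 1: undefined
  expect_identical(g$se[3], 0)                          # zero variance
  expect_identical(g$n, c(3L, 1L, 2L))
})

test_that("aggregation matches a brute-force oracle on random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    x <- sample(c(12, 16, 20, 24), n, replace = TRUE)
    y <- round(rnorm(n, 10, 3), 6)
    d <- make_numeric_dataset(y, x)
    g <- aggregate_by_axis(d)
    o <- oracle_groups(x, y)
    expect_equal(g$mean, o$mean, tolerance = 1e-12)
    expect_equal(g$se, o$se, tolerance = 1e-12)
    expect_identical(sum(g$n), n) # conservation of individuals
  }
})

test_that("non-numeric cells and empty datasets are rejected", {
  d <- make_numeric_dataset(c(1, "fast"), c(20, 20))
  expect_error(aggregate_by_axis(d), "row 2")
  d0 <- quick_sim()
  d0$rows <- d0$rows[0, , drop = FALSE]
  expect_error(aggregate_by_axis(d0), "empty")
})

test_that("the aggregated dataset is compliant but discouraged", {
  d <- quick_sim(n_per_temp = 4, seed = 13)
  agg <- to_aggregated_dataset(aggregate_by_axis(d), d)
  expect_identical(nrow(agg$rows), length(unique(d$rows$axis_1_value)))
  expect_true("aggregated_data" %in% agg$metadata$condition_tags)
  rep <- validate_dataset(agg)
  expect_identical(rep$n_errors, 0L)
  expect_true("AGGREGATED_DISCOURAGED" %in% rep$issues$rule_id)
  expect_identical(agg$rows$variability_metric[1], "standard error of the mean")
})

test_that("an undefined SE surfaces as an incompleteness error", {
  d <- quick_sim(n_per_temp = 1, seed = 14) # singleton groups: se undefined
  agg <- to_aggregated_dataset(aggregate_by_axis(d), d)
  rep <- validate_dataset(agg)
  expect_true("AGGREGATION_INCOMPLETE" %in% error_rule_ids(rep))
})

test_that("aggregation status is classified and survives a round trip", {
  d <- quick_sim(n_per_temp = 3, seed = 15)
  expect_identical(disaggregation_status(d), "individual")
  agg <- to_aggregated_dataset(aggregate_by_axis(d), d)
  expect_identical(disaggregation_status(agg), "aggregated")
  amb <- d
  amb$rows$unique_identifier <- rep("", nrow(amb$rows))
  expect_identical(disaggregation_status(amb), "ambiguous")
  for (x in list(d, agg)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_trait_dataset(x, path)
    expect_identical(disaggregation_status(read_trait_dataset(path)),
                     disaggregation_status(x))
  }
})
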