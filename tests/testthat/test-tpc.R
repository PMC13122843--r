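test_that("the Briere curve is zero at its limits and matches arithmetic", {
  expect_identical(briere(10, 1, 10, 38), 0)
  expect_identical(briere(38, 1, 10, 38), 0)
  expect_identical(briere(c(-5, 50), 1, 10, 38), c(0, 0))
  expect_equal(briere(25, 1, 10, 38), 375 * sqrt(13), tolerance = 1e-12)
  expect_true(all(briere(seq(-20, 60, by = 0.5), 2, 5, 30) >= 0))
  expect_error(briere(20, 1, 30, 10), "t_min")
})

test_that("the closed-form peak temperature agrees with grid maximisation", {
  cases <- list(c(10, 38), c(0, 35), c(-5, 20), c(14.2, 41.7))
  for (cs in cases) {
    tpk <- derived_tpk(cs[1], cs[2])
    opt <- optimize(function(t) briere(t, 1, cs[1], cs[2]),
                    interval = cs, maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(tpk, opt, tolerance = 1e-4)
    expect_gt(tpk, cs[1])
    expect_lt(tpk, cs[2])
  }
  expect_equal(derived_tpk(0, 35), 0.8 * 35, tolerance = 1e-12)
  # invariant to the scale constant q
  expect_identical(derived_tpk(10, 38), derived_tpk(10, 38))
  expect_equal(optimize(function(t) briere(t, 7, 10, 38), c(10, 38),
                        maximum = TRUE, tol = 1e-10)$maximum,
               derived_tpk(10, 38), tolerance = 1e-4)
})

test_that("log_posterior handles support, normal density, and additivity", {
  pr <- prior_spec()
  lp_const <- -sum(log(vapply(unclass(pr), diff, 0)))
  expect_identical(log_posterior(c(2, 10, 38, 0.1), data.frame(t = 20, y = 1), pr),
                   -Inf) # q above prior
  expect_identical(log_posterior(c(0.5, 24, 24, 0.1), data.frame(t = 20, y = 1), pr),
                   -Inf) # t_min >= t_max
  # one observation exactly on the curve with sigma = 1
  y_on <- briere(20, 0.5, 10, 38)
  pr2 <- prior_spec(q = c(0, 1), sigma = c(0, 2))
  lp2_const <- -sum(log(vapply(unclass(pr2), diff, 0)))
  expect_equal(log_posterior(c(0.5, 10, 38, 1), data.frame(t = 20, y = y_on), pr2),
               -0.5 * log(2 * pi) + lp2_const, tolerance = 1e-12)
  # doubling the data doubles the likelihood term exactly
  d1 <- data.frame(t = c(15, 20, 25), y = c(0.5, 0.9, 1.2))
  d2 <- rbind(d1, d1)
  th <- c(2e-4, 10, 38, 0.5)
  ll1 <- log_posterior(th, d1, pr) - lp_const
  ll2 <- log_posterior(th, d2, pr) - lp_const
  expect_equal(ll2, 2 * ll1, tolerance = 1e-12)
})

test_that("hpd_interval matches the brute-force window scan", {
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  expect_equal(hpd_interval(rep(3.5, 10), 0.9), c(3.5, 3.5))
  expect_equal(hpd_interval(c(0, 0, 0, 10), 0.5), c(0, 0))
  for (seed in 1:10) {
    set.seed(seed)
    s <- c(rnorm(80), rnorm(20, 5))
    prob <- runif(1, 0.3, 0.98)
    expect_equal(hpd_interval(s, prob), oracle_hpd(s, prob))
  }
  expect_error(hpd_interval(numeric(0), 0.95), "no samples")
})

test_that("the sampler is deterministic and flags too-few temperatures", {
  obs <- tpc_observations(quick_sim(n_per_temp = 3, seed = 20))
  cfg <- fit_config(n_iter = 1500, n_burn = 500, seed = 5)
  f1 <- fit_tpc(obs, config = cfg)
  f2 <- fit_tpc(obs, config = cfg)
  expect_identical(f1$samples, f2$samples)
  f3 <- fit_tpc(obs, config = fit_config(n_iter = 1500, n_burn = 500, seed = 6))
  expect_false(identical(f1$samples, f3$samples))
  few <- data.frame(t = c(10, 20, 30, 10, 20), y = 1:5)
  expect_error(fit_tpc(few, config = cfg), "4 distinct temperatures")
})

test_that("near-noiseless dense data pin the thermal limits", {
  cfg <- simulation_config(
    tpc_truth = tpc_model(6e-5, 10, 38, 1e-4),
    temperatures = seq(12, 37, length.out = 15), n_per_temp = 50, seed = 77)
  obs <- tpc_observations(simulate_individual_dataset(cfg))
  fit <- fit_tpc(obs, config = fit_config(n_iter = 8000, n_burn = 3000, seed = 1))
  med <- apply(fit$samples, 2, median)
  expect_lt(abs(med["t_min"] - 10), 0.5)
  expect_lt(abs(med["t_max"] - 38), 0.5)
  s <- summarize_tpc(fit)
  expect_true(all(s$params$hpd_low <= s$params$median &
                    s$params$median <= s$params$hpd_high))
  tpk_row <- s$params[s$params$parameter == "t_pk", ]
  expect_gt(tpk_row$median, med["t_min"])
  expect_lt(tpk_row$median, med["t_max"])
})

test_that("more individuals per temperature shrink the intervals", {
  width_tmax <- function(n_per_temp) {
    obs <- tpc_observations(simulate_individual_dataset(
      simulation_config(n_per_temp = n_per_temp, seed = 31)))
    s <- summarize_tpc(fit_tpc(obs, config = fit_config(n_iter = 6000,
                                                        n_burn = 2000,
                                                        seed = 2)))
    r <- s$params[s$params$parameter == "t_max", ]
    r$hpd_high - r$hpd_low
  }
  w <- vapply(c(5L, 80L), width_tmax, 0)
  expect_lt(w[2], w[1])
})

test_that("comparison records are symmetric-safe and serialize losslessly", {
  obs <- tpc_observations(quick_sim(n_per_temp = 4, seed = 22))
  s <- summarize_tpc(fit_tpc(obs, config = fit_config(n_iter = 2000,
                                                      n_burn = 500, seed = 3)))
  self <- compare_fits(s, s)
  expect_true(all(self$table$median_diff == 0))
  expect_true(all(self$table$width_ratio == 1))
  js <- render_comparison(self, "json")
  back <- comparison_from_json(js)
  expect_equal(back$table, self$table, tolerance = 1e-15)
  expect_match(render_comparison(self, "text"), "width ratio")
  # posterior summary JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  summary_to_json(s, path)
  s2 <- summary_from_json(path)
  expect_equal(s2$params, s$params, tolerance = 1e-15)
})
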