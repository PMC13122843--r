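# Shared fixture builders: everything is generated in code at test time.

quick_sim <- function(n_per_temp = 2L, seed = 1L, ...) {
  simulate_individual_dataset(
    simulation_config(n_per_temp = n_per_temp, seed = seed, ...))
}

# a small pool of randomized-but-valid generator configurations
random_config <- function(seed) {
  set.seed(seed)
  temps <- sort(sample(seq(12, 36, by = 2), sample(5:9, 1)))
  simulation_config(
    trait = sample(c("development_rate", "juvenile_lifespan"), 1),
    temperatures = temps,
    n_per_temp = sample(1:4, 1),
    resource_levels = if (runif(1) < 0.3) c(0.1, 0.5, 1) else NULL,
    seed = seed)
}

error_rule_ids <- function(report) {
  unique(report$issues$rule_id[report$issues$severity == "ERROR"])
}

# brute-force two-pass mean/se oracle, independent of aggregate_by_axis
oracle_groups <- function(x, y) {
  lev <- sort(unique(x))
  do.call(rbind, lapply(lev, function(v) {
    yy <- y[x == v]
    m <- sum(yy) / length(yy)
    se <- if (length(yy) < 2) NA_real_ else {
      ss <- sum((yy - m)^2) / (length(yy) - 1)
      sqrt(ss) / sqrt(length(yy))
    }
    data.frame(axis_value = v, mean = m, se = se, n = length(yy))
  }))
}

# brute-force HPD oracle: scan every window of ceiling(prob*n) sorted samples
oracle_hpd <- function(samples, prob) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(Inf, NA, NA)
  for (k in seq_len(n - m + 1)) {
    w <- s[k + m - 1] - s[k]
    if (w < best[1]) best <- c(w, s[k], s[k + m - 1])
  }
  best[2:3]
}
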