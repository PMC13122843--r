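# Bayesian fitting of a Briere-1 thermal performance curve by component-wise
# adaptive random-walk Metropolis. This is the computational demonstration of
# why the standard mandates least-aggregated data: fitting per-temperature
# means instead of individuals inflates posterior uncertainty on the thermal
# limits.

#' Briere-1 thermal performance curve parameters
#'
#' @param q Rate scaling constant, > 0.
#' @param t_min,t_max Lower and upper thermal limits in degrees Celsius,
#'   `t_min < t_max`.
#' @param sigma Observation noise SD in trait units, > 0.
#' @return An object of class `tpc_model`.
#' @export
tpc_model <- function(q, t_min, t_max, sigma) {
  stopifnot(q > 0, sigma > 0)
  if (t_min >= t_max) stop("t_min must be strictly below t_max")
  structure(list(q = q, t_min = t_min, t_max = t_max, sigma = sigma),
            class = "tpc_model")
}

#' Briere-1 thermal performance function
#'
#' `rate = q * t * (t - t_min) * sqrt(t_max - t)` for `t_min < t < t_max`,
#' and exactly 0 at and outside the thermal limits - the standard asymmetric
#' unimodal form for arthropod development rate.
#'
#' @param t Temperature(s), degrees Celsius; vectorised.
#' @param q,t_min,t_max Curve parameters (see [tpc_model()]).
#' @return Non-negative rate(s) in trait units.
#' @examples
#' briere(25, q = 1, t_min = 10, t_max = 38) # 375 * sqrt(13)
#' @export
briere <- function(t, q, t_min, t_max) {
  if (t_min >= t_max) stop("t_min must be strictly below t_max")
  inside <- t > t_min & t < t_max
  out <- numeric(length(t))
  ti <- t[inside]
  out[inside] <- q * ti * (ti - t_min) * sqrt(t_max - ti)
  pmax(out, 0)
}

#' Temperature of peak performance
#'
#' Closed-form argmax of the Briere-1 curve over `[t_min, t_max]`:
#' `(4 t_max + 3 t_min + sqrt(16 t_max^2 + 9 t_min^2 - 16 t_min t_max)) / 10`,
#' always strictly inside the thermal limits, and independent of `q`.
#'
#' @param t_min,t_max Thermal limits (vectorised); alternatively pass a
#'   [tpc_model()] as the first argument.
#' @return Peak temperature(s) in degrees Celsius.
#' @examples
#' derived_tpk(10, 38)
#' derived_tpk(0, 35) # = 0.8 * t_max when t_min = 0
#' @export
derived_tpk <- function(t_min, t_max) {
  if (inherits(t_min, "tpc_model")) {
    t_max <- t_min$t_max
    t_min <- t_min$t_min
  }
  if (any(t_min >= t_max)) stop("t_min must be strictly below t_max")
  (4 * t_max + 3 * t_min +
     sqrt(16 * t_max^2 + 9 * t_min^2 - 16 * t_min * t_max)) / 10
}

#' Independent uniform priors for the TPC parameters
#'
#' Weakly informative defaults, deliberately wide relative to a mosquito
#' development-rate problem (trait scale ~0.1 per day): the same priors are
#' shared between individual-level and aggregated fits so any difference
#' between the posteriors is attributable to the data alone.
#'
#' @param q,t_min,t_max,sigma Length-2 numeric `c(lower, upper)` bounds.
#'   `q` and `sigma` supports are open at 0; the joint support additionally
#'   imposes `t_min < t_max`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(q = c(0, 1), t_min = c(-10, 25), t_max = c(25, 50),
                       sigma = c(0, 1)) {
  b <- list(q = q, t_min = t_min, t_max = t_max, sigma = sigma)
  for (nm in names(b)) {
    stopifnot(length(b[[nm]]) == 2L)
    if (b[[nm]][1] >= b[[nm]][2])
      stop("prior for ", nm, " needs lower < upper")
  }
  if (b$t_min[1] >= b$t_max[2])
    stop("t_min and t_max prior supports leave no room for t_min < t_max")
  structure(b, class = "prior_spec")
}

prior_bounds <- function(priors) {
  list(lo = c(q = priors$q[1], t_min = priors$t_min[1],
              t_max = priors$t_max[1], sigma = priors$sigma[1]),
       hi = c(q = priors$q[2], t_min = priors$t_min[2],
              t_max = priors$t_max[2], sigma = priors$sigma[2]))
}

#' Log posterior density of a TPC model
#'
#' Gaussian observation model around the Briere-1 curve plus independent
#' uniform priors; returns `-Inf` outside the prior support or when
#' `t_min >= t_max`.
#'
#' @param params Numeric vector `c(q, t_min, t_max, sigma)` or a
#'   [tpc_model()].
#' @param data A data.frame with numeric columns `t` (temperature) and `y`
#'   (trait value); may have zero rows, in which case only the prior
#'   contributes.
#' @param priors A [prior_spec()].
#' @return A single number (possibly `-Inf`).
#' @export
log_posterior <- function(params, data, priors = prior_spec()) {
  if (inherits(params, "tpc_model"))
    params <- c(params$q, params$t_min, params$t_max, params$sigma)
  stopifnot(length(params) == 4L)
  b <- prior_bounds(priors)
  lp_const <- -sum(log(b$hi - b$lo))
  if (any(params < b$lo) || any(params > b$hi) ||
      params[1] <= 0 || params[4] <= 0 || params[2] >= params[3])
    return(-Inf)
  ll <- 0
  if (nrow(data) > 0L) {
    mu <- briere(data$t, params[1], params[2], params[3])
    ll <- sum(dnorm(data$y, mu, params[4], log = TRUE))
  }
  ll + lp_const
}

#' MCMC configuration for [fit_tpc()]
#'
#' @param n_iter Total iterations (including burn-in).
#' @param n_burn Burn-in iterations during which proposal scales adapt
#'   toward a 25-40% acceptance rate; scales are frozen afterwards, so the
#'   retained chain satisfies detailed balance.
#' @param seed Integer seed; identical `(data, priors, config)` give an
#'   identical chain.
#' @param proposal_scales Optional numeric(4) initial proposal SDs for
#'   `(q, t_min, t_max, sigma)`; defaults to 10% of each prior width.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_iter = 20000L, n_burn = 5000L, seed = 1L,
                       proposal_scales = NULL) {
  stopifnot(n_iter > n_burn, n_burn >= 0)
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 seed = as.integer(seed), proposal_scales = proposal_scales),
            class = "fit_config")
}

#' Extract (temperature, trait value) observations from a trait dataset
#'
#' @param dataset A `trait_dataset`.
#' @param axis_field Numeric axis column to use as temperature.
#' @return A data.frame with numeric columns `t` and `y`.
#' @export
tpc_observations <- function(dataset, axis_field = "axis_1_value") {
  stopifnot(inherits(dataset, "trait_dataset"))
  y <- parse_number(dataset$rows$trait_value)
  t <- parse_number(dataset$rows[[axis_field]])
  if (anyNA(y)) stop("trait_value is not numeric in row ", which(is.na(y))[1L])
  if (anyNA(t)) stop("'", axis_field, "' is not numeric in row ",
                     which(is.na(t))[1L])
  data.frame(t = t, y = y)
}

#' Fit a Briere-1 TPC by adaptive random-walk Metropolis
#'
#' Single-chain component-wise Metropolis with Gaussian proposals. During
#' burn-in each parameter's proposal scale is multiplicatively adapted every
#' 50 iterations toward an acceptance rate of about 0.3, then frozen; the
#' retained post-burn-in chain is a valid Metropolis sample. The initial
#' point is drawn uniformly from the prior support under the given seed.
#'
#' @param data A data.frame with numeric `t`, `y` columns (see
#'   [tpc_observations()]). At least 4 distinct temperatures are required
#'   (one per parameter); a 0-row data.frame is allowed and samples the
#'   prior.
#' @param priors A [prior_spec()] shared between any fits to be compared.
#' @param config A [fit_config()].
#' @return An object of class `tpc_fit`: list with `samples` (matrix, one
#'   column per parameter), `acceptance_rate` (per parameter, post burn-in),
#'   `scales`, `seed`, `n_obs` and `diagnostic_failure` (TRUE when overall
#'   post-burn-in acceptance fell below 1%).
#' @examples
#' cfg <- simulation_config(n_per_temp = 5, seed = 7)
#' obs <- tpc_observations(simulate_individual_dataset(cfg))
#' fit <- fit_tpc(obs, config = fit_config(n_iter = 2000, n_burn = 500, seed = 1))
#' @export
fit_tpc <- function(data, priors = prior_spec(), config = fit_config()) {
  stopifnot(is.data.frame(data), inherits(priors, "prior_spec"),
            inherits(config, "fit_config"))
  if (nrow(data) > 0L) {
    stopifnot(all(c("t", "y") %in% names(data)))
    if (length(unique(data$t)) < 4L)
      stop("need at least 4 distinct temperatures to identify 4 parameters")
  }
  b <- prior_bounds(priors)
  lo <- b$lo; hi <- b$hi
  lp_const <- -sum(log(hi - lo))
  tt <- data$t; yy <- data$y
  n <- length(tt)
  # log likelihood only; the flat-prior constant is added where needed
  ll_fun <- function(th) {
    if (any(th < lo) || any(th > hi) || th[1] <= 0 || th[4] <= 0 ||
        th[2] >= th[3]) return(-Inf)
    if (n == 0L) return(0)
    inside <- tt > th[2] & tt < th[3]
    mu <- numeric(n)
    ti <- tt[inside]
    mu[inside] <- th[1] * ti * (ti - th[2]) * sqrt(th[3] - ti)
    sum(dnorm(yy, mu, th[4], log = TRUE))
  }

  set.seed(config$seed)
  th <- runif(4, lo, hi)
  tries <- 0L
  while (!is.finite(ll_fun(th)) && tries < 1000L) {
    th <- runif(4, lo, hi)
    tries <- tries + 1L
  }
  if (!is.finite(ll_fun(th)))
    stop("could not find a starting point with finite posterior density")
  scales <- config$proposal_scales %||% (0.1 * (hi - lo))
  n_iter <- config$n_iter; n_burn <- config$n_burn
  n_keep <- n_iter - n_burn
  samples <- matrix(NA_real_, n_keep, 4,
                    dimnames = list(NULL, c("q", "t_min", "t_max", "sigma")))
  # pre-draw standard-normal increments and log-uniforms: cheap determinism
  z <- matrix(rnorm(n_iter * 4L), n_iter, 4L)
  lu <- matrix(log(runif(n_iter * 4L)), n_iter, 4L)
  # pre-drawn randomness for the occasional refresh proposal (see below)
  refresh_u <- runif(n_iter)
  refresh_draw <- matrix(runif(n_iter * 4L, rep(lo, each = n_iter),
                               rep(hi, each = n_iter)), n_iter, 4L)
  refresh_lu <- log(runif(n_iter))
  # q and sigma are positive scale parameters whose posteriors can sit many
  # orders of magnitude below their prior upper bounds; they get
  # multiplicative (log-scale) random walks with the log q' - log q
  # Hastings correction, while the thermal limits get additive walks.
  mult <- c(TRUE, FALSE, FALSE, TRUE)
  scales[mult] <- 0.5   # initial SD on the log scale
  ll_cur <- ll_fun(th)
  lp_of <- function(ll) ll   # flat prior: constant dropped in ratios
  acc_block <- numeric(4)
  acc_post <- numeric(4)
  for (i in seq_len(n_iter)) {
    if (refresh_u[i] < 0.05) {
      if (i <= n_burn && n > 0L) {
        # burn-in only: data-informed restart proposal, accepted greedily
        # uphill (burn-in transitions need not preserve the target). Thermal
        # limits come from the prior; q is the conditional least-squares
        # scale and sigma the residual RMSE, so a draw whose limits are
        # roughly right immediately reaches the dominant mode's basin -
        # the escape hatch from sharp local modes (e.g. a narrow spike
        # between adjacent temperatures with inflated sigma).
        prop <- refresh_draw[i, ]
        if (prop[2] < prop[3]) {
          inside <- tt > prop[2] & tt < prop[3]
          f <- numeric(n)
          ti <- tt[inside]
          f[inside] <- ti * (ti - prop[2]) * sqrt(prop[3] - ti)
          sf2 <- sum(f * f)
          if (sf2 > 0) {
            qhat <- sum(yy * f) / sf2
            if (qhat > 0 && qhat <= hi[1]) {
              prop[1] <- qhat
              prop[4] <- min(max(sqrt(mean((yy - qhat * f)^2)),
                                 lo[4] + 1e-9, 1e-9), hi[4])
              ll_prop <- ll_fun(prop)
              if (is.finite(ll_prop) && ll_prop > ll_cur) {
                th <- prop
                ll_cur <- ll_prop
              }
            }
          }
        }
      } else {
        # sampling phase: independence proposal from the uniform prior; its
        # proposal density is constant on the support, so the Hastings
        # ratio reduces to the posterior ratio and the kernel stays exact
        prop <- refresh_draw[i, ]
        ll_prop <- ll_fun(prop)
        if (is.finite(ll_prop) && refresh_lu[i] < ll_prop - ll_cur) {
          th <- prop
          ll_cur <- ll_prop
        }
      }
    }
    for (j in 1:4) {
      prop <- th
      if (mult[j]) {
        prop[j] <- th[j] * exp(scales[j] * z[i, j])
        hastings <- log(prop[j]) - log(th[j])
      } else {
        prop[j] <- th[j] + scales[j] * z[i, j]
        hastings <- 0
      }
      ll_prop <- ll_fun(prop)
      if (is.finite(ll_prop) && lu[i, j] < ll_prop - ll_cur + hastings) {
        th <- prop
        ll_cur <- ll_prop
        acc_block[j] <- acc_block[j] + 1
        if (i > n_burn) acc_post[j] <- acc_post[j] + 1
      }
    }
    if (i <= n_burn && i %% 50L == 0L) {
      rate <- acc_block / 50
      cap <- ifelse(mult, 20, hi - lo)
      scales <- pmin(pmax(scales * exp(rate - 0.3), 1e-12 * cap), cap)
      acc_block[] <- 0
    }
    if (i > n_burn) samples[i - n_burn, ] <- th
  }
  acc_rate <- acc_post / n_keep
  structure(list(samples = samples, acceptance_rate = acc_rate,
                 scales = scales, seed = config$seed, n_obs = n,
                 priors = priors,
                 diagnostic_failure = mean(acc_rate) < 0.01),
            class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("<tpc_fit> %d retained samples, %d observation(s), seed %d\n",
              nrow(x$samples), x$n_obs, x$seed))
  cat("  acceptance:", paste(sprintf("%s=%.2f", colnames(x$samples),
                                     x$acceptance_rate), collapse = ", "), "\n")
  if (x$diagnostic_failure)
    cat("  DIAGNOSTIC FAILURE: chain degenerate (acceptance < 1%)\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted samples containing
#' `ceiling(prob * n)` of them; ties are broken by the lowest start.
#'
#' @param samples Non-empty numeric vector.
#' @param prob Coverage fraction in (0, 1).
#' @return Numeric `c(low, high)`.
#' @examples
#' hpd_interval(1:100, 0.95)
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  if (length(samples) == 0L) stop("no samples")
  stopifnot(prob > 0, prob < 1)
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1L], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  k <- which.min(widths) # which.min returns the first (lowest-start) minimum
  c(s[k], s[k + m - 1L])
}

#' Summarise a TPC posterior
#'
#' Per-parameter medians and 95% HPD intervals, plus the derived peak
#' temperature `t_pk` and peak rate computed sample-by-sample (so their
#' intervals propagate the joint posterior).
#'
#' @param fit A `tpc_fit`.
#' @param prob HPD coverage (default 0.95).
#' @return An object of class `tpc_summary`: `params` data.frame
#'   (`parameter`, `median`, `hpd_low`, `hpd_high`) over
#'   `q, t_min, t_max, sigma, t_pk, peak_rate`, plus `prob` and
#'   `diagnostics`.
#' @export
summarize_tpc <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "tpc_fit"))
  sm <- fit$samples
  tpk <- derived_tpk(sm[, "t_min"], sm[, "t_max"])
  peak <- sm[, "q"] * tpk * (tpk - sm[, "t_min"]) * sqrt(sm[, "t_max"] - tpk)
  all <- cbind(sm, t_pk = tpk, peak_rate = peak)
  params <- data.frame(
    parameter = colnames(all),
    median = apply(all, 2, median),
    hpd_low = apply(all, 2, function(s) hpd_interval(s, prob)[1L]),
    hpd_high = apply(all, 2, function(s) hpd_interval(s, prob)[2L]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(params = params, prob = prob,
                 diagnostics = list(acceptance_rate = mean(fit$acceptance_rate),
                                    n_samples = nrow(sm), seed = fit$seed,
                                    diagnostic_failure = fit$diagnostic_failure)),
            class = "tpc_summary")
}

#' @export
print.tpc_summary <- function(x, ...) {
  cat(sprintf("<tpc_summary> %d samples, %.0f%% HPD\n",
              x$diagnostics$n_samples, 100 * x$prob))
  print(x$params, digits = 4)
  invisible(x)
}

#' Serialize / restore a posterior summary
#' @param summary A `tpc_summary`.
#' @param path Optional file path; `NULL` returns the JSON string.
#' @return JSON text or `path` invisibly; [summary_from_json()] restores the
#'   `tpc_summary`.
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "tpc_summary"))
  doc <- list(params = summary$params, prob = summary$prob,
              diagnostics = summary$diagnostics)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                          pretty = TRUE, dataframe = "rows")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname summary_to_json
#' @param json JSON text or a file path produced by [summary_to_json()].
#' @export
summary_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  structure(list(params = doc$params, prob = doc$prob,
                 diagnostics = as.list(doc$diagnostics)),
            class = "tpc_summary")
}

#' Compare individual-level and aggregated fits
#'
#' For each parameter and derived quantity, reports the posterior median
#' difference (aggregated minus individual) and the HPD width ratio
#' (aggregated over individual): a width ratio above 1 means the aggregated
#' fit is less certain, i.e. information was lost in averaging.
#'
#' @param fit_individual,fit_aggregated `tpc_summary` objects obtained with
#'   the same priors on the same trait.
#' @return An object of class `tpc_comparison`: data.frame `table` with
#'   `parameter`, `median_individual`, `median_aggregated`, `median_diff`,
#'   `width_individual`, `width_aggregated`, `width_ratio`.
#' @export
compare_fits <- function(fit_individual, fit_aggregated) {
  stopifnot(inherits(fit_individual, "tpc_summary"),
            inherits(fit_aggregated, "tpc_summary"))
  pi_ <- fit_individual$params
  pa <- fit_aggregated$params
  stopifnot(identical(pi_$parameter, pa$parameter))
  wi <- pi_$hpd_high - pi_$hpd_low
  wa <- pa$hpd_high - pa$hpd_low
  tab <- data.frame(parameter = pi_$parameter,
                    median_individual = pi_$median,
                    median_aggregated = pa$median,
                    median_diff = pa$median - pi_$median,
                    width_individual = wi, width_aggregated = wa,
                    width_ratio = wa / wi, stringsAsFactors = FALSE)
  structure(list(table = tab, prob = fit_individual$prob),
            class = "tpc_comparison")
}

#' Render a fit comparison
#' @param comparison A `tpc_comparison`.
#' @param format `"text"` or `"json"`.
#' @return A character string; JSON round-trips losslessly through
#'   [comparison_from_json()].
#' @export
render_comparison <- function(comparison, format = c("text", "json")) {
  stopifnot(inherits(comparison, "tpc_comparison"))
  format <- match.arg(format)
  if (format == "json")
    return(as.character(jsonlite::toJSON(
      list(prob = comparison$prob, table = comparison$table),
      auto_unbox = TRUE, digits = I(17), pretty = TRUE, dataframe = "rows")))
  tab <- comparison$table
  lines <- c(sprintf("TPC fit comparison (aggregated vs individual, %.0f%% HPD)",
                     100 * comparison$prob),
             sprintf("%-10s %14s %14s %12s %12s", "parameter", "median(ind)",
                     "median(agg)", "diff", "width ratio"),
             vapply(seq_len(nrow(tab)), function(i)
               sprintf("%-10s %14.6g %14.6g %12.4g %12.4g", tab$parameter[i],
                       tab$median_individual[i], tab$median_aggregated[i],
                       tab$median_diff[i], tab$width_ratio[i]), ""))
  paste(lines, collapse = "\n")
}

#' @rdname render_comparison
#' @param json JSON produced by `render_comparison(..., format = "json")`.
#' @export
comparison_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  structure(list(table = doc$table, prob = doc$prob),
            class = "tpc_comparison")
}

#' @export
print.tpc_comparison <- function(x, ...) {
  cat(render_comparison(x, "text"), "\n")
  invisible(x)
}

#' Plot a fitted TPC with its credible band
#'
#' Draws the posterior-median Briere-1 curve, a pointwise 95% credible band
#' for the central response, and the observations.
#'
#' @param fit A `tpc_fit`.
#' @param data Optional data.frame with `t`, `y` to overlay.
#' @param n_grid Temperature grid resolution.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the grid and band matrix.
#' @export
plot_tpc_fit <- function(fit, data = NULL, n_grid = 200L, ...) {
  stopifnot(inherits(fit, "tpc_fit"))
  sm <- fit$samples
  tr <- range(sm[, "t_min"], sm[, "t_max"])
  if (!is.null(data)) tr <- range(tr, data$t)
  grid <- seq(tr[1], tr[2], length.out = n_grid)
  idx <- seq(1L, nrow(sm), length.out = min(500L, nrow(sm)))
  curves <- vapply(idx, function(i)
    briere(grid, sm[i, "q"], sm[i, "t_min"], sm[i, "t_max"]),
    numeric(n_grid))
  band <- t(apply(curves, 1, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  ylim <- range(band, if (!is.null(data)) data$y else 0)
  graphics::plot(grid, band[, 2], type = "n", xlab = "temperature (Degrees celsius)",
                 ylab = "trait value", ylim = ylim, ...)
  graphics::polygon(c(grid, rev(grid)), c(band[, 1], rev(band[, 3])),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(grid, band[, 2], col = "steelblue4", lwd = 2)
  if (!is.null(data)) graphics::points(data$t, data$y, pch = 16,
                                       col = grDevices::adjustcolor("black", 0.5))
  invisible(list(grid = grid, band = band))
}
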