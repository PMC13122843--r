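---
title: "Methods: an executable minimum information standard for vector trait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an executable minimum information standard for vector trait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirevtd)
```

## What the package formalizes

A minimum information standard is a checklist, not a file format: it says
*what* must accompany a vector trait measurement for someone else to reuse
it — the organism (and pathogen, in transmission studies), a precise trait
description with the value and its unit in separate machine-readable fields,
and the axes of variation along which the trait was deliberately measured —
without prescribing field names. This package fixes one canonical snake_case
data standard implementing that checklist, so the checklist becomes testable:
`default_mirevtd_schema()` is the field registry, `validate_dataset()` is the
checklist evaluation, and an `alias_map` at read time binds other naming
conventions (e.g. database-style CamelCase headers) onto the canonical
fields. Nothing in the schema enforces taxonomic or trait ontologies; the
validator checks interpretability, not scientific correctness.

## The rule registry and its severities

The standard's wording mixes hard requirements ("must") with advice
("should", "prefer"). The engine encodes that split as two fixed severities:

* **ERROR** — the violation destroys machine reusability: a required
  descriptor is empty; a trait value is present without a unit, or is not a
  bare number (`"45 days"`); a declared-numeric axis cell fails to parse; a
  date is unparseable; a proportion lacks its numerator/denominator counts;
  latitude/longitude are out of range; citation or submitter metadata are
  missing; an aggregated value lacks its sample size or variability metric;
  a transmission study lacks pathogen taxonomy.
* **WARNING** — heuristic or stylistic findings a human should review:
  recognizable non-ISO dates (`03/01/2022` is interpretable but ambiguous,
  unlike `"yesterday"`, which is an ERROR); non-ASCII characters;
  abbreviation-like tokens; exact duplicate identifier/axis combinations
  (repeat measures across axis levels are legitimate); a field study without
  coordinates; and the blanket reminder that aggregated data are less
  reusable.

A dataset is *compliant* iff it has zero ERRORs. Abbreviation detection is
a deliberately modest heuristic (a short blacklist plus "at most three
letters ending in a period") and can therefore never be more than a
WARNING — the absence of abbreviations is not machine-provable. Two rules
from the standard's guidance are *not* implemented: single-natural-language
detection (no reliable desk-scale language detector exists, so guessing
would produce noise) and any unit ontology. Conditional rules are triggered
by explicit metadata tags (`transmission_study`, `field_study`,
`aggregated_data`, `proportion_trait`) because the trigger conditions are
not machine-decidable from the cells alone.

Missing values: the empty string is the canonical missing cell, and the
sentinel `"NA"` — ubiquitous in ecology exports — is treated as missing too.
Both trip the required-field rule. The CSV dialect is fixed: UTF-8, comma
separator, RFC 4180 quoting (only when a cell contains a comma, quote or
newline), header row first. Field names and text cells are capped at 255
characters, matching common database column restrictions.

## The thermal performance model

The demonstration trait is juvenile development rate (d⁻¹) of *Aedes
aegypti* across temperature. The curve is **Brière-1**,

$$ r(T) = q \, T \,(T - T_{\min}) \sqrt{T_{\max} - T}, \qquad
   T_{\min} < T < T_{\max}, $$

and exactly zero at and outside the thermal limits. Brière-1 is the standard
asymmetric unimodal form for arthropod development rate and is parameterized
directly in the quantities of epidemiological interest: the thermal limits
\(T_{\min}, T_{\max}\) (°C) and, derived in closed form,

$$ T_{pk} = \frac{4T_{\max} + 3T_{\min} +
   \sqrt{16T_{\max}^2 + 9T_{\min}^2 - 16T_{\min}T_{\max}}}{10}, $$

the temperature of peak performance (independent of the scale constant
\(q\); it reduces to \(0.8\,T_{\max}\) when \(T_{\min}=0\), and the unit
tests verify it against numerical maximization). Observations are modelled
as Gaussian around the curve with a single noise SD \(\sigma\) in trait
units.

### Priors

All four parameters get independent uniform priors, deliberately weak for a
development-rate problem whose trait scale is about 0.1 d⁻¹:

| parameter | default support | units |
|---|---|---|
| \(q\) | (0, 1] | d⁻¹ · °C⁻³ᐟ² scale constant |
| \(T_{\min}\) | [−10, 25] | °C |
| \(T_{\max}\) | [25, 50] | °C |
| \(\sigma\) | (0, 1] | trait units (≈ 10 × trait scale) |

The joint support additionally imposes \(T_{\min} < T_{\max}\). The bounds
are configurable through `prior_spec()`, and — critically for the
aggregation comparison — the *same* prior object is shared by both fits, so
any difference between posteriors is attributable to the data alone.

### Sampler

`fit_tpc()` runs a single-chain component-wise random-walk Metropolis.
Numerical choices, in order of how much they matter:

* **Proposal geometry.** \(q\) and \(\sigma\) are positive scale parameters
  whose posteriors can sit several orders of magnitude below their prior
  upper bounds, so they get multiplicative proposals (Gaussian steps on the
  log scale, with the \(\log q' - \log q\) Hastings correction); the thermal
  limits get additive Gaussian steps.
* **Adaptation.** During burn-in each parameter's proposal scale is
  multiplied by \(\exp(\hat a - 0.3)\) every 50 iterations, where
  \(\hat a\) is that block's acceptance rate, steering acceptance into the
  0.25–0.40 band; scales are frozen at the end of burn-in, so the retained
  chain is a fixed, valid Metropolis kernel.
* **Mode escape.** The Brière posterior can carry sharp local modes — e.g. a
  narrow spike squeezed between two adjacent observed temperatures with an
  inflated \(\sigma\) absorbing everything else — that trap a random walk.
  With 5 % probability per iteration the sampler attempts a refresh
  proposal. During burn-in this refresh is data-informed and greedy: thermal
  limits drawn from the prior, \(q\) set to its conditional least-squares
  value and \(\sigma\) to the residual RMSE, accepted only uphill (burn-in
  transitions need not preserve the target). In the sampling phase the
  refresh is an independence proposal from the uniform prior, whose constant
  proposal density makes the Hastings ratio collapse to the posterior ratio
  — an exact kernel.
* **Initialization and determinism.** The initial point is drawn uniformly
  from the prior support under the configured seed; every random quantity is
  pre-drawn from that seed, so identical inputs give byte-identical chains.
  A zero-row dataset is accepted and samples the prior (used by the
  prior-recovery test).
* **Diagnostics.** The fit records per-parameter post-burn-in acceptance
  rates and flags `diagnostic_failure` when mean acceptance falls below 1 %.

Defaults are 20 000 iterations with 5 000 burn-in, which on the generator's
study conditions (below) give HPD coverage at the nominal rate; the
information-loss replication uses 8 000/2 500 per fit, which is sufficient
for interval *widths*. These problem sizes are stated here as the package's
reference configuration; both are plain arguments.

95 % intervals are **highest posterior density** intervals: the shortest
contiguous window containing ⌈0.95 n⌉ sorted samples, ties broken toward
the lowest start, cross-checked in the tests against a brute-force scan over
every window. \(T_{pk}\) and the peak rate are computed sample-by-sample so
their intervals propagate the joint posterior.

## The synthetic generator: what it emulates and what it does not

`simulate_individual_dataset()` emulates a laboratory thermal-gradient assay:
by default 8 rearing temperatures (12–36 °C), 20 individuals per
temperature, Brière-1 truth \(q = 6\times10^{-5}\), \(T_{\min} = 10\),
\(T_{\max} = 38\) (peak rate ≈ 0.104 d⁻¹ at \(T_{pk} ≈ 31.6\) °C — a
realistic magnitude for mosquito juvenile development), and additive
Gaussian noise with SD 0.015, about 15 % of the peak — moderate noise for
this kind of assay. An optional resource axis scales the rate
proportionally with resource level, mimicking two-stressor designs
(temperature × initial resource concentration). Lifespan datasets are
generated as whole-day counts from the reciprocal rate — an approximation
adequate for exercising the data standard, not a demographic model.

Two deliberate artifacts to keep in mind when generalizing from passing
tests to real data:

* the noise is additive Gaussian on the rate scale with a positivity floor
  at \(10^{-6}\), exactly matching the fitting likelihood; real development
  rates are heteroskedastic and right-skewed, so real-data fits inherit
  model misspecification the tests do not probe;
* near the cold end (where the mean rate is small relative to the noise SD)
  the floor truncates the noise distribution, so per-temperature means are
  slightly biased upward there — visible, and intentional: real assays
  cannot observe negative rates either.

`perturb_for_fixture()` plants exactly one named rule violation in a
compliant dataset (using the standard's own printed example vocabulary, e.g.
`"percent mortality"`, `"Culex spp."`), giving the validator a pairwise
pass/fail fixture per rule; the tests assert that each ERROR fixture
triggers its target rule and no other ERROR.

## Aggregation and the information-loss demonstration

`aggregate_by_axis()` collapses individuals to one group per distinct axis
value, reporting mean, standard error of the mean (sample SD with the n−1
denominator over √n; undefined — never silently zero — for n = 1) and n.
SE is the canonical variability metric because it is the one the standard
names as its example; the `variability_metric` field is free text so other
metrics can be recorded. Grouping compares parsed numeric values exactly;
fuzzy binning of axis values is out of scope. The reverse direction is
deliberately absent: group summaries cannot be disaggregated.

The demonstration fits the same model with the same priors to (a) the
individuals and (b) the per-temperature means treated as plain observations
— no SE weighting, because that is precisely how "single-point averages" are
(mis)used when only averages were published. Across seeded replicates of the
default design, the 95 % HPD for \(T_{\max}\) from the aggregated fit is
wider than from the individual fit in well over 80 % of replicates (median
width ratio ≈ 1.9). Mechanically: 8 means give the fit only 8 residuals to
estimate \(\sigma\) and pin four parameters, while 160 individuals both
anchor \(\sigma\) and expose the spread the means hide. A modeller could
compensate only by importing strongly informative priors on the thermal
limits — outside information standing in for what averaging destroyed.

## Design decisions that were genuinely open

* **Canonical field names.** The standard prescribes none; one fixed
  snake_case naming with read-time aliasing was chosen over free-form
  schemas so that two compliant datasets are column-compatible by
  construction.
* **Severity policy.** The must/should language maps to ERROR/WARNING; a
  checklist with uniform severity would either block harmless stylistic
  issues or wave through unusable files.
* **Required-field rule scope.** Fields covered by a dedicated rule
  (trait units; the conditional pathogen, location, aggregation and
  proportion blocks) are excluded from the generic required-field rule so
  each violation surfaces under exactly one ERROR code.
* **Dates.** Stricter than the standard's "preferably ISO 8601": recognized
  non-ISO forms warn, unparseable ones error — interpretable-but-ambiguous
  versus unusable.
* **Sex and life stage** are free text, with `"unknown"` and `"mixed"`
  valid, since the standard's own examples use them and no closed vocabulary
  is specified.
* **TPC family.** Brière-1, the standard insect development-rate form whose
  parameter set matches the quantities of interest
  (\(T_{\min}, T_{\max}, T_{pk}\)); alternative families and hierarchical
  extensions are out of scope.
* **Sampler.** A dependency-free adaptive Metropolis rather than a gradient
  sampler: the problem is 4-dimensional and desk-scale, and the sampler's
  correctness is itself verified against quadrature and prior recovery in
  the test suite.
* **Row indices** in reports are 1-based data-row numbers (header excluded),
  the R convention.

## Known limitations

* The validator checks interpretability, not data quality: a wrong but
  well-formatted value passes.
* Language mixing and unit vocabulary are unchecked (see above).
* The Gaussian likelihood ignores the positivity of rates; for traits
  measured near zero a truncated or log-scale model would be more faithful.
* Aggregated fits treat means as homoskedastic plain observations by
  design; SE-weighted fitting is a different (and better) analysis that the
  comparison intentionally does not perform.
* Single-chain MCMC: convergence is attested by acceptance diagnostics,
  determinism, and the quadrature/prior/coverage checks in the tests, not by
  multi-chain R-hat.
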