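# mirevtd

An executable implementation of **MIReVTD**, the Minimum Information standard
for Reporting Vector Trait Data. Trait measurements on disease vectors —
development rates, lifespans, fecundity, vector competence, measured across
temperature and other gradients — are the raw material for mechanistic models
of vector-borne disease risk, but they are only reusable when every dataset
reports the same minimum descriptors in a machine-readable form. This package
turns that reporting checklist into running code for the people on both ends
of the exchange: experimentalists who want to check a dataset before
depositing it, and modellers who want to ingest, harmonize and refit data
from many sources.

It provides:

* a **machine-readable schema** of the standard's minimum descriptors —
  organism (vector taxonomy, identifier, life stage, sex, conditional
  pathogen block), trait description (name, numeric value, separate unit,
  conditional numerator/denominator, sample size and variability for
  summaries), and axes of variation as `(name, value, unit)` column triples —
  extensible with further axes and interactor blocks, serializable to JSON;
* strict **CSV I/O** (UTF-8, RFC 4180, header-bound columns, verbatim cells,
  exact write-read round trips) with alias maps for foreign headers;
* a **validation rule engine** with 18 registered rules (severity ERROR for
  violations that destroy machine reusability, WARNING for heuristic or
  stylistic findings), rendering reports as text or stable JSON for CI;
* **aggregation tools** that move between individual-level and group-mean
  representations (mean, SE with the n−1 denominator, n) and classify a
  dataset's aggregation status;
* **Bayesian thermal-performance-curve fitting**: the Brière-1 model
  `r(T) = q·T·(T−T_min)·√(T_max−T)` on `T_min < T < T_max` (else 0) with a
  Gaussian observation model and independent uniform priors, sampled by
  component-wise adaptive random-walk Metropolis; posterior medians and 95 %
  highest-posterior-density intervals for `q`, `T_min`, `T_max`, `σ` and the
  derived peak temperature `T_pk` and peak rate;
* a **synthetic-data generator** with known ground truth (emulating an
  *Aedes aegypti* juvenile development-rate assay across a temperature
  gradient, optionally crossed with a resource gradient) plus perturbation
  fixtures that plant exactly one rule violation each;
* a **command line** (`exec/mirevtd`) with `validate`, `simulate`,
  `aggregate`, `fit` and `compare` subcommands and CI-friendly exit codes.

The scientific point the package demonstrates: **aggregation is irreversible
information loss for mechanistic inference.** Fitting the same TPC with the
same priors to per-temperature means instead of the underlying individuals
systematically widens the posterior intervals on the thermal limits — which
is why the standard mandates reporting the least-aggregated data available.

## Worked example

```r
library(mirevtd)

# a compliant individual-level dataset: 8 temperatures x 20 mosquitoes,
# true thermal limits 10 and 38 C, noise SD 0.015 per day
d <- simulate_individual_dataset(simulation_config(seed = 42))
d
#> <trait_dataset> 'synthetic development_rate (seed 42)': 160 rows x 19 fields (mirevtd-1.0)

# plant a classic violation: a value cell carrying its unit
rep <- validate_dataset(perturb_for_fixture(d, "UNITS_NOT_SEPARATED"))
cat(render_report(rep, "text"))
#> Status: NOT COMPLIANT (1 error(s), 0 warning(s))
#> ERRORS:
#>   [UNITS_NOT_SEPARATED] trait_value '0.0279069648067736 days' in row 1 is not
#>   a bare number; units belong in their own field
#>   <Box 1: numerical data should be separated from its units into different fields>

# the information cost of aggregation: same model, same priors, individuals
# versus per-temperature means
fit_i <- fit_tpc(tpc_observations(d), config = fit_config(seed = 1))
g     <- aggregate_by_axis(d)
fit_a <- fit_tpc(data.frame(t = g$axis_value, y = g$mean),
                 config = fit_config(seed = 2))
compare_fits(summarize_tpc(fit_i), summarize_tpc(fit_a))
#> TPC fit comparison (aggregated vs individual, 95% HPD)
#> parameter     median(ind)    median(agg)         diff  width ratio
#> q              5.8133e-05    5.79783e-05   -1.547e-07         1.61
#> t_min             9.31086        9.32515      0.01429        1.647
#> t_max             37.8524        37.8688      0.01633        1.787
#> sigma           0.0141874     0.00440084    -0.009787        2.342
#> t_pk              31.3784        31.3941      0.01568        1.782
#> peak_rate        0.102328       0.102293   -3.464e-05        1.682
```

Both fits recover the generating curve (true `t_min` 10, `t_max` 38, peak
rate ≈ 0.104 d⁻¹), but every 95 % HPD interval from the aggregated fit is
1.6–2.3 times wider: the eight means simply carry less information about
where the curve hits zero than the 160 individuals they replaced.

The same pipeline from a shell:

```sh
exec/mirevtd simulate --out traits.csv --seed 42
exec/mirevtd validate traits.csv --format json     # exit 0 iff compliant
exec/mirevtd aggregate traits.csv --out means.csv
exec/mirevtd fit traits.csv --out fit_i.json --seed 1
exec/mirevtd fit means.csv  --out fit_a.json --seed 2
exec/mirevtd compare fit_i.json fit_a.json
```

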