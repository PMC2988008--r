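# temrel

Technical error of measurement (TEM) and observer reliability for
repeated anthropometric measurements.

Anthropometric data — height, weight, mid-upper arm circumference
(MUAC), skinfolds, waist circumference — underpin nutritional
surveillance, yet they are only as good as the observers taking them.
`temrel` is for study teams running observer-reliability sub-studies
(a panel of subjects, each measured by every observer on repeated
occasions) who need to know whether their measurements are precise
enough to use, which observers or variables are the problem, and how
much of a longitudinal change could be nothing but measurement error.

## The statistics

All estimators act on one session value per (subject, observer,
session, variable), replicate readings having been averaged.

* Paired-difference TEM (same observer, two occasions — or two
  observers): `TEM = sqrt(Σ D² / 2N)`, with `D` the within-subject
  difference.
* K-observer TEM (one determination per observer):
  `TEM = sqrt( Σᵢ (Σₖ M² − (Σₖ M)²/K) / (N(K−1)) )` — the root mean
  within-subject variance across observers; for K = 2 it equals the
  paired form.
* Relative TEM: `%TEM = 100·TEM/mean`.
* Reliability coefficient: `R = 1 − TEM²/SD²` (equivalently
  `1 − (%TEM/(100·CV))²`), clamped to [0, 1] for reporting with the raw
  value preserved.
* Total TEM: `sqrt( mean(TEM²intra) + TEM²inter )`, pooling both error
  sources.
* 95% imprecision band: `1.96·sqrt(TEM² + TEM²)`; divided by a
  hypothesized gain it gives the share of a longitudinal change
  attributable to measurement error.

Verdicts follow the field standards: absolute TEM ≤ 0.1 kg (weight),
0.3 cm (height), 0.2 cm (limb girth); %TEM ≤ 5% (skinfolds) or 1%
(otherwise); R > 0.95.

## Worked example

Simulate a study with the default design — 12 subjects, 3 observers,
2 sessions on consecutive days, 5 variables with triplicate skinfolds —
and estimate reliability for MUAC:

```r
library(temrel)
ds <- simulate_reliability_study(synthetic_config(), seed = 7)

inter_observer_table(ds, "muac")
#> # A tibble: 2 × 11
#>   session n_subjects k_observers  mean    sd     cv    tem percent_tem  r_raw
#>     <int>      <int>       <int> <dbl> <dbl>  <dbl>  <dbl>       <dbl>  <dbl>
#> 1       1         12           3 31.26 6.279 0.2009 0.3612       1.156 0.9967
#> 2       2         12           3 31.20 6.341 0.2032 0.3349       1.073 0.9972

intra_observer_table(ds, "muac")
#> # A tibble: 3 × 11
#>   observer n_subjects k_observers  mean    sd     cv    tem percent_tem  r_raw
#>   <chr>         <int>       <int> <dbl> <dbl>  <dbl>  <dbl>       <dbl>  <dbl>
#> 1 O1               12           1 31.06 6.348 0.2044 0.2046      0.6586 0.9990
#> 2 O2               12           1 31.41 6.300 0.2006 0.2777      0.8842 0.9981
#> 3 O3               12           1 31.22 6.290 0.2015 0.2388      0.7648 0.9986
```

Each observer repeats MUAC to about 0.2–0.3 cm (intra TEM); observers
disagree with each other slightly more (inter TEM ≈ 0.34–0.36 cm,
because each carries a fixed personal bias), yet with this
heterogeneous panel (CV ≈ 0.20) reliability stays above 0.99.

How much of a 2.8 kg six-month weight gain would a 0.51 kg TEM eat?

```r
change_attribution(0.51, gain = 2.8)
#> # A tibble: 1 × 6
#>   variable scenario   tem  gain ci_halfwidth percent_of_gain
#>   <chr>    <chr>    <dbl> <dbl>        <dbl>           <dbl>
#> 1 <NA>     <NA>      0.51   2.8        1.414           50.49
```

Half the expected gain sits inside the 95% imprecision band.

Because the data were simulated, the generator's error settings can be
compared against what the estimators recover:

```r
recovery_report(ds, variables = "muac")
#> # A tibble: 5 × 6
#>   variable component estimate target nominal relative_error
#>   <chr>    <chr>        <dbl>  <dbl>   <dbl>          <dbl>
#> 1 muac     intra:O1    0.2046 0.3     0.3           0.3182
#> 2 muac     intra:O2    0.2777 0.3     0.3           0.07430
#> 3 muac     intra:O3    0.2388 0.3     0.3           0.2041
#> 4 muac     inter:s1    0.3612 0.3779  0.5831        0.04414
#> 5 muac     inter:s2    0.3349 0.3779  0.5831        0.1137
```

With only 12 subjects the estimates are noisy, as expected; the test
suite demonstrates convergence at larger panels.

The one-shot driver `run_analyze()` ingests long-format CSVs (one or
several study occasions), writes the four reliability tables as TSV
(`table1_inter.tsv` … `table4_attribution.tsv`), a versioned
machine-readable `report.json` and a log of per-cell n. A thin CLI with
`analyze`, `simulate` and `attribution` subcommands is installed under
`inst/cli/temrel`. The bundled `reference_study_summary()` carries the
published summary statistics of a two-occasion, three-observer field
study used throughout the examples and checks.

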