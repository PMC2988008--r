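---
title: "Quantifying observer error in repeated anthropometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying observer error in repeated anthropometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temrel)
```

## The problem

Anthropometric measurements — height, weight, circumferences, skinfolds —
are cheap and non-invasive, which makes them attractive for nutritional
surveillance in large cohorts. They are also vulnerable to observer
error, especially when several newly trained observers share the
measuring. Unreliability has two components: *imprecision*, the error
variance contributed by intra- and inter-observer variability, and
*undependability*, true physiological day-to-day variation. `temrel`
quantifies the first: it answers "how much of what I measure, and how
much of a change I observe over time, is measurement noise?"

The reference design the package is built around is a two-occasion
reliability sub-study embedded in a longitudinal cohort: on each
occasion, about a dozen heterogeneous adult volunteers are each measured
by every observer (here three), once per day on two consecutive days.
Skinfolds are read in triplicate within a session and averaged.

## Estimators

All estimators act on *session values*: one value per (subject,
observer, session, variable), the mean of that cell's replicates.

**Paired-difference TEM** (`intra_pair_tem()`). For duplicate
determinations — one observer on two days, or two observers once each —

$$TEM = \sqrt{\frac{\sum_i D_i^2}{2N}},$$

with $D_i$ the difference between subject $i$'s two measurements. Used
per observer across the two sessions, it is the intra-observer TEM.
Note that it cannot separate reading noise from genuine day-to-day
change: a session effect inflates it by construction (see the generator
section).

**K-observer TEM** (`multi_observer_tem()`). With one determination per
observer within a session,

$$TEM = \sqrt{\frac{\sum_i\left(\sum_k M_{ik}^2 - (\sum_k M_{ik})^2/K\right)}{N(K-1)}},$$

the root of the average within-subject sample variance across the $K$
observers. With $K = 2$ this reduces algebraically to the
paired-difference form — a property the test suite verifies on random
instances. Internally the within-subject sum of squares is computed in
its row-centred form, which is algebraically identical but does not lose
precision to cancellation when observers agree to many digits.

**Relative TEM** (`percent_tem()`): $\%TEM = 100 \cdot TEM / \bar{x}$,
for comparison across variables and units.

**Reliability coefficient** (`reliability_coefficient()`):
$R = 1 - TEM^2 / SD^2$, the proportion of between-subject variance free
of measurement error. Because the mean cancels, $R$ is equally
computable from the relative quantities, $R = 1 - (\%TEM/(100\,CV))^2$;
both entry points are provided and agree. $R$ can be negative when the
error variance exceeds the between-subject variance; the raw value is
preserved (`r_raw`) and a value clamped to $[0,1]$ is reported (`r`),
matching the field convention of printing 0.00 for such cells.

**Total TEM** (`total_tem()`): the pooled imprecision
$\sqrt{\overline{TEM_{intra}^2} + TEM_{inter}^2}$ — the mean of the
squared per-observer intra-observer TEMs plus the squared
inter-observer TEM, square-rooted. Written for a three-observer panel,
it generalizes to any panel size.

**95% imprecision band** (`ci95_halfwidth()`):
$1.96\sqrt{TEM_a^2 + TEM_b^2}$; with a single estimate the two error
terms are taken equal, giving $1.96\sqrt{2}\,TEM \approx 2.772\,TEM$.
`change_attribution()` divides this band by a hypothesized longitudinal
gain to express imprecision as a share of the change one hopes to
detect.

### Definitional choices the formulas leave open

The classical presentation of these estimators does not pin down two
quantities, and the package fixes them as follows:

* **SD entering R** is the between-subject sample SD (denominator
  $n-1$) of the per-subject means of exactly the measurements entering
  the TEM estimate. Per-subject means isolate the between-subject
  variance that R is meant to reference, and this choice reproduces the
  reference study's published R values within printed rounding.
* **mean entering %TEM** is the grand mean of all measurements entering
  the TEM estimate — the only reading consistent with a single "mean"
  in the %TEM formula.
* **No rounding inside computations.** Rounding happens only in the
  reporting layer (`reporting_precision()`: TEM/R/CV to 2 decimals,
  %TEM to 3 significant figures, all configurable).

## The analysis pipeline

`inter_observer_table()` estimates one K-observer TEM per session;
`intra_observer_table()` one paired-difference TEM per observer (first
two sessions). Both use per-variable listwise deletion: a subject
enters an estimate only with a complete set of required cells, and the
retained n is part of every row — in field data n shifts between
variables (no-shows, refusals) and must stay visible.

`total_comparison_table()` pools the components per study occasion. The
inter-observer component is taken from the **first session** by
default. This policy was chosen by reverse-engineering the reference
study's published totals: nine of its ten derivable cells reproduce
exactly with the session-1 inter TEM (the tenth is discussed below).
`"last"` and `"pooled"` (root mean square across sessions) policies are
available. The occasion's %Total TEM uses the occasion grand mean and
its R the occasion between-subject SD, computed over complete cases.

`scenario_extremes()` picks, per error component, the best (minimum)
and worst (maximum) TEM across occasions, and recombines the selected
components into best/worst totals. Extremes are taken on components,
never on published totals — recombination is what makes the best-case
total internally consistent.

`classify_acceptability()` applies the field standards: absolute TEM at
most 0.1 kg for weight, 0.3 cm for height, 0.2 cm for limb girths
(no absolute cutoff exists for skinfolds or trunk girths); %TEM at most
5% for skinfolds and 1% otherwise; R strictly above 0.95.

## The synthetic generator

`simulate_reliability_study()` draws data from the additive model

```
reading = truth(subject) + bias(observer, variable)
          + session_effect(subject, session) + noise
```

* **Truth** is drawn once per subject, by default uniform over the
  trait ranges of a deliberately heterogeneous adult panel (height
  152–186 cm, weight 41.5–99.4 kg, MUAC 21.3–40.6 cm, triceps skinfold
  4.50–64.67 mm, waist 63–110 cm). Only ranges are published for the
  reference panel, so the uniform shape is an assumption, not an
  inference.
* **Bias** is drawn once per observer × variable and held fixed across
  subjects and sessions. This is precisely what makes inter-observer
  error exceed intra-observer error, the central contrast the
  estimators are designed to expose.
* **Session effect**, shared by all of a subject's readings within a
  session, models physiological day-to-day variation. Its default is 0
  so that the intra-observer TEM cleanly recovers the reading-noise SD;
  switching it on demonstrates (rather than "corrects") the fact that
  the paired-difference estimator conflates noise with day effects.
* **Noise** is fresh per reading. Default SDs per variable (bias/noise:
  height 0.8/0.5 cm, weight 0.4/0.4 kg, MUAC 0.5/0.3 cm, triceps
  skinfold 4/2 mm, waist 1.5/1.2 cm) were set once to the error
  magnitude typical of newly trained observers — largest, relatively,
  for the skinfold. Per-observer `bias_scale`/`noise_scale` multipliers
  let one observer be made systematically worse than the panel.
* Non-positive draws are resampled (noise redrawn), not clipped, so the
  shape of the distribution of positive-valued measures is preserved.
* Each (variable, observer) pair draws from its own RNG sub-stream
  derived from the master seed: adding an observer never changes
  another observer's data at the same seed, and a fixed seed yields a
  byte-identical CSV.
* Missingness rules drop whole subject-sessions (no-shows) or a
  variable for chosen subjects (refusals), reproducing the 12 → 11 and
  n = 7 complete-case patterns of the reference design.

### What recovery means with a finite observer panel

`recovery_report()` pairs each generator SD with its estimator. Two
subtleties:

* Replicate averaging shrinks the effective per-session-value noise to
  $\sigma_e/\sqrt{m}$ for $m$ replicates; targets account for this.
* The inter-observer TEM at fixed $K$ converges, as subjects grow, to
  $\sqrt{s_b^2 + \sigma_e^2}$ where $s_b^2$ is the **realized** sample
  variance of the $K$ drawn biases — not the nominal $\sigma_b^2$,
  which is approached only in expectation over panels. The report
  therefore exposes both the realized-panel `target` (computable
  because the truth sidecar records the biases) and the `nominal`
  value. The test suite checks single-study recovery against the
  realized target, and the nominal identity
  $E[TEM_{inter}^2] = \sigma_b^2 + \sigma_e^2$ as a root mean square
  over 400 replicate simulated panels.

Validation problem sizes were fixed in advance: single-study recovery
uses 2000 subjects (relative error below 5%), the replicate-panel check
400 panels of 100 subjects and 3 observers, and consistency is checked
by comparing mean recovery error across ten seeds at 40 vs 800
subjects.

### What passing tests do and do not show

The generator is additive, Gaussian and homoscedastic; real
anthropometry has skewed skinfold distributions, error that grows with
the measured value, instrument drift and digit preference. Parameter
recovery on synthetic data therefore validates the estimators and the
pipeline plumbing, not the adequacy of the additive model for any
particular field dataset.

## Reproduction of the reference study, and its irreducible cells

The package bundles the published summary table of a two-occasion,
three-observer reliability study (`reference_study_summary()`); its raw
measurements were never deposited. Everything internally derivable is
recomputed by the test suite and the acceptance script: total TEMs from
printed components, best/worst scenario percentages of a hypothesized
6-month gain (2.8 kg weight, 1 cm MUAC), and R from printed CV and
%TEM. A few printed cells resist derivation and are documented rather
than forced:

* The occasion-A waist-circumference total equals its day-1
  inter-observer TEM verbatim and matches no component combination — a
  transcription defect in the source table.
* The published MUAC best/worst "total" cells match no combination of
  printed component extremes.
* The worst-case weight total percentage follows only from the rounded
  total (1.74), not from full-precision recombination (1.729).
* Six of the fifty R cells cannot be rebuilt from CV and %TEM because
  the CV is printed to two decimals (for CV ≈ 0.05–0.12 that rounding
  moves recomputed R by more than 0.01).

Comparisons elsewhere use an absolute tolerance of one unit in the last
printed decimal, since it is generally unknowable whether published
cells were computed from rounded or unrounded intermediates.

## Degenerate inputs and edge policies

* Fewer replicates in a cell than the schema declares: averaged over
  what exists, with a warning (collected into the JSON report's
  `warnings` array by `run_analyze()`, never console-only).
* A session with fewer than two complete observers, or an observer
  lacking a session: reported as an absent row with a reason, not
  dropped silently.
* Zero between-subject SD (all subjects identical): R is undefined and
  reported `NA` rather than forced.
* Datasets with more than two sessions: the intra-observer pairing uses
  the first two declared sessions.
* `complete_cases()` is idempotent and can only shrink the subject set.

## Limitations

The package deliberately implements only this estimator family: no
intraclass correlation variants, no Bland–Altman agreement analysis, no
mixed-model variance decomposition, and no comparison tests between
study populations. Those are natural extensions but different tools.
TEM-based reliability also says nothing about *accuracy* — a panel
sharing a miscalibrated instrument can be precise and wrong together;
only comparison against a reference observer or instrument detects
that.
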