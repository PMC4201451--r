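---
title: "Methods: the midpoint survival-time adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the midpoint survival-time adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(edssmidpath)
```

## 1. Model and assumptions

### 1.1 The measurement process

Disability is measured on the Expanded Disability Status Scale (EDSS), an
ordinal score on the grid $\{0\} \cup \{1.0, 1.5, \ldots, 10\}$ (0.5 is
not an admissible value). Time is measured in years since assessed
symptom onset (yso); a patient with a known onset contributes a synthetic
*onset anchor* record (EDSS 0 at yso 0), reflecting the working assumption
that relapsing-onset disease starts from a normal examination.

EDSS is recorded only at clinic visits, which occur irregularly and
independently of the disability process in our model. Consequently every
disability transition is *interval-censored*: it happened somewhere
between the last visit below the new level and the visit at which the new
level was first recorded.

### 1.2 Irreversible disability paths

A level $e \ge 1$ on the grid is **irreversible** for a patient when some
visit records EDSS $\ge e$ and no later visit records EDSS $< e$. The
attainment time $t_{\max}(e)$ is the earliest such visit. Readings later
contradicted by a strictly lower score — typically relapse-related
elevations — are *transitory* (label `Ot`) and never enter the
irreversible path. The remaining observations at path levels are labelled
`Of` (first at a level), `Om` (interior repeat), `Or` (last repeat); the
onset anchor is `Oo` and imputed measures are `Exp`.

Internally irreversibility is computed from the suffix minimum of the
EDSS sequence (`irreversible_levels()`), which is equivalent to the
definitional scan but linear in the number of visits; the test suite
verifies the equivalence against a brute-force implementation on 10,000
random trajectories.

### 1.3 The three survival-time assumptions

For each irreversible level $e$ with bracket
$(t_{\min}(e),\, t_{\max}(e)]$, where $t_{\min}(e)$ is the last visit at
which the patient was still strictly below $e$:

* **maximum** — the event is placed at $t_{\max}(e)$, the attaining
  visit. This is the conventional choice and the slowest-progression
  reading of the data.
* **minimum** — the event is placed at $t_{\min}(e)$, the fastest
  reading. We represent the time as $t_{\min}$ itself rather than
  "immediately after $t_{\min}$": introducing an $\varepsilon$ offset
  would make downstream results depend on an arbitrary constant, while
  the tie-handling conventions below make the exact-endpoint choice
  innocuous. When no record below $e$ exists and the onset is unknown,
  the minimum time falls back to $t_{\max}(e)$.
* **midpoint** — the event is placed at the expected midpoint of the
  bracket (next section).

### 1.4 Expected midpoint measures

When one visit attains a run of $k$ consecutive grid levels
$e_1 < \cdots < e_k$ at the same time $t_b$ (levels are *skipped* between
non-adjacent observed values), all $k$ levels share the bracket
$(t_a, t_b]$, where $t_a$ is the last observation strictly below $e_1$.
The run is resolved by placing the levels at the **equal-subinterval
midpoints**

$$t_j \;=\; t_a + \frac{(2j-1)\,(t_b-t_a)}{2k}, \qquad j = 1,\ldots,k,$$

i.e. the bracket is divided into $k$ equal subintervals and each level is
placed at its subinterval's midpoint. For $k = 1$ this is the ordinary
interval midpoint. The formalization keeps all imputed times strictly
inside the bracket and strictly increasing with level.

Because $t_a$ is the last observation *strictly below* the run's lowest
level — not the last observation of any kind — transitory highs can never
shrink a bracket. When the first bracket of a trajectory is undefined
(onset unknown and no visit below the first irreversible level), that
level's expected measure is skipped with a warning and the level enters
models at its maximum time; we prefer dropping one measure to inventing a
left boundary.

`augment_cohort()` merges the expected measures into the record stream as
rows with `source = "expected_midpoint"`, one per irreversible level,
without ever modifying clinical records; augmentation is idempotent, and
expected rows are regenerated (never read) by the I/O layer.

### 1.5 Rate-of-change model

Progression speed is the slope $\beta$ of the through-origin model

$$\mathrm{EDSS}_{ij} = \beta \cdot \mathrm{yso}_{ij} + \varepsilon_{ij}$$

fitted over the near-linear range EDSS $\le 6$ (levels above 6.5 accrue
much more slowly and would bend the line). The origin constraint encodes
the onset anchor: EDSS 0 at yso 0. Under the *maximum* assumption the
model is populated with the observed records only; under *midpoint* the
expected measures are added; under *minimum* each irreversible level
additionally enters at its minimum time. Transitory (`Ot`) records are
included by default — they are genuine EDSS measurements — with a switch
(`include_transitory = FALSE`) to study their leverage.

Two record populations are available. The default `"stream"` population
follows the populating contract above (observations, plus expected
measures under midpoint). The `"measures"` population instead uses one
record per irreversible level at its assumption-specific survival time —
the vertices of the irreversible path — so the survival-time assumption is
the *only* difference between analyses. The distinction matters for
assessment-rate sensitivity: a clinical observation $(t, \mathrm{EDSS}(t))$
samples the current state whenever the visit happens, so the stream
population is insensitive to visit density, whereas under the maximum
assumption each measure is recorded late by the visit-schedule residual
delay, which scales with the typical visit gap. Dispersion comparisons
across assessment eras (`variability_report()`) are therefore made on the
measures population, where sparse-era maximum estimates are biased low and
the midpoint adjustment recentres them.

Two variants are provided. The default pooled variant estimates
$\hat\beta = \sum x y / \sum x^2$ across all records; the `"fe"` variant
adds per-patient intercepts (within-patient demeaning), relaxing the
common-origin constraint at the cost of requiring repeated measures. Both
reduce to closed-form sums, which makes the patient-level cluster
bootstrap (default $B = 999$, seeded) cheap: resampling patients only
permutes per-patient sufficient statistics. `compare_assumptions()` uses
a *paired* bootstrap — the same patient resample is used for both
assumptions — so the confidence interval for
$\beta_{\text{mid}} - \beta_{\text{max}}$ reflects the correlation
between the two estimates; the comparison is flagged significant when
that interval excludes zero.

### 1.6 Survival curves

`km_suite()` fits product-limit (Kaplan–Meier) curves of time to each
irreversible level (default EDSS 1–9) under a chosen assumption. Patients
who never irreversibly attain a level are right-censored at their **last
clinical observation under every assumption**: the midpoint adjustment
moves event times only; shrinking follow-up for censored patients would
inject bias of its own. At tied times events precede censorings (the
standard convention). The median is the earliest time at which the curve
reaches 0.5 or below, `NA` when the curve never does. The onset cohort
for survival analysis requires a known onset and at least
`min_clinical_obs = 2` clinical records — the weakest filter that still
gives every patient a non-degenerate censoring window, and the same
threshold used by the assessment-rate diagnostics.

### 1.7 Censoring-size metrics

The bias of the maximum assumption grows with the distance between
$t_{\min}$ and $t_{\max}$, i.e. with sparse assessment.
`assessment_rate()` reports records per patient-year over two bases —
first-to-last clinical observation (the interval-censoring window) and
onset-to-last — counting clinical observations alone or clinical plus
expected measures. The primary rate is pooled (total records / total
person-years); the mean of per-patient rates is reported alongside.
Patients with one clinical observation have a zero-length first-to-last
window and are excluded from that basis. `censoring_partition()` splits a
patient's timeline into left- (onset to first observation), interval-
and right-censoring (last observation to horizon) windows, and
`era_report()` aggregates assessment rates by calendar era using
`onset_year` plus yso to place records in calendar time; a year-only
onset is resolved to mid-year (1 July), the midpoint of the year being the
expectation under a uniform within-year onset.

## 2. The synthetic cohort generator

`simulate_cohort()` generates natural-history-like cohorts for parameter
recovery. Per patient:

* **Latent disability** $D(t) = \min(\beta_i t, 10)$, with
  $\beta_i \sim N(\beta_{\text{true}}, \sigma_\beta^2)$ truncated at 0.
  Observed EDSS is $D(t)$ floored to the grid (values in $(0,1)$ floor
  to 0 since 0.5 does not exist).
* **Visit process**: a gamma renewal process (shape 2 by default) — more
  regular than Poisson scheduling but still irregular, matching clinics
  that recall patients at roughly fixed intervals. The first visit occurs
  a gamma-distributed delay after onset, so the mean onset-to-first-visit
  gap equals `onset_delay_mean`.
* **Follow-up**: a fixed window after onset; visits beyond it are not
  observed, giving right censoring.
* **Relapses**: a Poisson process of transient elevations; while an
  elevation is active the observed EDSS is raised by its height and
  snapped to the grid. Relapse readings later contradicted by lower
  scores are exactly the transitory (`Ot`) observations the path
  construction must exclude.

Default study conditions (fixed once, used by tests and the acceptance
script): $n = 250$ patients, $\beta_{\text{true}} = 0.17$ EDSS/year
(a typical relapsing-onset progression speed on the 0–6 range), 2-year
mean visit gap and 2-year mean onset-to-first-visit delay (sparse
assessment, so the censoring adjustment has something to correct),
20-year follow-up (enough to reach EDSS 3 for most patients), relapse
rate 0.4/year with elevations of 1–2 points lasting 0.15 years.
`simulate_era_cohort()` concatenates blocks with different visit
densities to emulate assessment-practice eras.

What the generator deliberately does **not** emulate: informative visit
scheduling (visits triggered by worsening), measurement error on the EDSS
itself, non-linear latent trajectories, secondary-progressive transitions,
or mortality. These omissions are intentional — the generator's purpose is
to give a known ground truth for the *censoring* machinery, not to be a
disease model.

## 3. Numerical design decisions

* **Grid arithmetic is exact.** All admissible EDSS values are halves,
  exactly representable in doubles, so grid membership and flooring use
  exact comparisons — no tolerances.
* **Ties.** Records are ordered patient, time, then source
  (anchor < clinical < expected) at tied times. Duplicate
  (patient, time) *observations* are rejected as input errors rather than
  merged.
* **Determinism.** Every stochastic step (simulation, bootstraps) takes
  an explicit seed; `run_pipeline()` writes no timestamps, so identical
  configuration and seed reproduce all artifacts byte for byte. Full
  double precision is used in delimited output so a write/read round trip
  is bit-exact.
* **Degenerate cases.** All-zero trajectories yield empty paths and zero
  slopes; empty brackets cannot arise (the bracket construction
  guarantees $t_a < t_b$); a curve that never crosses 0.5 has median
  `NA`, never an extrapolated value.
* **Dense-observation limit.** As the visit schedule densifies, the
  midpoint and maximum estimates converge ($\beta_{\text{mid}} -
  \beta_{\text{max}} \to 0$): with vanishing brackets there is no
  censoring left to adjust. At finite density a small positive gap
  remains, because grid flooring keeps clinical readings slightly below
  the latent line while midpoint measures sit on it; the test suite
  asserts the monotone convergence rather than exact equality.

## 4. Limitations

* The midpoint expectation is a deterministic imputation. It is not a
  full interval-censored likelihood: a Turnbull/NPMLE estimator or a
  parametric interval-censored survival model would propagate the
  within-bracket uncertainty instead of fixing it at the midpoint. The
  midpoint rule was chosen for transparency and because it can be applied
  record-wise to populate a regression model.
* The bootstrap quantifies sampling variability across patients, not the
  systematic component of within-bracket placement.
* Visit times are assumed non-informative. If deterioration triggers
  visits, $t_{\max}$ is closer to the true event than our model assumes
  and the midpoint rule over-corrects.
* The through-origin linear model is a working approximation on EDSS 0–6;
  it is not meant to extrapolate above 6.5, where the scale changes
  character.
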