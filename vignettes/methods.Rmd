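---
title: "Redlining, gentrification and socio-spatial mobility: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redlining, gentrification and socio-spatial mobility: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gentriflow)
```

# The scientific question

Neighborhoods graded "hazardous" (redlined) on the 1930s Home Owners'
Loan Corporation (HOLC) maps still show markedly lower life expectancy at
birth than neighborhoods graded "best".  But tracts do not stand still:
some historically disinvested tracts gentrify, replacing lower-income
residents with higher-income newcomers.  A cross-sectional association
between HOLC grade and life expectancy therefore mixes two things — the
legacy of the policy, and the contemporary re-sorting of people by income
across tracts.  `gentriflow` implements an analysis pipeline that
separates these: it classifies tracts by gentrification status, measures
household-level socio-spatial mobility flows directly, and asks how much
of the life-expectancy gap between gentrified and non-gentrified tracts
within a HOLC grade survives adjustment for those flows.

All computation lives in package functions; the numbered scripts under
`analysis/` run the workflow end to end on a synthetic metropolitan area
and write result tables under `results/`.

# Tract classification

**HOLC grade.** A modern tract overlapping several 1930s neighborhood
polygons takes the grade covering the largest fraction of its area
(`assign_holc_grade()`); tracts with no graded overlay are
"unclassified".  Tied fractions resolve to the *worse* grade.  The tie
break is not prescribed anywhere we could find; choosing the worse grade
is conservative toward the exposure of interest and is enumerated in the
test suite over all two-way ties.

**Gentrification status.** For each tract, a composite score per time
window sums percentage-point changes in percent college-educated,
percent short-tenured (<5 years), and percent owner-occupied housing
(`composite_score()`).  The score is described as "weighted" in the
index literature without stated weights; the default is equal weights
`c(1, 1, 1)`, exposed as an argument.  Because the gentrification
thresholds are distribution-relative (below), classifications are
invariant to rescaling all three weights — a property the tests check.

`classify_gentrification()` then assigns one of four statuses:

* **ineligible** — baseline (2011) median household income at least 40%
  above the metro average (inclusive at the boundary).  The metro
  average is the unweighted mean of tract median incomes — the simplest
  reading of "metropolitan area average"; a population-weighted variant
  would be a one-line change.
* **earlier** — eligible, and the 2000–2010 composite score is at least
  one standard deviation above the mean.
* **recent** — eligible, not earlier, and the 2011–2018 score is at
  least one standard deviation above that window's mean.
* **none** — eligible, neither window crosses its threshold.

Two readings were open.  First, the "metropolitan area's average" in the
one-standard-deviation clause is taken to be the mean of the composite
score itself (not per-attribute averages).  Second, score means and
standard deviations are computed over *eligible* tracts only: the
threshold is meant to detect transformation among candidates, and
ineligible tracts are outside the gentrification-eligible universe.  A
tract exceeding the threshold in both windows is labeled **earlier**:
the categories are mutually exclusive and "earlier" denotes process
onset.

# Socio-spatial mobility

The unit of observation is a household with an annual residence (tract,
outside the metro, or missing) and income, 2011–2018.

**Exclusion rule** (`filter_complete()`).  A household is retained iff
its residence history has no internal gap — missing years may only form
a terminal run, which encodes exit from the database — and income is
observed at its most recent observed year.  This resolves two
requirements that naturally sit in tension: demanding complete
residential histories while also coding households that drop out of the
database as out-movers in their origin tract.  Terminal missingness is treated as informative exit (kept,
coded out-mover); internal missingness as record incompleteness
(excluded).

**Income classes** (`assign_income_class()`).  Final incomes (most
recent observed year) are pooled across all retained households once;
the 25th/75th percentiles split lower / moderate / higher.  Identical
incomes degrade to all-moderate with a warning.

**Mover coding** (`classify_mobility()`).  Only first and last observed
locations matter.  Same tract at both ends: non-mover.  Two different
metro tracts: one out-move at the origin, one in-move at the
destination.  Origin in the metro but last seen outside it or absent by
2018: out-move at origin only.  Entered from outside: in-move at
destination only.  Households never observed in the metro contribute
nothing and are counted.

**Net changes and magnitude categories** (`net_changes()`,
`categorize_magnitude()`).  Per tract and income class, net = in − out,
in integer arithmetic.  Each class's net distribution is cut at its
25th/50th/75th percentiles into major decline / minor decline / minor
increase / major increase.  Type-1 (inverse-CDF) quantiles are used so
cut points are observed integers, and a tract exactly at a cut point
goes to the lower category.  A net of exactly zero is assigned *minor
decline*: the decline/increase category ranges meet at zero (−1 | +1),
so a deterministic convention is required, and zero is "no increase".

# Life-expectancy summaries

Tracts missing life expectancy or population (or with zero population)
are excluded with logged counts and one-decimal percentages
(half-up rounding, `pct_report()`).  Group summaries use the
population-weighted mean `sum(pop * LE) / sum(pop)`.  The 95% CI is a
normal approximation `mean ± 1.96 · s_w / sqrt(m)` with `s_w` the
population-weighted SD (with an `m/(m−1)` correction) and `m` the tract
count; there is no single standard CI for a population-weighted mean at
tract aggregation, so this choice is isolated in one function where a
bootstrap over tracts could be swapped in.  Input life-expectancy uncertainty (the published standard errors of
small-area estimates) is ignored — a known limitation.

# Regression battery

`fit_ols()` is ordinary least squares on a dummy-coded design built by
`build_design()` with explicit reference levels; reference rows appear
in the coefficient table with coefficient exactly 0 and an `is_ref`
marker, and 95% CIs use the t distribution with `n − p` degrees of
freedom.  Mobility models use `major_decline` as reference.  Stratified
gentrification models (`fit_stratified_ols()`) fit one model per HOLC
grade; the reference status is `ineligible` where the stratum has such
tracts and `earlier` otherwise (the two worst grades have no ineligible
tracts, matching the empirical pattern).  The adjusted variant adds the
three mobility category variables; the sensitivity variant additionally
adjusts for the 2011–2018 percentage-point change in non-White
population.  No further socio-economic covariates are admitted — the
gentrification index is itself built from education and tenure, and
adding correlated SES measures would manufacture collinearity.
Rank-deficient designs are refused with the collinear columns named;
strata too small to support the adjusted model are skipped with a
warning rather than silently under-fitting.

# The Bayesian spatial model

The unstratified spatial model is

$$y_i = x_i^\top\beta + s_i + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \tau_\varepsilon^{-1}),$$

with fixed effects for transformation status (HOLC grade crossed with
gentrification status, reference "unclassified / ineligible") and an
intrinsic conditional autoregressive (ICAR) spatial effect $s$ on the
rook-adjacency graph: a first-order Gaussian Markov random field with
precision $\tau_s (D - W)$ and a sum-to-zero constraint.  Structured additive
regression tools often smooth areal data with bivariate P-spline
surfaces instead; both are GMRF smoothers over the tract graph, and the
model's inferential outputs — a smoothed tract deviation from the
metro-average surface and a credible-interval flag — are the same in
kind, while the ICAR form keeps every full conditional conjugate.
Numerical agreement with a spline surface is not a goal and is not
claimed.

Sampling is plain Gibbs: multivariate normal updates for $\beta$ and
(via sparse Cholesky of $\tau_\varepsilon I + \tau_s(D-W)$) for $s$,
gamma updates for both precisions under inverse-gamma(0.001, 0.001)
variance priors.  After each sweep $s$ is recentred to mean zero and the
offset absorbed into the intercept, which enforces the constraint
without changing the likelihood.  Defaults are 12,000 iterations, 2,000
burn-in, thinning 5 (2,000 retained draws); convergence is monitored by
split-chain potential scale reduction on $\beta$ and the precisions, and
a precision collapsing below 1e−12 aborts with diagnostics.  A tract is
flagged **lower** / **higher** when the 95% credible interval of $s_i$
lies entirely below / above zero.  Flags are invariant to adding a
constant to all outcomes (absorbed by the intercept) — tested.

Stratified spatial models are refused by design: tracts of one HOLC
grade are typically spatially disconnected, and a disconnected subgraph
has no usable neighborhood matrix.  `fit_spatial()` raises a descriptive
error in that case; for the full metro, where excluded tracts can
occasionally split the lattice, islands are instead attached to the
nearest mainland tract by centroid distance with a warning.

# The synthetic metro generator

No real inputs ship with the package: household traces are proprietary,
and tract life expectancy, the HOLC crosswalk and census attributes are
restricted or bulky.  `generate_metro()` creates a full substitute with
known ground truth:

* **Tracts** on an `n_rows × n_cols` lattice (default 12×12) with rook
  adjacency.  HOLC grades fill concentric bands around the lattice
  center — hazardous innermost, then definitely declining, still
  desirable, best — over `holc_seed_fraction` (default 30%) of tracts,
  mirroring both the inner-city clustering of graded areas and their
  approximate composition (the hazardous band is the largest graded
  share).  This also reproduces the stratification failure mode: a
  single grade's tracts form a thin, easily disconnected region.
* **Statuses** planted by construction: ~15% of tracts ineligible
  (incomes drawn 140–200k against 35–70k for eligible tracts, so the
  1.4× rule is exact by a wide margin, and never on the two worst
  grades), and ~15% of eligible tracts per grade given earlier / recent
  attribute drift (+8 to +18 percentage points per attribute in the
  respective window) against ±2pp noise drift elsewhere.  The planted
  separation is large enough that the distribution-relative classifier
  recovers every planted label, which the tests require exactly.
* **Households** (default 100 per tract plus 10% outside entrants)
  relocate annually with income-class-specific hazards (defaults 0.10 /
  0.06 / 0.07 for lower / moderate / higher — renters move most),
  leave the database with probability 0.02 per year, and move out of the
  metro on 15% of relocations.  Destination choice is the gentrification
  engine: higher-income movers weight gentrifying and ineligible tracts
  4:1, lower-income movers weight non-gentrified tracts 4:1, and a
  lognormal per-tract attractiveness factor (sd 0.5 on the log scale)
  adds the within-status variation in flows that any real metro has —
  without it, mobility categories and gentrification status would be
  perfectly collinear within strata.  Incomes follow a multiplicative
  random walk (3% annual noise).  A `missing_prob` fraction (default
  8.7%, a realistic incomplete-record rate for commercial household
  traces) of households receives an incomplete record to exercise the
  exclusion filter.
* **Life expectancy** is additive: a 78-year baseline, per-grade offsets
  (+1.5, +1.0, 0, −2.5, −3.5 years for best → hazardous, a ~5-year
  best-to-hazardous gradient of the size reported for large U.S. metros), 2.5 years per
  10-percentage-point deviation of the tract's higher-income household
  share from the metro mean, a smoothed spatial field (sd 1.0 years),
  and iid noise (sd 0.8 years), clipped to 60–95.  All components are
  recorded in the truth object.

What the generator does *not* emulate: real tract geography and
population sizes, ACS-calibrated marginals, income dynamics beyond a
random walk, household demographic composition, multiple moves mattering
(only first/last locations are analyzed anyway), and re-entry after
leaving the metro.  Passing tests therefore demonstrate that the
*pipeline logic* is correct and that the *structural phenomena* (flow
patterns by status, attenuation, spatial flagging) are recovered where
planted — not that any real metro's estimates would be reproduced.

The household income construct is a single annual household income
scalar; commercial trace providers vary in what their income field
measures (household vs per-capita, pre- vs post-tax), and no finer
structure is modeled.

# Simulation study sizes

The test suite and `scripts/acceptance.R` run three standing
experiments, with sizes chosen to make each well-posed rather than
maximal:

* **Attenuation** (the headline structural claim): 50 replicates of a
  12×12 metro (~14,400 households) in the tests (20 in the acceptance
  script), with life expectancy driven *solely* by income composition —
  HOLC offsets, spatial field and iid noise all zero — and a graded core
  covering 80% of the lattice.  The denser core is a design requirement,
  not calibration: the adjusted within-stratum model estimates ~12
  parameters, and at the default 30% core the hazardous stratum has only
  ~16 tracts, which leaves the stratified fit rank-deficient or wildly
  unstable.  At 80% the stratum has ~41 tracts.  The claim checked is
  that adjustment for the three mobility categories shrinks the
  no-gentrification coefficient's magnitude within the hazardous stratum
  in at least 90% of replicates.
* **Spatial null coverage and detection**: 10×10 metros with no spatial
  field, 3,000 iterations / 500 burn-in / thinning 2 — reduced from the
  defaults because the experiment repeats the fit 40 times; split-chain
  diagnostics at these settings stay near 1.  Under the null, the
  fraction of flagged tracts must not exceed 10% (in practice it is
  ~0%: the credible-interval rule on a smoothed deviation is
  conservative).  A planted −6-year anomaly in a 3×3 corner must be
  flagged `lower` on a majority of its tracts, with no wrong-sign flag,
  in at least 90% of runs.
* **Analysis workflow** (`analysis/`): one 20×20 metro with 60
  households per tract, large enough that every stratified adjusted
  model except the small "best" stratum fits stably.

# Known limitations

* Life expectancy enters as a point estimate; its published uncertainty
  is not propagated into group CIs or models.
* The weighted-mean CI is a normal approximation at the tract level.
* The ICAR smoother is a stand-in for the original spline surface;
  smoothed deviations are comparable in role, not in value.
* The attenuation analysis is associational; no mediation decomposition
  is attempted.
* Only one life-expectancy period is modeled; longitudinal change in
  life expectancy is out of scope.
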