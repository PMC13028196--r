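---
title: "Modelling five-year treatment-change trajectories of hypoglycemia-associated medication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling five-year treatment-change trajectories of hypoglycemia-associated medication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypotraj)
```

## The estimand and the data it is computed from

Community-pharmacy dispensing databases record, per patient, only ATC
codes and dispensing dates. `hypotraj` turns such records into annual
treatment-change trajectories for the two glucose-lowering drug classes
with the highest severe-hypoglycemia risk — sulfonylureas (`A10BB`) and
insulins (`A10A`) — and models those trajectories. Three constructions
carry all the scientific content, and each involves choices that this
vignette documents.

### The anniversary snapshot

A drug subgroup (ATC-5, the chemical subgroup) is *active* at an
assessment date when at least one dispensing with that prefix falls in
the closed window ±45 days around the date. The window half-width is a
tunable (`window_days`, in days, default 45); 45 days reflects prior
sensitivity work on minimizing misclassification of initiation and
discontinuation under the roughly two-to-three-month refill cycles of
Dutch pharmacies. Both window boundaries are inclusive so that counts are
bit-reproducible; widening the window can only add drugs (monotonicity,
property-tested). Fixed oral combinations (`A10BD`) are decomposed into
their constituent classes through a shipped, editable lookup — otherwise
sulfonylurea exposure inside a combination tablet would be missed.

Drug *activity* is tracked at ATC-5 granularity (so premixed insulin
`A10AD` is distinguishable for the risk score), while *change detection*
operates on class-level flags (insulin, SU, other). One consequence:
two different sulfonylurea products share the subgroup `A10BB`, so the
taxonomy label "SU combination" (two distinct SU subgroups; 0.1% of the
reference cohort) is retained in the classifier but unreachable, and the
generator omits it from its initial-regimen menu.

Anniversaries are calendar anniversaries of the index date (a Feb-29
index maps to Feb 28 in non-leap years), not index + 365k; consecutive
assessment gaps are therefore 365 or 366 days, and the Markov model
treats every gap as exactly one year.

### The change classification

Each of the five patient-intervals is classified from the *net* change
between its two endpoint snapshots: `NC` when no hypoglycemia-associated
class was added or dropped (including intervals where only "other"
glucose-lowering drugs changed), `IN` for additions of or switches to
SU/insulin, `DI` for discontinuations of or switches away from them.
Changes that revert within the year are invisible by construction; the
analysis captures sustained changes only.

Subtypes carry a Mono/Comb prefix from the therapy type at the interval
start. A "switch" label requires movement on the non-hypo side: an
intensification is a switch when a previously active non-hypo subgroup
disappeared, a de-intensification is a switch when a non-hypo subgroup
newly appeared; otherwise the label is an addition or discontinuation.
Mixed deltas follow insulin dominance: SU dropped + insulin added is the
intensifying "Switching from SU to insulin"; insulin dropped + SU added
is the de-intensifying "Switching from insulin to SU"; simultaneous
moves of both classes in the same direction are counted once at the
insulin level, because the subtype vocabulary has no compound labels. A
complete stop of all glucose-lowering drugs counts as de-intensification
(discontinuation of the highest-precedence hypo drug previously present)
only when a hypo drug was present before; a full stop from a pure-other
regimen is not a hypo-associated change. This convention — rather than
censoring full stops — is a design choice; the classifier is exhaustively
tested against an independently written rule oracle over all 256 ordered
pairs of regimens drawn from {metformin, SU, insulin, DPP4}.

### The piecewise-constant multi-state Markov model

States observed annually form panel data: transitions between
assessments are unobserved, so the likelihood of an observed one-year
transition i→j is the (i,j) entry of the matrix exponential
P_k = exp(Q_k) of that interval's generator. Each of the four
year-to-year intervals gets its own 3×3 generator (six free intensities
per piece, optimized as log-intensities to enforce positivity), making
the per-piece model *saturated*: whenever the empirical transition
matrix of a piece is embeddable (expressible as exp(Q) for a valid
generator), the MLE equals the empirical row-normalized matrix. The
fitter exploits this — it initializes at the matrix logarithm of the
empirical matrix when that is a valid generator and at
continuity-corrected crude rates otherwise, then polishes with BFGS
(relative tolerance 1e-12, max 500 iterations, convergence reported with
the central-difference gradient norm). The saturation property is also
the module's correctness anchor in the tests, since fitted values from
restricted patient-level data cannot be compared exactly.

Confidence intervals use a seeded parametric bootstrap (default 500
draws) over the asymptotic normal of the log-intensities, propagated
through the matrix exponential; draws are clamped to log-intensity 6
(far beyond any annual-panel-compatible rate) so near-empty rows cannot
overflow, and intervals are clipped to contain the point estimate. A
delta-method alternative was considered and rejected: it needs the
Fréchet derivative of the matrix exponential for a 36-entry output, and
the bootstrap is both simpler and exact in distribution as draws grow.

## The synthetic generator: what it emulates and what it does not

`simulate_population()` emulates the structure the analysis assumes:

* a latent annual change process — a CTMC on (NC, IN, DI) observed
  yearly. Default intensities are frozen as the matrix logarithm of a
  one-year matrix with NC row (0.876, 0.077, 0.047) — the year-1 state
  shares of the reference cohort — and IN/DI rows with persistence
  around 0.41/0.40 and return-to-NC around 0.50/0.49, the pattern
  reported for that cohort's fitted model;
* regimen realism: initial regimens drawn from the reference cohort's
  baseline taxonomy frequencies; drawn changes are applied as concrete
  add/drop/switch actions at one uniformly drawn date per year, in the
  interior of the interval (≥46 days clear of both anniversaries) so a
  change is attributable to exactly one interval. A drawn change that is
  infeasible for the current regimen — intensification when insulin and
  SU are both present, de-intensification without any hypo drug —
  degrades to NC, and the recorded latent truth is what actually
  happened. Because ~7% of patients start on insulin + SU and ~43% on
  pure non-hypo regimens, the *population* year-1 shares under the
  default configuration sit slightly below the NC-row targets (about
  7.1% IN); the convergence test therefore uses an all-feasible
  configuration (everyone starts on SU + metformin), for which the
  year-1 distribution is exactly the NC row;
* refill structure: per-drug renewal processes with truncated-normal
  intervals (default mean 60 d, sd 15 d, floor 14 d — typical Dutch
  dispensing cycles). Drugs active at the index are emitted backwards
  from just before the index window and forwards from the index, so the
  first in-window dispensing *is* the index date and the latent and
  observed anniversary grids coincide;
* heterogeneity used by the inference modules: a DI-hazard multiplier
  for women (default 1.12) and for insulin users (default 2.5), making
  de-intensification more likely in the high-risk group;
* edge cases at configurable fractions: spot users (exactly one A10
  dispensing in the index year; default 5%), insulin-only pre-index
  patients (2%; the fractions are stipulated, since the reference flow
  chart's step counts are not published), and short-registration
  patients (49.2%, the published share failing the ten-year
  requirement). Patients whose index regimen is insulin-only get a
  discontinued oral in their pre-index history so the type-1-like
  exclusion does not misfire on genuine type 2 patients.

What it does **not** emulate: dosing and DDDs (dose-level change
detection is out of scope), mortality beyond `registration_end`,
seasonal or stockpiling refill behaviour, pharmacy switching, and any
dependence of refill timing on regimen complexity. Passing tests on
synthetic data therefore show that the *pipeline* is correct — that the
classifier recovers a known generative process (≥99% of patient-years
under short refill intervals) and the estimators recover known
parameters — not that real dispensing data meet the assumptions.

The risk-score coefficients shipped as defaults are synthetic: the
original algorithm's coefficients are not public, so the default vector
uses clinically plausible directions dominated by insulin exposure and
is calibrated so that about a quarter of the default simulated cohort
exceeds the 0.6 cutoff, mirroring the published ~26% high-risk share.
Real analyses must supply the validated coefficients file.

## Numerical and procedural conventions

* All reported percentages round half away from zero to one decimal
  (`round_half_up()`), matching printed tables; base R's half-to-even
  would disagree on exact halves.
* The ≥2-dispensing prevalent-user rule counts the index dispensing
  itself (closed interval [index, index+365]); the index window is
  closed on both ends; age is completed years with a July-1 birthday
  convention since the database stores birth year only.
* Patients with *no* pre-index glucose-lowering dispensings are retained
  (incident-like users); the insulin-only exclusion fires only when
  pre-index A10 history exists and is all insulin.
* Exclusion steps run in a fixed declared order (dummy ids, no index,
  age, spot user, registration, insulin-only), so the flow tally plus
  the retained count always equals the input count.
* Multinomial logit: full Newton–Raphson with step halving, convergence
  on relative log-likelihood change < 1e-10; Wald CIs from the observed
  information; two-sided p < 0.05 flags significance; no
  multiple-testing correction (none is standard for a two-model OR
  table). Rank deficiency and separation are errors naming the
  predictor. Unobserved outcome categories are dropped from the
  equations.
* Risk score: the 0.6 cutoff assigns the boundary to "high" (score ≥
  cutoff); counts are distinct ATC-5 subgroups, not dispensing events,
  making the predictors robust to refill frequency.
* All randomness flows from explicit seeds: the generator derives a
  per-patient substream for the latent stage (so `latent_truth()` can
  re-derive the truth from the configuration alone) and a single derived
  stream, in fixed episode order, for refill emission; pipeline outputs
  are byte-identical under a fixed configuration and contain no
  timestamps.

## Problem sizes used by the test and acceptance code

The packaged checks run at sizes chosen to make Monte-Carlo error
negligible relative to the tolerances while staying comfortable on a
single CPU: generator-convergence and risk-score calibration checks use
25,000 simulated patients; Markov parameter recovery and bootstrap
coverage use 200 replicates of 5,000-patient panels with 500 bootstrap
draws; regression CI coverage uses 100 replicates at n = 25,000 (fitted
on grouped counts); the acceptance script's end-to-end run simulates
25,000 patients. The published-count fixtures are exact and run in
milliseconds.

## Known limitations

* Intra-year churn is invisible; states are net annual changes.
* The regimen taxonomy is reconstructed from published labels; a
  source-database operational appendix could differ in corner cases.
* The fitted transition probabilities of the restricted reference cohort
  are not exactly reproducible from aggregate tables (the published
  crude year-to-year matrices are not even embeddable), so the Markov
  module's validation rests on closed forms, saturation and simulation
  recovery rather than value-matching.
* The insulin-dominance tie-break forces one label per interval; a
  richer vocabulary would split compound changes.
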