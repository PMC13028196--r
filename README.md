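# hypotraj

Five-year treatment-change trajectories of hypoglycemia-associated
medication in type 2 diabetes, reconstructed from community-pharmacy
dispensing records.

## The problem

Sulfonylureas and insulins are the glucose-lowering drug classes that
carry the highest risk of severe hypoglycemia. Whether, when, and for
whom these drugs are added (*intensification*) or stopped or replaced
(*de-intensification*) is central to personalized diabetes management,
but in claims and dispensing databases nothing is observed except
(patient, ATC code, dispensing date) triples. `hypotraj` implements the
full analytical chain that turns raw dispensing tables into annual
treatment-change trajectories and their determinants:

1. **Cohort selection** — prevalent users of glucose-lowering drugs
   (ATC `A10`): index at the first A10 dispensing in a one-year window,
   age ≥ 35, ≥ 2 A10 dispensings within 365 days of index, ten years of
   continuous registration (5 pre + 5 post), exclusion of type-1-like
   patients whose pre-index glucose-lowering history is insulin only,
   with a selection-flow tally.
2. **Anniversary snapshots** — the set of drug subgroups dispensed in a
   ±45-day window around the index date and each of its five yearly
   anniversaries, with `A10BD` fixed combinations decomposed into
   constituent classes, classified into the baseline regimen taxonomy
   (metformin monotherapy, SU + non-insulin combination, ...).
3. **Change classification** — each patient-year becomes `NC` (no
   change), `IN` (intensification: addition of or switch to SU/insulin)
   or `DI` (de-intensification: discontinuation of or switch away from
   SU/insulin), with a Mono/Comb subtype label ("Mono—Addition of SU",
   "Comb—Discontinuation of insulin", ...). Mixed changes follow an
   insulin-dominance rule.
4. **Tabulation** — annual transition matrices, pooled subtype rankings,
   crude rates stratified by age band (35–49, 50–64, 65–74, ≥75) and sex,
   and the net five-year outcome (index regimen vs Year-5 regimen).
5. **Multi-state Markov model** — a continuous-time three-state Markov
   model with piecewise-constant transition intensities Q_k fitted to the
   annual panel by maximum likelihood; the one-year transition matrices
   are P_k = exp(Q_k), with seeded parametric-bootstrap confidence
   intervals (`fit_msm()`, an S3 model object with `print`, `summary`,
   `coef`, `plot`, `simulate`, `residuals` methods).
6. **Hypoglycemia risk score** — an inverse-logit dispensing-based score
   (age, sex, drug counts, premixed insulin, antidepressants, insulin
   duration) dichotomized at 0.6; coefficients are a user-supplied file,
   with a documented synthetic default.
7. **Outcome regression** — multinomial logit (Newton–Raphson, Wald CIs)
   of the net five-year outcome on risk category, sex and age per decade
   (`fit_mlogit()` / `fit_outcome_model()`).

Because the source databases of such studies are access-restricted, the
package includes a **synthetic dispensing-data generator**
(`sim_config()` / `simulate_population()`) whose latent annual change
process is itself a CTMC; `latent_truth()` exposes the generative state
of every patient-year, so the classifier can be validated against a
known truth.

## Worked example

```r
library(hypotraj)

cfg <- sim_config(2000, seed = 7)
sim <- simulate_population(cfg)
sel <- select_cohort(sim$patients, sim$dispensings)
sel$flow
#>              dummy_id       no_index_dispensing         age_below_minimum
#>                     0                         0                         2
#>             spot_user insufficient_registration     insulin_only_preindex
#>                   101                       982                        42
#>              retained
#>                   873

events <- annual_states_all(sel$members, sim$dispensings)
tt <- transition_tables(events)
tt$periods[[1]]$subtotal_pct
#> [1] 87.6  7.0  5.4

fit <- fit_msm(events_to_panel(events), boot_draws = 500, seed = 1)
round(fit$prob[[1]]$p, 3)
#>       NC    IN    DI
#> NC 0.899 0.068 0.033
#> IN 0.737 0.156 0.107
#> DI 0.767 0.139 0.094
```

The flow tally mirrors the cohort-selection flow chart (here about half
the simulated patients fail the ten-year registration requirement, the
study condition); the subtotal percentages are the year-1 shares of no
change / intensification / de-intensification; the fitted matrix gives
the one-year transition probabilities between change states, whose
diagonal `NC → NC` entry is the annual persistence of a stable regimen.

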