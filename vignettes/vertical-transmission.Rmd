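---
title: "Bounding vertical transmission of a phoretic colony symbiont"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding vertical transmission of a phoretic colony symbiont}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoresim)
```

## The question and the model

Phoretic symbionts of social-insect colonies — here, cockroaches living in
leaf-cutter fungus gardens and riding on dispersing female alates — can
reach new host colonies vertically (co-establishing with a colony-founding
queen and persisting until the colony matures) or horizontally (moving
between established colonies). `phoresim` implements a deliberately simple
ceiling argument: assume transmission is *strictly vertical*, push every
free parameter in the direction that favours vertical transmission, and ask
how much mature-colony prevalence that machine can sustain at equilibrium.

Four classes are tracked: foundresses with and without the symbiont
(`F_i`, `F_u`) and mature colonies with and without it (`M_i`, `M_u`).
Foundress counts are exogenous constants — the model deliberately omits
feedback from mature colonies to foundress production, because the
equilibrium prevalence below does not depend on it. With maturation rates
`s_i`, `s_u`, persistence probability `z` and shared mature-colony
mortality `q`:

$$\frac{dM_i}{dt} = F_i s_i z - M_i q, \qquad
  \frac{dM_u}{dt} = F_u s_u + F_i s_i (1 - z) - M_u q.$$

Writing $J = F_i / (F_i + F_u)$ for foundress prevalence and
$\delta = s_i / s_u$ for the symbiont's effect on reaching maturity, the
equilibrium mature-colony prevalence $V = M_i^\*/(M_i^\* + M_u^\*)$ is

$$V = \frac{\delta z}{1/J - 1 + \delta}.$$

Three structural facts drive everything else:

* `q` cancels — colony lifespan does not matter for the equilibrium mix;
* $V \le z \le 1$, and with $\delta = z = 1$, $V = J$ exactly: even a
  neutral, never-lost symbiont can only *mirror* foundress prevalence;
* $V$ is nondecreasing in each of $\delta$, $J$, $z$, which is what makes
  "choose the favourable extreme of every parameter" a genuine ceiling.

### Model assumptions

* Infected foundresses that lose the symbiont mature at the same rate
  `s_i` as those that keep it (the symbiont's damage is done early).
* Infected and uninfected mature colonies die at the same rate `q`
  (long chronic infections with no apparent colony-level harm).
* No density dependence, no spatial structure, and no
  horizontal-transmission force of infection — by construction: the model
  exists to bound the vertical route alone.

## The estimation chain

The parameters fed to the closed form are estimated, not assumed:

* **δ from survivorship.** A two-treatment (symbiont present/absent),
  daily-checked incipient-garden survivorship experiment is fitted with a
  Cox proportional-hazards model (`cox_fit()`); δ is the inverse of the
  fitted hazard ratio (`delta_from_hr()`). Daily checks produce heavily
  tied event days, so the ties correction is explicit: Breslow by default,
  Efron available. Nest-within-flight heterogeneity is absorbed by a gamma
  shared frailty (penalized partial likelihood). The original analysis of
  this design used a lognormal random effect; gamma frailty has a
  tractable closed-form penalized likelihood, and coefficients may differ
  slightly between the two — a stratified-by-flight fixed-effects fit is
  the fallback when the frailty fit is not wanted.
* **Two endpoint definitions.** A garden can fail because the foundress
  abandons it ("uncaring") or because she dies. `endpoint_events()`
  implements both the `combined` definition (either counts as an event)
  and `uncaring_only` (foundress deaths are right-censored at the death
  day — censoring, not deletion, so risk sets are preserved). Foundress
  death is treatment-independent, so under the `combined` definition the
  observed event mixes a proportional-hazards process with a flat one and
  the fitted hazard ratio is attenuated toward 1; `uncaring_only` targets
  the garden-failure hazard itself. Parameter-recovery checks therefore
  use `uncaring_only`; fitting both and comparing is part of the intended
  workflow. Treating δ estimated from the combined endpoint as
  conservative (biased toward neutrality) is consistent with the ceiling
  logic.
* **J and V_field from surveys.** `survey_summary()` reduces an
  11-colony nuptial-flight survey to the fraction of colonies infected
  (`V_field`), per-colony alate prevalences, and their maximum (`J_max`).
  Direct observations of symbionts in foundress chambers are lacking, so
  the maximum alate prevalence from a single mound (0.07 = 50/719 on
  record) stands in for `J` — almost certainly a large overestimate, which
  again only inflates the ceiling.
* **Auxiliary statistics.** `proportion_ci()` (Clopper–Pearson exact by
  default — the exact bounds reproduce the reported 52.0%–72.2% interval
  for a 60/96 disturbance proportion, which Wald/Wilson do not — plus
  Wilson and Wald), and `chi_square_2x2()` with the Yates correction on by
  default.

## The stochastic cohort simulator

`simulate_cohorts()` is an independent Monte-Carlo check on the closed
form, not a second implementation of it: time is discretized to years and
every transition is a binomial draw (infected foundress arrivals, maturation,
symbiont retention, colony death). Mortality strikes the colonies existing
at the start of a year and the year's new maturations join the census
afterwards, so each mature class fluctuates around `F·s/q` and the census
order adds no `O(q)` bias to class means. With 5,000–10,000 foundresses a
year and a century-scale horizon, the post-burn-in mean prevalence agrees
with the closed form to Monte-Carlo precision across random parameter
draws.

One statistical subtlety is worth recording. The simulator's Monte-Carlo
standard error is estimated from a small number of independent replicates
(typically 4–10), so "within 3 SE" is a Student-t event at few degrees of
freedom — roughly a 94–99% event per draw, not 99.7%. The test suite
asserts near-complete coverage over 100 draws (≥ 97 within 3 SE, ≥ 99
within 4 SE) rather than the statistically incorrect "all 100 inside".

## The synthetic-data generators

No raw data ship with the package; both study designs are emulated by
seed-deterministic generators.

`generate_survival_experiment()` draws a 96-chamber, two-flight (53 + 43)
experiment by default: chambers are assigned a nest uniformly within
flight, treatment is balanced within flight, garden-failure times are
exponential with hazard `baseline · exp(nest effect + treatment · log HR)`
rounded **up** to whole days (the daily-check protocol — this is what
forces ties and exercises the ties corrections), and an independent
exponential foundress-death process competes; earliest event wins, same-day
collisions resolve to foundress death (a dead caretaker makes the garden
effectively dead), and everything is censored at the end of follow-up.

Defaults, chosen once as field-realistic values and not tuned: baseline
garden-failure hazard 0.02/day (median control failure ≈ 35 days within a
60-day follow-up — incipient gardens are fragile), treatment log hazard
ratio `log(3.36)`, nest frailty SD 0.3 on the log-hazard scale, 4 nests
per flight (the source count is not recorded, so this is a free design
knob), foundress death hazard 0.005/day (~26% foundress mortality over
follow-up, matching a death process that does not differ between
treatments), and disturbance probability 0.625.

`generate_field_survey()` draws 11 colonies, each infected with
probability 8/11; infected colonies get a per-colony alate prevalence
uniform on 2.2%–6.8% and a binomial count of alates carrying a hitchhiker,
on 300–1,000 alates sampled per colony (order-of-magnitude of a morning's
collecting on a nest mound).

What the generators deliberately do **not** emulate: garden-mass dynamics,
tending-behaviour durations, or any behavioural sequence behind the
disturbance flags (those are Bernoulli draws); non-proportional hazards;
informative censoring; between-site heterogeneity in the survey. Passing
tests therefore certify the estimation chain under proportional hazards
with nested frailty and the survey under binomial sampling — they say
nothing about, e.g., hazard non-proportionality in real gardens.

## Numerical choices

* `equilibrium_prevalence()` returns 0 at `J = 0` or `δ = 0` by continuity
  (keeps sensitivity grids total); the single genuinely indeterminate
  point `J = 1, δ = 0` errors.
* `integrate_dynamics()` uses fixed-step RK4 with step `0.1/q` and horizon
  `20/q` by default (the system is linear and non-stiff for `q·step < 1`);
  a step ≥ `1/q` warns and falls back to an adaptive solver (lsoda).
  Convergence of the limiting prevalence to the closed form is checked to
  1e-6.
* `cox_fit()` delegates the partial-likelihood maximization to
  `survival::coxph()`; its correctness is tested against a brute-force
  1-D maximization of the Breslow partial likelihood on small tie-free
  fixtures (agreement to 1e-6), and its calibration by parameter-recovery
  simulation (absolute bias of the log hazard ratio < 0.05 at 500
  chambers per arm over 200 replicates) and by 2·SE coverage of the
  configured truth at the 96-chamber study scale.
* Monotone likelihoods (a treatment arm with no events) are refused with
  an error naming the offending group rather than returning a divergent
  estimate.
* Reported values keep the analysis's printed precision — two decimals for
  δ and V, nearest percent for contribution ratios — with raw unrounded
  values always retained alongside.
* Reproducibility: every generator and the simulator take an explicit
  integer seed. When many seeded runs are compared in bulk, seeds are
  scattered from a single master stream rather than taken as consecutive
  integers, which measurably distorts the variance of the first draws of
  R's default RNG.

## Problem sizes used in the checks

The test suite runs the full property checks at reduced but informative
scales, chosen as the package's own verification design: 100 random
parameter draws for the deterministic and stochastic oracle-equivalence
checks (5,000 foundresses/year, 120 years, 10 replicates each), 200
replicates at 500 chambers/arm for parameter recovery, and 100 seeds at
the 96-chamber study scale for end-to-end coverage.

## Known limitations

* Absolute rates `s_u`, `s_i`, `q` are not identified by any quantity the
  analysis uses — only δ and the prevalences matter. Constructors accept
  δ alone and flag the placeholder rates (`rates_placeholder`), and
  reports print provenance for every number so the placeholders are
  auditable.
* The gamma-frailty fit is a pragmatic stand-in for a lognormal random
  effect; variance estimates on 8 nests are noisy and the frailty variance
  should be read qualitatively.
* The ceiling argument is one-directional: it can rule vertical
  transmission *insufficient*, but a low ceiling says nothing about how
  much horizontal transmission actually occurs.
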