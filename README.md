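# phoresim

Bounding the contribution of **vertical transmission** to symbiont
prevalence in social-insect colonies.

## The problem

*Attaphila* cockroaches live in the fungus gardens of leaf-cutter ant
colonies and disperse by riding on female alates (winged virgin queens)
during nuptial flights. Field surveys find most mature colonies infected,
yet the roaches could in principle reach a new colony in two ways: by
**vertical transmission** — hitchhiking on an alate, co-establishing with
the foundress, and persisting until the colony matures — or by
**horizontal transmission** between established colonies. `phoresim`
implements the quantitative argument that separates the two: a
strict-vertical-transmission model whose equilibrium prevalence can be
compared with the prevalence actually observed in the field. If the model's
ceiling falls far below the field value, horizontal transmission must carry
the difference.

## The model

Foundresses found colonies alone; a fraction `J` of them carry the
symbiont. Infected foundresses reach colony maturity at rate `s_i`,
uninfected ones at `s_u`; their ratio `δ = s_i / s_u` is the symbiont's
effect on the chance of reaching maturity (δ < 1 harmful, δ = 1 neutral).
An inherited infection persists to maturity with probability `z`, and
mature colonies (infected or not) die at rate `q`:

    dM_i/dt = F_i s_i z − M_i q
    dM_u/dt = F_u s_u + F_i s_i (1 − z) − M_u q

At equilibrium the mature-colony infection prevalence is closed-form:

    V = δ z / (1/J − 1 + δ)

`q` cancels, and `V ≤ z ≤ 1` always. δ is estimated from a two-treatment
incipient-garden survivorship experiment as the inverse of the fitted Cox
hazard ratio; `J` is bounded by the maximum proportion of alates from a
single colony observed carrying a hitchhiker.

The package provides this model (closed form, ODE integration, sensitivity
grids), the estimation chain (Cox proportional-hazards fits with
Breslow/Efron ties and gamma shared frailty, Kaplan–Meier curves, exact
binomial confidence intervals, 2×2 chi-square, survey summaries), a
discrete-time stochastic cohort simulator used as an independent
Monte-Carlo check on the equilibrium, and seed-deterministic synthetic-data
generators for both study designs.

## Worked example

```r
library(phoresim)
run_reproduction()
```

```
Vertical-transmission ceiling analysis
  delta (lab estimate)     = 0.30 [default]
  delta (neutral symbiont) = 1.00 [default]
  J (foundress prevalence) = 0.07 [default]
  z (persistence)          = 1.00 [default]
  V_field (observed)       = 0.73 [default]
  V under lab delta        = 0.02 (raw 0.02208)
  V under neutral delta    = 0.07 (raw 0.07000)
  vertical transmission accounts for at most 3% (lab delta) or 10% (neutral) of field prevalence
```

Reading: with the laboratory-estimated virulence ratio (δ = 0.3, the
inverse of a garden-failure hazard ratio of 3.36), a conservative foundress
prevalence (J = 0.07, the largest single-mound alate prevalence on record)
and perfect persistence (z = 1), strict vertical transmission sustains at
most 2% mature-colony prevalence — about 3% of the 73% observed in the
field. Even a perfectly neutral symbiont could reach only 7% (about 10% of
the field value). Every number in the report is tagged with its provenance
(`config`, `computed`, or `default`).

The same chain runs from data. Generate a synthetic 96-chamber experiment
and survey, then fit everything end to end:

```r
recs <- generate_survival_experiment(experiment_design(seed = 1))
svy  <- generate_field_survey(survey_design(seed = 1))
rep  <- run_reproduction(survival_records = recs, survey_records = svy,
                         endpoint = "uncaring_only")
rep$cox     # the underlying Cox fit (hazard ratio, SE, frailty variance)
```

A thin command-line wrapper with subcommands `equilibrium`, `simulate`,
`fit-survival`, `survey`, `synth`, and `reproduce` is installed at
`inst/cli/phoresim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/phoresim.R", package="phoresim"))')" \
  equilibrium --delta 0.3 --J 0.07 --z 1
```

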