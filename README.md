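# rflbounds

Partial-identification tools for two-arm randomized trials with missing
outcome data.

Randomization makes the two arms of a trial comparable at baseline, but when
outcomes go missing between randomization and follow-up — *attrition* — the
complete-case difference in means can be badly biased, and the assumptions
that would restore a point estimate (MCAR or MAR missingness) cannot be
verified from the observed data. `rflbounds` is for trial analysts who want
to treat attrition as potentially non-random (MNAR) and report an honest
*interval* for the average treatment effect instead:

- **Attrition diagnostics** — per-arm observed-outcome proportions, the
  trimming share, the power retained after attrition, covariate balance
  regressions, and the adjusted-vs-unadjusted comparison that probes the
  MCAR assumption.
- **Horowitz–Manski worst-case bounds** — assumption-free bounds that fill
  missing outcomes with the extremes of the outcome support.
- **Lee trimming bounds** — under monotone sample selection, trim the
  outcome distribution of the less-attrited arm by the attrition
  differential; the resulting interval brackets the average treatment
  effect for *never-attriters*, with bootstrap outer confidence intervals.
- **Random Forest Lee Bounds (RFLB)** — a four-step procedure that tightens
  Lee bounds by conditioning on covariates, *including continuous ones*: a
  random-forest attrition model is screened by cross-validated permutation
  importance against an injected random benchmark variable (with a
  treatment-interaction confirmation step), the selected covariates are
  discretized by an entropy decision tree, and cell-wise conditional Lee
  bounds are aggregated over the resulting cells.
- **A synthetic-trial generator** — seeded two-arm trials with configurable
  MCAR/MAR/MNAR attrition mechanisms, a preset calibrated to a published
  acrophobia VR-CBT trial (96 treated / 97 control, observed outcome means
  48.46 vs 74.68, attrition 40/96 vs 11/97), effect-size scaling
  (d = 0.2/0.4/0.8), and a replication-study harness.

## The model in brief

With outcome `y_i`, assignment `T_i ∈ {0,1}` and observation indicator
`S_i`, the baseline estimand is `β` in `y_i = α + β·T_i + ε_i`, estimated by
OLS on complete cases (identical to the difference in observed arm means).
The per-arm observation proportions

```
q_1 = Σ 1(T_i=1, S_i=1) / Σ 1(T_i=1),   q_0 likewise,
```

give the trimming share `q = (max(q_0,q_1) − min(q_0,q_1)) / max(q_0,q_1)`.
Under monotone selection (assignment can push attrition in only one
direction), trimming the less-attrited arm's outcome distribution by `q`
from each tail in turn yields lower and upper bounds on `β` among
never-attriters. Power retained after attrition follows
`θ = 2.8·(N_os/N_fs) − 1.96` with power `Φ(θ)` (80% at a ratio of 1, 56% at
0.75). RFLB conditions the trimming on data-driven cells; a covariate
enters the conditioning set only if both its main importance and its
treatment-interaction importance strictly exceed the random benchmark's.

## Worked example

Simulate a trial-scale dataset whose attrition is driven jointly by
assignment, gender and the continuous baseline severity score, then compare
unconditional Lee bounds with RFLB:

```r
library(rflbounds)
g <- generate_trial(selective_attrition_preset(), seed = 42)
attrition_rates(g$dataset)
#> Attrition: 141 of 193 outcomes observed
#>   observed proportion, treated: 0.5417  control: 0.9175
#>   trimming share q = 0.4096 (trimmed arm: control)

bounds_ci(g$dataset, "lee", analysis_config(seed = 42))
#> lee bounds
#>   point estimate (unadjusted beta): -26.445
#>   lower -40.418  upper -12.493  width 27.926  (trim share 0.410, trimmed arm control)
#>   95% outer CI [-48.525, -4.097]  width 44.429  (outer, 500 bootstrap replicates, 0 dropped)

rflb_bounds(g$dataset, analysis_config(seed = 42))
#> Attrition importance (normalized, max = 1):
#>   [treatment]           1.00 ########################################
#>   aq_pre                0.92 #####################################
#>   female                0.10 ####
#>   age                   0.03 #
#>   [random benchmark]    0.00   <- benchmark
#> Conditioning set (rule 'both'): female, aq_pre
#> Conditioning scheme on {female, aq_pre}: 2 cell(s)
#>    cell            rule n_treated n_control obs_treated obs_control
#>  cell_1 aq_pre <= 81.64        39        38          31          32
#>  cell_2  aq_pre > 81.64        57        59          21          57
#> rflb bounds
#>   point estimate (unadjusted beta): -26.445
#>   lower -31.606  upper -13.335  width 18.270  (trim share 0.283, trimmed arm control)
#>   95% outer CI [-39.781, -5.208]  width 34.573  (outer, 500 bootstrap replicates, 0 dropped)
```

Reading the output: complete-case analysis reports a 26.4-point symptom
reduction, but 41% differential attrition means that point is not
identified. Unconditional trimming brackets the never-attriter effect in
[-40.4, -12.5]; RFLB finds that the pre-score (importance 0.92, far above
the benchmark at 0.00) and gender drive attrition *conditionally on
assignment*, splits the sample at a pre-score of 81.6, and tightens the
interval to [-31.6, -13.3] — a 35% narrower identified set whose outer
95% CI still excludes zero.

A command-line front end wraps the same functions:

```sh
rflbounds diagnose --input trial.csv --out-dir reports
rflbounds bounds   --input trial.csv --method lee --seed 1 --out-dir reports
rflbounds rflb     --input trial.csv --seed 1 --out-dir reports
rflbounds study    --preset selective --methods lee,rflb --reps 50 --out-dir reports
```

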