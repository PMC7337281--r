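---
title: "Methods: trimming bounds and random-forest conditioning for trial attrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trimming bounds and random-forest conditioning for trial attrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflbounds)
```

## The problem

A two-arm randomized trial identifies the average treatment effect (ATE) by
the difference in arm means. When some participants' outcomes are never
measured — attrition — the complete-case difference identifies the ATE only
under assumptions about the missingness mechanism:

- **MCAR**: missingness is unrelated to assignment and to all baseline
  characteristics. Testable implications are weak: covariates should not
  predict assignment on the observed sample, and adjusting the outcome
  regression for covariates should not move the estimate.
- **MAR**: missingness is explainable by *observed* covariates; adjustment
  restores the point estimate.
- **MNAR**: missingness may depend on unobservables (including the outcome
  itself). No point estimate is available without further assumptions; the
  honest report is an *identified interval*.

`rflbounds` implements the diagnostics for the first two scenarios and two
bounding strategies for the third, plus a procedure that tightens the
bounds by conditioning on covariates selected by a random-forest screen.

## Estimands and procedures

**Worst-case (Horowitz–Manski) bounds** require only a known outcome
support $[y_{\min}, y_{\max}]$: missing outcomes are filled with the
support extremes, best case against worst case. They bound the
full-population ATE and are typically wide.

**Trimming (Lee) bounds** add one assumption — *monotone selection*:
assignment can shift each participant's attrition probability in only one
direction. Let $q_1, q_0$ be the per-arm observed-outcome proportions and
$q = (\max(q_0,q_1)-\min(q_0,q_1))/\max(q_0,q_1)$ the trimming share. The
less-attrited arm's outcome distribution is trimmed by mass $q$ from its
lower and upper tail in turn; the two resulting mean differences bracket
the ATE *among never-attriters* — participants whose outcome would be
observed under either assignment. The reference population for that
estimand is characterized by the observed participants of the arm that
remains untrimmed.

These are bounds on **different estimands**. A consequence worth knowing:
the trimming interval is not mathematically guaranteed to nest inside the
worst-case interval. When the observed outcomes span the entire support
and the attrition differential is extreme, the trimmed mean of a
half-trimmed arm can exceed the worst-case bound for the full population
(a dedicated unit test constructs such a boundary case). In the regime
worst-case bounds are used in practice — an instrument whose logical range
strictly contains the observed score spread — containment holds in every
one of the package's property-test draws.

**Conditional trimming** performs the procedure within discrete cells and
averages the per-cell bounds with weights proportional to each cell's
share of observed participants in the globally untrimmed arm (the
never-attriter reference population). Each cell is trimmed in the
direction of its *own* attrition differential; cells whose differential
flips sign relative to the global one are retained — their trim simply
applies to the other arm — and flagged in the per-cell table, because
discarding them would bias the weights. Monotonicity should then be judged
per cell.

**Random Forest Lee Bounds (RFLB)** makes conditioning possible for
continuous covariates, in four steps:

1. fit a random-forest classifier of the observation indicator on
   assignment, the baseline covariates, and an injected pure-noise
   *benchmark* column;
2. score each feature by permutation importance on held-out
   cross-validation folds, normalized so the maximum is 1; a covariate is
   a candidate only if its importance strictly exceeds the benchmark's.
   A second forest scores explicit interaction features $T \cdot X_j$
   against $T \cdot \text{benchmark}$: covariate-related attrition is
   necessary but not sufficient for tightening — the covariation between
   attrition and *assignment* must itself be conditional on the covariate,
   which is what the interaction screen confirms;
3. discretize the selected covariates with a single entropy-gain decision
   tree predicting the observation indicator (assignment excluded from the
   splits); leaves become cells;
4. run conditional trimming bounds on the cells, with the bootstrap for
   uncertainty.

If nothing passes the screen, or the tree cannot form more than one
feasible cell, the pipeline falls back to unconditional trimming bounds —
loudly, never silently — so conditioning can never widen the identified
set.

## Power retained after attrition

For a trial designed for 80% power on the full sample, the power retained
when only $N_{os}$ of $N_{fs}$ outcomes are observed is modelled as
$\Phi(\theta)$ with $\theta = 2.8\,(N_{os}/N_{fs}) - 1.96$: a ratio of 1
gives $\theta = 0.84$ and 80% power; 0.75 gives $\theta = 0.14$ and 56%.
The linear-in-the-ratio form is the package default because it reproduces
those anchor points exactly. A variant replacing the ratio with its square
root — the scaling suggested by the usual $\sqrt{n}$ behaviour of test
statistics — is available via `form = "sqrt"` for sensitivity analysis;
the two coincide at the no-attrition point.

## Numerical choices

- **Fractional trimming.** Removing mass $q$ of $n$ observations is
  generally non-integer (34% of 86 observations is 29.24). The default
  puts fractional weight on the order statistic straddling the
  $q$-quantile, matching the population trimming formula; this is
  permutation-invariant under ties by construction. An integer mode
  (remove $\lceil qn \rceil$ whole observations) exists for replicating
  implementations that round; the choice materially moves bounds, so it is
  an explicit argument, and replication attempts should run both.
- **Bound labeling.** The two tail-trimmed differences are computed and
  then *sorted* into lower/upper, so no outcome direction convention is
  hard-coded (symptom scales improve downward, many outcomes upward).
- **Treatment coding.** Labelled treatment columns require an explicit
  `treated_level`; the package never infers which arm is treated, because
  a silent flip inverts every bound.
- **Robust inference.** All diagnostic regressions use HC1
  heteroskedasticity-robust covariance: trimmed and selected samples are
  not homoskedastic by construction. The balance regression is a linear
  probability model (the coefficients are not interpreted, only tested
  against zero).
- **Bootstrap.** Bounds uncertainty is a nonparametric bootstrap over
  participants, resampled within arm, recomputing the entire procedure —
  trimming shares included; for RFLB the conditioning scheme is held fixed
  and reapplied to each resample (the screen is a modelling decision, not
  a statistic to be re-estimated per replicate). The default interval is
  the *outer* interval (each bound extended outward by $z \cdot SE$),
  covering the whole identified set; an Imbens–Manski-style interval with
  the adjusted critical value (coverage for the parameter, not the set) is
  available via `ci_method = "imbens-manski"`. Replicates with degenerate
  attrition are dropped and counted; more than 20% dropped aborts with an
  instability error.
- **Degenerate inputs.** An arm with zero observed outcomes is a
  degenerate-attrition error (bounds undefined). Equal observed
  proportions give trimming share 0; the trimmed-arm label is then
  reported as `"control"` by convention and trimming is vacuous. If no
  feature improves the held-out Brier score, all normalized importances
  are 0 and nothing can be selected (the "maximum equals 1" normalization
  has no anchor in that degenerate case).
- **Conditioning-tree feasibility.** Splits are admitted only if both
  children keep at least `min_cell_obs` observed outcomes per arm
  (default 20), so every cell supports its own trimmed means; enforcing
  the constraint at split time is equivalent to growing and merging
  undersized leaves back. For user-supplied cells, undersized cells are
  pooled into an `".other"` cell (or the pooling can be disabled to get a
  hard error).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `ci_level` | 0.95 | conventional reporting level |
| `n_bootstrap` | 500 | SE stability at trial scale; raise for publication runs |
| `rf_settings$num_trees` | 500 | standard forest size; importance noise decays slowly beyond |
| `rf_settings$mtry` | $\sqrt{p}$ | classification default |
| `rf_settings$min_node_size` | 5 | classification default |
| `rf_settings$cv_folds` | 5 | held-out importance without halving the sample |
| `rf_settings$n_perm` | 3 | permutation repeats per fold, variance reduction |
| `rf_settings$benchmark_mode` | `"single"` | one uniform draw, as a single random benchmark variable; `"median5"` reduces benchmark noise |
| `rf_settings$selection_rule` | `"both"` | main *and* interaction importance must beat the benchmark |
| `tree_settings$max_leaves` | 4 | cells beyond a handful starve the per-cell trims at trial scale |
| `tree_settings$min_cell_obs` | 20 | each cell's trimmed means need support in both arms |

The importance measure is *held-out permutation* importance rather than
impurity importance: impurity importance is biased toward continuous
variables, which would rig the comparison against a continuous uniform
benchmark. The interaction benchmark is $T \cdot \text{benchmark}$ in the
same second forest — the construction of interaction importances was a
genuinely open design point, and explicit product features screened
symmetrically to the main screen is the simplest faithful reading.

## The synthetic generator

`trial_scenario()` draws covariates from per-covariate specs, builds the
control potential outcome as mean + standardized-covariate loadings +
Gaussian residual (the stated outcome SD is the *total* SD, loadings
included), adds a homogeneous additive effect for the treated potential
outcome, assigns treatment with fixed margins (exact arm sizes), and draws
both potential observation indicators $S(1), S(0)$ from a logistic index
on per-arm base rates, covariates, treatment-interactions and (for MNAR)
the standardized latent control outcome.

Monotonicity is *enforced by construction*: both indicators come from one
uniform draw per participant and the treated-arm probability is clamped to
the enforced direction. With continuous covariates a coefficient-sign
condition cannot guarantee one-directional effects (the logistic index
difference is unbounded), whereas clamping yields exactly zero
direction-flipped participants and keeps the never-attriter set
well-defined.

Mechanism labels constrain coefficients: MCAR forces all of them to zero
(arm base rates may still differ — attrition caused by assignment alone,
the pattern in the motivating trial); MAR allows covariate and interaction
terms; MNAR additionally allows outcome dependence.

Presets:

- `zerophobia_preset()` emulates the motivating acrophobia trial: 96/97
  participants, observed outcome moments 48.46 (24.33) treated and 74.68
  (21.55) control, attrition 40/96 vs 11/97 (trimming share ≈ 0.34),
  covariates gender, age and a baseline severity score correlated ≈ 0.5
  with the outcome. The two printed arm SDs differ, which a homogeneous
  effect with common noise cannot reproduce, so the preset uses
  arm-specific residual noise: increments are heterogeneous but
  mean-preserving and independent of attrition, leaving the never-attriter
  ATE equal to the stated effect in expectation. Attrition loads on
  assignment only, mirroring the trial's importance graph in which no
  background characteristic beat the random benchmark.
- `selective_attrition_preset()` re-simulates attrition to be jointly
  driven by assignment, gender and the continuous pre-score through
  treatment-interaction coefficients (−1.0 gender, −2.0 standardized
  pre-score, treated base rate 0.65 vs control 0.90), chosen so the
  treated arm loses roughly the same share of outcomes as the motivating
  trial but selectively — the regime in which conditioning tightens
  bounds and the screen should fire.
- `mnar_outcome_preset()` is a 1,000 + 1,000 trial whose attrition index
  loads on the latent outcome itself (coefficient 0.8) with monotone
  selection and a homogeneous effect, so the never-attriter ATE equals the
  stated effect *exactly* — the recovery target for coverage checks.

What the generator does **not** emulate: non-additive treatment-effect
heterogeneity correlated with attrition, item-level missingness,
longitudinal dropout patterns, measurement floors/ceilings, or clustered
randomization. Passing tests therefore demonstrate internal correctness of
the estimators under the stated mechanisms, not robustness to every
real-data pathology.

## Problem sizes used by the test suite

Property tests are sized to be decisive yet fast on one CPU: 1,000 random
vectors against the brute-force trimming oracle; 100 bounded-support
datasets for the containment sweep; 200 replications of the
2,000-participant outcome-MNAR scenario for never-attriter coverage
(observed: 100% coverage); 100 trial-scale MCAR replications for the
fallback regression (observed: fallback in well over half, each null
covariate selected in under half) and 50 interaction-MNAR replications for
tightening (observed: ≈ 25–30% mean width reduction, in line with the
≈ 35% single-draw example in the README). Balance-test size is checked at
500 participants per replication, where the robust Wald test's finite-sample
size sits inside the 99% binomial band around 5%.

## Known limitations

- The trimming estimand is the never-attriter ATE; it coincides with the
  full-population ATE only under extra assumptions (e.g. effect
  homogeneity).
- The monotonicity assumption is only partially testable (the balance
  check on the trimmed sample is necessary, not sufficient).
- The benchmark screen at trial scale (n ≈ 200) has limited power: weakly
  selective attrition may go undetected, in which case RFLB correctly
  falls back but the resulting bounds are simply the unconditional ones.
- Bootstrap outer intervals treat the two bound estimates separately; the
  Imbens–Manski option narrows them for parameter-level coverage but still
  relies on bootstrap normality.
- No regression-adjusted trimming variants and no quantile
  treatment-effect bounds are implemented.
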