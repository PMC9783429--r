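---
title: "Separating local adaptation from adaptive plasticity with dual-generation sympatric-allopatric tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating local adaptation from adaptive plasticity with dual-generation sympatric-allopatric tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadapt)
```

## The question and the experimental design

Populations can match their environment through **local adaptation**
(genetic differentiation that raises fitness at home) or through
**adaptive phenotypic plasticity** (an environmentally induced shift that
raises fitness in the inducing environment). A reciprocal
common-environment experiment can separate the two when each population is
assayed twice: once on individuals derived directly from the field
(phase `"field"`, e.g. generations G0/G1), and once on their descendants
after two generations in a shared laboratory environment (phase
`"common"`, e.g. G2/G3). A sympatric advantage that persists into the
common phase is attributed to genetic effects; an advantage present only
in field-derived individuals points to (grand)maternal or other plastic
effects.

`sadapt` implements the statistical machinery for such data: each record
is one rearing unit (a multi-medium choice arena or a single-medium vial)
by test environment, with a population label, the population's
environment of origin, the assay phase, and egg/adult counts. Three trait
types are supported, each with its conventional transform:

| trait | measurement | response | unit adjustment |
|---|---|---|---|
| preference | eggs laid per medium, choice arena | `log(eggs + 1)` | arena fixed block |
| fecundity  | eggs laid, no-choice vial | `log(eggs + 1)` | none |
| performance | egg-to-adult survival | `asin(sqrt(adults/eggs))` | log egg-density covariate |

Survival proportions above one (miscounted low-egg vials) are capped at
one and flagged rather than dropped, so a sensitivity re-run can exclude
them; performance vials with zero eggs have an undefined proportion and
are excluded with a warning. The `log(x + 1)` offset is a package choice:
zero egg counts occur in both assay types and the unit offset is the
standard count remedy; it is recorded in the trait specification.

## The dual-generation model

On the transformed scale the joint model for both phases is an ordered
fixed-effect decomposition (sum-to-zero contrasts throughout):

1. population quality (one level per population, shared across phases);
2. test-environment quality;
3. **genetic SA covariate**: the sympatric indicator (1 when the test
   environment equals the population's origin), residualized against the
   preceding blocks;
4. the origin x test interaction remainder;
5. field-phase deviations of the population effects (including the
   overall field-vs-common shift) and of the test-environment effects;
6. **plastic SA covariate**: field-phase indicator x sympatric indicator,
   centered against the main-effect and field-deviation blocks;
7. the field-phase interaction-deviation remainder;
8. the trait's unit adjustment (arena block or egg-density covariate).

Because the sympatric contrast is one direction inside the
`(J-1)(K-1)`-dimensional origin x test interaction space, entering it
*before* the interaction remainder gives it 1 df and leaves
`(J-1)(K-1) - 1` df of interaction remainder; with three environments
that is the familiar df pair (1, 3).

Two F statistics are formed from the sequential (Type I) mean squares:

- `F_genetic = MS(sa_genetic) / MS(interaction remainder)` tests for a
  sympatric advantage shared by both phases (local adaptation);
- `F_plastic = MS(sa_plastic) / MS(field interaction-deviation remainder)`
  tests for an additional field-only sympatric advantage (adaptive
  plasticity).

The denominators are the interaction remainders, not the model residual:
the SA contrast must be judged against the typical magnitude of
origin-by-environment idiosyncrasies, otherwise any strong but
non-sympatric interaction pattern would masquerade as adaptation. This
also reproduces the (1, 3) degrees of freedom a three-environment system
prints. A significant F with a **positive** estimate supports local
adaptation (genetic) or adaptive plasticity (plastic); negative estimates
indicate the maladaptive direction.

### Estimates are joint-fit coefficients

The reported SA estimates are the coefficients of the two SA covariates
in the *joint* least-squares fit of the full model (computed via
Frisch-Waugh partialling, with each interaction block reduced to the
remainder orthogonal to its SA column so the parameterization is full
rank). This matters: a purely sequential projection would attribute half
of a field-only sympatric bonus to the genetic term, because the genetic
SA column (constant across phases) overlaps the field-phase covariate.
With the joint-fit convention, noise-free data built with a genetic bonus
`s` and no plasticity return exactly `(genetic, plastic) = (s, 0)`, and a
pure field-phase bonus `b` returns exactly `(0, b)` — the package tests
pin both identities to machine precision. Standard errors scale the
coefficient variance by the F-test's denominator mean square, so the
estimate's uncertainty is judged against the same interaction yardstick
as the test.

### The phi statistics

The fraction of interaction variance attributable to the SA contrast is

```
phi = (MS_constrained - MS_free) / MS_constrained
```

where `MS_constrained` is the interaction mean square from an independent
refit with the SA column omitted (the interaction block then carries its
full `(J-1)(K-1)` df) and `MS_free` is the interaction-remainder mean
square with SA estimated. `phi` can be negative because the two mean
squares use different degrees of freedom; values near 1 mean the
interaction is almost entirely a sympatric-vs-allopatric pattern.

## Descriptive layers

- `effect_means()` residualizes the data against a nuisance-only model
  (population, test environment, unit adjustment — no SA, no interaction)
  and averages the residuals per origin x test cell: the common-phase mean
  is the genetic effect, the field-minus-common difference the plastic
  effect. The plastic interval treats the field-phase variance as
  plastic-plus-genetic noise and subtracts the common-phase variance; when
  the common phase is the noisier one the interval is reported as absent
  rather than imaginary. This construction is a reconstruction of the
  figure convention it supports, not a formal variance decomposition.
- `original_vs_alternative()` produces the per-population sympatric vs
  allopatric means (two allopatric points sharing one sympatric value in a
  three-environment system); points below the identity line indicate a
  sympatric advantage.
- `weighted_pearson()` computes the weighted product-moment correlation
  with a Fisher-z interval on the effective sample size
  `n_eff = (sum w)^2 / sum(w^2)`; population-level summaries are weighted
  by their total vial counts. `cross_generation_correlation()` and
  `preference_performance_correlation()` build the paired population
  means (raw per phase, residualized per trait, respectively) and
  delegate to it.

## The synthetic-data generator

`sim_config()` encodes the study conditions the package targets:
three environments (cherry, strawberry, blackberry), 9/3/13 populations
per origin (25 total), 8 rearing units per population per phase, one
record per unit x test environment, both phases. With 8 units per
population per phase this reproduces the scale of the motivating
experiment (roughly 540-600 vials per phase across 25 populations); one
egg count per vial is what a no-choice assay yields, so the
per-unit-per-environment replication defaults to one.

Link-scale effects are Gaussian: population quality (SD 0.5),
test-environment quality (SD 0.5), *two* independent double-centered
origin x test interaction surfaces — one shared across phases, one
confined to the field phase so that both F denominators face genuine
interaction noise under the null — (SD 0.25 each), unit effects (SD
0.25), and residuals (SD 0.5). The SA effects are added to sympatric
cells (both phases for genetic, field only for plastic). Families map the
linear predictor through the identity (normal; the trait value is emitted
directly), `exp` with Poisson egg counts (analyze as fecundity), or
`plogis` with Binomial adults out of Poisson-distributed egg counts
(analyze as performance; the varying egg counts make the egg-density
covariate meaningful). The SD defaults are package choices on the link
scale — main effects comparable to the residual, interaction and unit
effects half as large — fixed before any calibration experiment and kept.

Every dataset is a pure function of its config (seed included); replicate
streams in `estimate_fpr()`/`estimate_power()` are spawned from the
master seed by a single draw, so each replicate is independently
reproducible.

### What "detection" means in the simulation studies

A replicate counts as detecting local adaptation (or adaptive plasticity)
when the F test rejects at the nominal level **and** the SA estimate is
positive, mirroring the interpretive rule that only a significant
positive contrast supports adaptation. Under a symmetric null this
directional definition rejects at roughly half the nominal level, which
is what makes the tests conservative (about 2-3% at alpha = 0.05). The
raw two-sided rejection rate is available with `directional = FALSE`.

## Numerical choices

- All fits run through a block-wise Gram-Schmidt sequential decomposition
  (two orthogonalization passes per block). Columns whose norm falls
  below `1e-8` of their pre-orthogonalization scale are aliased with
  earlier terms; they are dropped and the block's df reduced.
- An F denominator below `1e-14` of the total mean square (noise-free
  data) is reported as an undefined F with a flag instead of an absurd
  ratio; the estimate and SE (then 0) are still returned.
- Arena/vial blocks are centered within population x phase, so
  between-unit differences in population mean stay in the population
  block and population quality remains identifiable.
- Unbalanced data use exactly the same construction; nothing downstream
  assumes orthogonality.
- If a dataset carries no sympatric-vs-allopatric contrast at all (e.g.
  every assay sympatric), the SA contrast is undefined and the design
  builders raise an explicit error rather than returning zero.
- With two environments the single-generation interaction remainder has
  0 df; the test errors and points to the dual test or more environments.

## Problem sizes used by the packaged studies

The test suite and the acceptance script run the calibration study at
1000 null replicates per condition (three families x balanced 8/8/8 and
unbalanced 9/3/13 layouts) and the power study at 300 replicates per
condition with design scales X1 and X10; these sizes give Monte-Carlo
standard errors around half a percentage point on a rate and finish in a
few minutes on one CPU.

## Known limitations

- **Unbalance plus strong interaction variance makes the F tests mildly
  liberal.** The sequential ANOVA weights cells by observation counts.
  With equal populations per origin, an isotropic random interaction
  surface loads the SA direction and the remainder directions equally and
  the F tests are exact (empirically about 2-3% directional false
  positives at alpha = 0.05). With 9/3/13 populations per origin the SA
  direction carries roughly 30% more interaction variance per df than the
  remainder, and the directional false-positive rate rises to roughly
  3.5-4.5% under the generator's default variance components. This is an
  intrinsic property of fixed-effects SA testing under unbalance, not a
  numerical artifact: it vanishes when the interaction SD is set to zero.
  Conclusions drawn from strongly unbalanced designs with large
  non-sympatric interaction variance should treat p-values near the
  threshold with caution.
- The generator emulates the study layout but idealizes real data: no
  missing cells, no temporal batch structure, no overdispersion beyond
  the link-scale Gaussian components, and interaction surfaces shared
  exactly by all populations of an origin. Passing calibration here shows
  the machinery is correct under the stated generative model, not that
  field data meet that model.
- The plastic-effect confidence intervals in `effect_means()` reconstruct
  a figure convention (variance differencing) and can be absent by
  design; they are descriptive, not inferential.
- No mixed-model variant is provided; the fixed-effects ANOVA route is
  deliberate (random-effect formulations inflate false positives in this
  setting and were out of scope).
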