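---
title: "Two-stage Bayesian mixing models for stream allochthony: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian mixing models for stream allochthony: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomix)
```

## The scientific problem

Stream food webs draw carbon from two basal pools: terrestrial
(allochthonous) inputs, chiefly leaf litter, and in-stream (autochthonous)
algal production. Bulk stable-isotope measurements (δ¹³C vs VPDB, δ¹⁵N vs
air, both in ‰) separate these pools because terrestrial C3 vegetation is
typically ¹³C-depleted relative to stream algae. Two obstacles stand
between raw measurements and a statement such as "consumers assimilate
X% of their carbon from leaf litter":

1. **The algal endmember is never measured directly.** Field-sampled
   biofilm is a composite of algae, microbes and trapped detritus, so its
   signature is itself a mixture of the algal and terrestrial endmembers.
2. **Consumers fractionate.** Tissue is enriched relative to diet by a
   trophic enrichment factor (TEF) per trophic step, and the number of
   steps (the trophic level) is unknown.

`allomix` addresses both with two linked Bayesian models, applied per
watershed land-use category (forest, coffee plantation, pasture; forest is
the baseline throughout).

## Stage 1: unmixing the algal endmember from biofilm

Per land use *j* and tracer *t*, each biofilm observation is modelled as

δ_P ~ Normal( δ_A[j,t] · (1 − Φ_T[j]) + δ_T[j,t] · Φ_T[j], σ_t ),

where δ_A is the latent algal endmember, δ_T the terrestrial endmember
(taken as the per-land-use leaf-litter sample mean — litter is a measured
source), and Φ_T the terrestrial fraction of biofilm. Land-use structure
is additive on the baseline:

- δ_A[j,t] ~ Normal( δ_f[t] + β_c[t]·[j = coffee] + β_p[t]·[j = pasture], σ_δt ),
  with each non-forest category receiving only its own indicator offset;
- Φ_T[forest] = Φ_f, Φ_T[coffee] = Φ_f − α_c, Φ_T[pasture] = Φ_f − α_p.

Priors: the forest endmember δ_f gets the informative literature prior
(δ¹³C ~ N(−23.72, 4.10), δ¹⁵N ~ N(4.10, 3.13), summarising published algal
measurements in tropical streams); β and α offsets are N(0, 1);
Φ_f ~ Uniform(0, 1). The additive fraction parameterization can
push Φ_T outside [0, 1], so the joint prior is truncated to the region
where every Φ_T lies in [0, 1] (log-posterior −∞ outside). This keeps the
printed additive structure while guaranteeing interpretable fractions.

Two scale priors are not dictated by the model statement and were chosen
once, on the ‰ scale of the data: σ_t ~ half-Normal(0, 10 ‰) for the
biofilm likelihood and σ_δt ~ half-Normal(0, 5 ‰) for the endmember scale
— weakly informative relative to observed biofilm SDs (1.5–9.7 ‰).

Φ_T is shared between the two tracers within a land use by default: one
biofilm has one physical composition. Per-tracer fractions are available
(`share_phi = FALSE`) because the alternative reading — independent C and
N unmixing — is also defensible; the default is the physically motivated
one.

## Stage 2: consumer source apportionment

Per consumer taxon × land-use cell, tracer *t* and observation *i*:

δ_{t,i} ~ Normal( Σ_s Φ_s · (δ_{t,s} + Δδ_t · L), σ_c,t ),

with Φ a simplex of source proportions over the ordered sources (default
leaf litter, algae), L the latent trophic level, Δδ_t the TEF, and
δ_{t,s} latent source signatures. Priors: Φ ~ Dirichlet(1, …, 1);
L ~ Uniform(0, 10); Δδ¹³C ~ N(0.39, 1.14) and Δδ¹⁵N ~ N(3.4, 0.9)
(literature per-step fractionation); δ_{t,s} ~ Normal(source prior), where
leaf-litter priors are the measured litter mean/SD per land use and algal
priors are the stage-1 posterior mean/SD. σ_c,t ~ half-Normal(0, 3 ‰),
chosen once at the scale of observed consumer SDs (0.4–4.1 ‰). C and N
are fit jointly per cell (shared Φ and L); cells are fit independently —
no pooling across taxa or land uses, mirroring a per-cell reporting
format.

The two stages are linked by **cut inference**: the stage-1 algal
posterior is collapsed to a mean and SD and treated as a fixed prior in
stage 2, with no feedback. This matches the "estimate, then pass the
values on" workflow and keeps stage-2 cells embarrassingly independent.

A three-source variant (adding bulk biofilm) is available through
`build_source_sets(..., biofilm_rows = )`. It exists because published
per-cell litter and algae means from such two-source fits often do not
sum to 1, suggesting either a third implicit source or non-complementary
reporting; with only two named sources the package defaults to the
two-source model and leaves the variant to the analyst.

## Posterior simulation

`sample_posterior()` is a gradient-free adaptive random-walk
Metropolis-within-Gibbs engine: each iteration sweeps the coordinates with
per-coordinate Gaussian proposals (scales tuned to 20–40% acceptance in
warm-up batches of 50) and then makes one multivariate random-walk move
whose proposal covariance is the running warm-up covariance of the chain
(Haario-style adaptive Metropolis), scaled toward 25% acceptance. All
adaptation freezes when sampling starts, preserving detailed balance.
Constrained parameters are sampled through bijections — log for scales,
logistic for intervals, stick-breaking for simplexes — with exact
log-Jacobians.

Mixing-model posteriors are ridge-shaped: proportions trade off against
enrichment and latent signatures almost deterministically when residual
noise is small. A plain random walk on the full parameter vector mixes
poorly there, so both fits exploit the models' conditionally Gaussian
structure instead of walking the full space:

- **Stage 2** integrates the latent block (source signatures and the
  accumulated enrichment shift e_t = Δδ_t · L) out of the likelihood
  analytically — the cell's observations are then exchangeable normal —
  and samples only (Φ sticks, L, σ_c). The latent block is reconstructed
  for every stored draw by its exact conjugate (Kalman-update) Gaussian
  conditional.
- **Stage 1** does the same with the Gaussian endmember block
  (δ_f, β_c, β_p, δ_A per tracer), sampling only the fractions and scales
  (Φ_f, α_c, α_p, σ, σ_δ).

The sampled marginals are 4–10 dimensional and nearly ridge-free; split
R-hats land near 1.00 with effective sample sizes in the hundreds to
thousands at 4 chains × 5000 iterations. The collapsed targets are the
exact marginals of the stated joint posteriors; the test suite verifies
this against deterministic grid integration on reduced models (≤ 2%
relative error on posterior means and SDs) and against a direct
random-walk fit of the full joint density.

Reproducibility: chain *c* is seeded with `seed + c − 1`; stage-2 cells
derive per-cell seeds as `seed + 1000·(cell − 1)`; the conjugate
reconstruction uses its own fixed offset stream. Identical seeds give
bit-identical draws, diagnostics and reports.

## Diagnostics

`split_rhat()` implements the classic split-chain potential scale
reduction factor (rank normalization available by flag, off by default —
the split variant predates rank-normalized refinements and matches the
conventional R̂ < 1.1 gate applied here). `effective_sample_size()` uses
multi-chain autocovariances with Geyer's initial-positive-sequence
truncation. `convergence_report()` gates a fit on the maximum finite R̂;
fits never fail silently — a failed gate is carried in the result and in
`algal_summary()` warnings.

## The synthetic-data generator

No raw per-individual data are public, so the package carries two
generative routes:

- `generate_from_summary()` resamples each printed summary row (mean, SD,
  n) as independent normals per tracer. `make_study_fixture()` applies
  this to the bundled study summary table (2 resources + 10 consumer taxa
  × 3 land uses, per-cell n as printed, 422 observations at seed 1).
  Tracers are drawn independently because printed tables report only
  marginal moments — no C–N covariance can be emulated, and none is
  claimed.
- `simulate_stage1()` / `simulate_stage2()` forward-simulate from the two
  model equations with known truth, for parameter-recovery tests. The
  biofilm simulator defaults to mixing against the litter *mean* (the
  two-endmember mean-mixture reading); mixing against per-observation
  litter draws is available (`litter_mode = "draw"`) since the model
  statement does not fix that choice.

What passing tests on these data do **not** show: robustness to C–N
covariance, within-stream hierarchical structure, seasonality, lipid
effects, or non-normal residuals — none of which the generator emulates.
Fixture-based results are structural checks (the machinery recovers what
the model family can express), not re-measurements of the field system.

## Numerical choices and degenerate inputs

- Posterior modes: Gaussian KDE with Silverman's rule-of-thumb bandwidth
  on a 512-point grid spanning the draw range, clipped to [0, 1] for
  proportions; constant draw vectors short-circuit to their value.
- Credible intervals: empirical type-7 (linearly interpolated) quantiles,
  2.5–97.5% by default.
- Overlap coefficient: ∫ min(f, g) by trapezoid rule on a shared grid
  (KDE for draw samples, closed-form normal for the comparison density).
  The operator is symmetric and shift-invariant; with finite samples the
  KDE side carries Monte-Carlo error of order 10⁻², so tests assert
  symmetry at that scale.
- Missing tracer values are carried as NA and dropped per-tracer in
  likelihoods; δ sanity ranges (δ¹³C ∈ [−60, 0], δ¹⁵N ∈ [−20, 30]) warn
  but never reject, because real biofilm spreads (SD up to 9.7 ‰) produce
  legitimate outliers.
- `sd = 0` summary rows are accepted with a degenerate-spread warning and
  generate constant draws.
- A land use with litter but no biofilm data aborts stage 1 unless
  `allow_prior_only = TRUE`, in which case its algal endmember is
  reported as the exact no-data posterior of the collapsed (direct-prior)
  model: independent draws from the literature prior. Under the full
  hierarchy the no-data marginal would be the prior convolved with the
  endmember scale — wider than the prior itself — which is not what a
  prior-only report should carry forward into stage 2.

## Problem sizes

The test suite fits the full 30-cell study fixture at 4 chains ×
500–800 post-warmup iterations per target — sizes at which the collapsed
samplers already reach per-parameter effective sizes in the hundreds —
and runs recovery sweeps at n = 50–200 observations per cell with 50
replicate simulations for interval calibration. The acceptance script
uses the study protocol itself: 4 chains × 5000 post-warmup iterations
for every fit.

## Known limitations

- Two (optionally three) sources; no concentration dependence, elemental
  C:N weighting, isotope routing, or lipid normalization.
- No hierarchical pooling across taxa, streams or seasons; cells are
  independent by design.
- The terrestrial endmember in stage 1 is the litter sample mean;
  litter-mean uncertainty is not propagated by default.
- The engine is serial; chains run one after another.
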