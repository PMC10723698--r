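# allomix

Two-stage Bayesian stable-isotope mixing models for quantifying
**allochthony** — the reliance of stream consumers on terrestrial (leaf
litter) carbon as opposed to in-stream algal carbon — from bulk δ¹³C and
δ¹⁵N measurements. Written for trophic ecologists working with the
standard field design: basal resources (biofilm, leaf litter) and
consumer taxa sampled across land-use categories (forest, coffee
plantation, pasture), with forest as the baseline.

## The model

Two obstacles sit between raw isotope tables and "consumers assimilate
X% of their C from leaf litter": the algal endmember is never measured
directly (field biofilm is itself an algae/detritus mixture), and
consumer tissue is shifted from its diet by trophic fractionation.
`allomix` handles both with linked Bayesian stages:

**Stage 1 — algal endmember estimation** (`fit_stage1()`). Per land use
*j* and tracer *t*, biofilm is a two-source mixture

> δ_P ~ N( δ_A[j,t] (1 − Φ_T[j]) + δ_T[j,t] Φ_T[j], σ_t )

with leaf litter as the measured terrestrial endmember δ_T, a latent
algal endmember δ_A ~ N(δ_f + β_c + β_p, σ_δ) carrying additive land-use
offsets on an informative literature baseline
(δ¹³C ~ N(−23.72, 4.10), δ¹⁵N ~ N(4.10, 3.13)), and terrestrial fractions
Φ_T built additively from Φ_f ~ U(0,1) with N(0,1) offsets, truncated so
every Φ_T ∈ [0, 1].

**Stage 2 — consumer source apportionment** (`fit_stage2()`). Per
consumer taxon × land-use cell,

> δ_{t,c} ~ N( Σ_s Φ_s (δ_{t,s} + Δδ_t · L), σ_c )

with source proportions Φ ~ Dirichlet(1, …, 1), trophic level
L ~ U(0, 10), trophic enrichment factors Δδ¹³C ~ N(0.39, 1.14) and
Δδ¹⁵N ~ N(3.4, 0.9), and latent source signatures drawn from the litter
data (leaf litter) and the stage-1 posterior (algae) — cut inference, no
feedback. C and N are fit jointly per cell.

Posterior simulation is an adaptive random-walk MCMC engine
(`sample_posterior()`) that exploits the models' conditionally Gaussian
structure: latent Gaussian blocks are integrated out analytically and
reconstructed with exact conjugate draws, so 4 chains × 5000 iterations
give split-R̂ ≈ 1.00 throughout. Convergence is gated at split-R̂ < 1.1
(`split_rhat()`, `effective_sample_size()`, `convergence_report()`).

A synthetic-data module makes the whole pipeline testable without any
download: `make_study_fixture()` rebuilds a study-like per-individual
dataset from the bundled summary table of a cloud-forest stream food-web
study (10 consumer taxa × 3 land uses, per-cell sample sizes as printed),
and `simulate_stage1()` / `simulate_stage2()` forward-simulate from the
model equations for parameter-recovery tests.

## Worked example

Simulate one consumer cell with known truth (80% leaf litter, trophic
level 2) and recover it:

```r
library(allomix)

src <- source_set(c("leaf_litter", "algae"),
                  mean = cbind(c(-32, -20), c(-1, 4)),  # d13C, d15N
                  sd   = matrix(0.5, 2, 2))
truth <- stage2_truth(phi = c(leaf_litter = 0.8, algae = 0.2), L = 2,
                      tef = c(0.39, 3.4), source_mean = src$mean,
                      source_sd = src$sd, sigma_c = c(0.5, 0.5))
ds  <- simulate_stage2(truth, n_consumers = 50, seed = 2)
fit <- fit_stage2(ds, src, cfg = mcmc_config(chains = 4, iterations = 2000,
                                             warmup = 2000, seed = 3))
build_cell_table(fit)
```

```
<stage2_fit> 1 consumer cells (1 passed the convergence gate)
  leaf_litter_mode leaf_litter_mean leaf_litter_lo leaf_litter_hi
1            0.745            0.744          0.426          0.985
  trophic_level_mean tef_d13C_mean tef_d15N_mean
1              2.215         0.048         3.284
```

The posterior mean litter contribution (0.744) recovers the simulated
0.8 within its credible interval (0.43–0.99); the trophic level (2.2)
and nitrogen TEF (3.3 ‰) sit near their true values 2 and 3.4 ‰. The
full study-style analysis — fixture simulation, endmember estimation,
30-cell mixing fits, biplot and overlap reports — is laid out as numbered
drivers under `analysis/` (run them in order from the repository root;
tables land in `results/`).

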