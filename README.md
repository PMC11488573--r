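# nfixpd — temporal change in nitrogen-fixer diversity from vegetation resurveys

`nfixpd` is an R package plus a scripted analysis workflow for asking
whether nitrogen-fixing plants are losing ground in plant communities that
have been censused twice, decades apart — and whether that loss tracks
cumulative nitrogen deposition rather than concurrent changes in
temperature and aridity. It is aimed at community ecologists and
phylogeneticists working with paired-survey (resurvey) data on permanent
plots.

## What it computes

**Diversity metrics.** For any species set *S* on a dated phylogeny:
Faith's PD (total branch length of the minimal subtree connecting *S* and
the root; a crown-based toggle exists), MPD (mean pairwise patristic
distance) and MNTD (mean nearest-taxon distance), with explicit
conventions for empty and single-species fixer sets (PD = 0 for the empty
set; MPD = MNTD = 0 for singletons). Species missing from the reference
tree are grafted at the genus or family level by deterministic,
ultrametricity-preserving rules.

**Per-plot change statistics.** For each plot with baseline and resurvey
species sets, the change in the fixer share of richness, in fixer Faith's
PD, and in the fixer share of total PD:

    Δ(PD share) = (PD_fixer / PD_all)_resurvey − (PD_fixer / PD_all)_baseline

**Environmental predictors.** Per site: cumulative N deposition over the
half-open between-survey interval (g N m⁻², last rate carried forward past
the end of the deposition series), and changes in 5-year moving means of
temperature and of the UNEP aridity index AI = P/PET.

**Inference.** Random-intercept linear mixed models fitted by profiled
REML (authored in-package, cross-checked against `nlme`):

    Δy = β₀ + β_N·cumN* + β_T·ΔT* + β_A·ΔAI* + β_B·baseline* + u_site + ε

with standardized predictors (asterisks), the baseline response as a
regression-to-the-mean covariate, containment-style degrees of freedom,
VIF screening and residual diagnostics. Guild comparisons (lost / gained /
conserved fixers) use the same machinery with reference-level refits
sharing one covariance estimate. Per-species fates give loss/gain
probabilities and the net plot-occupancy change
ΔP = (P_G − P_L)/(P_C + P_G + P_L), tested for phylogenetic signal with an
in-package Pagel's λ (cross-checked against `phytools`).

**Synthetic studies.** `simulate_dataset()` generates complete input sets
(Yule tree, clade-conserved fixer trait, site environmental trajectories,
paired occupancy surveys with deposition-dependent loss and site random
effects) under presets `paperlike`, `null` and `strong-signal`, fully
deterministic under a seed.

## Worked example: the scripted workflow

The analysis lives in five thin drivers under `analysis/`, each calling
package functions and writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic study system -> results/data/
Rscript analysis/02_derive.R        # change table, species fates, guild PD
Rscript analysis/03_models.R        # mixed models for all responses
Rscript analysis/04_guilds_signal.R # guild contrasts + Pagel's lambda
Rscript analysis/05_calibration.R   # slope recovery + type-I error checks
```

A run of the full configuration (53 sites, 1007 plots, 1500 species, seed
1234) prints:

```
Plots with >=1 fixer in either survey: 982
  of which >=2 fixers in one survey: 863 ; >=2 in both surveys: 481
Mean fixer richness: 3.09 (baseline) -> 1.69 (resurvey); 73 % of plots lost fixers.
Mean change in fixer Faith's PD: -143.9 My (SD 148.8 ).
N-deposition slope on delta_prop_rich: -0.00951 (SE 0.00116, p = 1.04e-15)
N-deposition slope on delta_pd: -52.51 (SE 8.41, p = 6.84e-10)
Faith's PD, conserved - gained: 80.58 My (SE 8.43, p = 3.99e-21)
Pagel's lambda for p_lost: 0.0000 (p = 1)
Slope recovery: mean estimate -0.01026 (truth -0.010), sign recovered 100%
Type-I error at nominal 5%: cum_n 0.033, delta_t 0.040, delta_ai 0.047
```

Reading this: fixer richness roughly halves between surveys and the
decline in the fixer share of richness steepens with cumulative
deposition (negative standardized slope β_N ≈ −0.01), exactly the effect
built into the generator; the fates of individual fixer species carry no
phylogenetic signal (λ = 0, p = 1) because losses are driven by
deposition, not clade identity; and the estimator is unbiased with
calibrated error rates.

Output tables: `results/change_table.csv` (one row per plot: responses,
baselines, predictors, filter flags), `results/species_fates.csv`
(PC/PL/PG, probabilities, ΔP), `results/guild_pd.csv`,
`results/model_estimates.csv` (response, variant, term, estimate, SE, t,
df, p), `results/guild_contrasts.csv`, `results/phylosignal.csv`,
`results/calibration.csv`.

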