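---
title: "Methods: quantifying temporal change in N-fixer phylogenetic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying temporal change in N-fixer phylogenetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfixpd)
```

## The scientific problem

Nitrogen-fixing plants hold a competitive advantage in nitrogen-limited
soils through their symbiosis with diazotrophic bacteria. Chronic
anthropogenic nitrogen deposition erodes that advantage, and long-term
vegetation resurveys — permanent plots censused decades apart — are the
natural data for asking whether nitrogen-fixer diversity has declined and
whether the decline tracks deposition rather than concurrent climate
change. `nfixpd` implements that analysis end to end: community
phylogenetic diversity on a dated phylogeny, per-plot change statistics,
environmental change predictors, random-intercept mixed models, species
fate statistics, and phylogenetic-signal tests — together with a
synthetic-data generator that produces complete study systems with known
ground truth, so every stage can be validated by simulation.

## Data model

Four inputs, all plain text:

* **Community table** (long CSV `plot,site,survey_role,year,species`):
  two censuses per plot. When a plot has several resurveys only the most
  recent is kept, so each plot contributes one baseline/resurvey pair.
* **Trait table** (`species,genus,family,is_fixer`): the fixer trait is
  assigned at the genus level — nodulation assessments are incomplete at
  the species level and the trait is strongly conserved within genera —
  and the validator enforces genus-constancy.
* **Phylogeny** (newick, branch lengths in My): a dated reference tree.
  Species observed in the plots but absent from the tree are grafted at
  the genus level where congeners exist, else at the family level.
* **Environmental series** (`site,year,n_dep,temp,precip,pet`): per-site
  annual deposition rate (g N m⁻² yr⁻¹), mean temperature (°C), annual
  precipitation and potential evapotranspiration (mm).

## Diversity metrics

Faith's PD is the total branch length of the minimal subtree connecting a
species set; the implementation is **root-inclusive** by default (the stem
path from the set's common ancestor to the root is counted), the
convention used by the standard community-phylogenetics packages, so a
single species contributes its full root-to-tip depth. The crown-based
alternative is available via `faith_pd(..., include_root = FALSE)`; the
choice shifts every survey's PD by the shared stem length and matters most
for small species sets. MPD is the unweighted mean patristic distance over
unordered pairs; MNTD the mean distance to each taxon's nearest neighbour
within the set. Conventions at the degenerate margins, chosen so that
change statistics remain defined when fixers vanish from a plot:

* empty fixer set: Faith's PD = 0, MPD/MNTD undefined (set to 0 in the
  change table, where a variant response needs them);
* single fixer: Faith's PD is the root-spanning value; MPD = MNTD = 0.

All metrics are computed directly from the edge matrix (pure functions,
double precision) and are tested against independent brute-force oracles:
an edge-set union over per-tip root paths for PD, explicit pair loops and
row minima over the cophenetic matrix for MPD/MNTD, and `picante` as an
external cross-check.

## Grafting unplaced species

Reference phylogenies never contain every recorded species. A missing
species with two or more congeneric tips is attached as a polytomy at the
genus crown node; with exactly one congener, the congener's pendant branch
is split at its midpoint and the new species attached as a cherry;
species whose genus is absent are placed the same way within their family.
The pendant length is chosen so the new tip's root-to-tip depth equals the
mean depth of its group's tips — on an ultrametric input the output stays
ultrametric (verified to 1e-9 in the tests). Placements are resolved
against the original tips before any surgery, so grafting order cannot
affect the result. Where within the genus a real placement should fall is
genuinely unidentifiable without sequence data; the crown-polytomy rule is
deterministic and is the natural reading of "added at the genus level",
but it is a modelling choice, and pruning-based analyses are insensitive
to it by construction (graft-then-prune recovers the original distance
matrix exactly).

## Environmental predictors

Three predictors per site and survey pair:

* **Cumulative N deposition** (g N m⁻²): the sum of annual deposition over
  the between-survey interval. The interval is half-open —
  `(baseline_year, resurvey_year]` — which avoids double-counting the
  baseline year and makes sums additive over abutting intervals; the
  closed-interval alternative is a function argument. Deposition models
  typically end before the most recent resurveys, so for years beyond the
  series end the last available rate is carried forward.
* **Temperature change** (°C): difference between 5-year moving means
  (survey year plus its four predecessors) at resurvey and baseline. The
  5-year window buffers single-year weather against the census date.
* **Aridity change** (dimensionless): same windows applied to the annual
  UNEP aridity index AI = P/PET (higher = wetter). AI is computed per
  year and then averaged, not computed from averaged P and PET.

## Per-plot responses and filters

For each plot: the change in the fixer share of richness, the change in
fixer Faith's PD, and the change in the fixer share of total Faith's PD
(resurvey ratio minus baseline ratio). Three nested plot filters mirror
what each response can support: richness needs at least one fixer in
either survey; PD needs at least two fixers in one survey (with the
single-fixer MPD/MNTD = 0 convention for the variant responses); a strict
subset demands two fixers in both surveys and drops the convention
entirely. Genus-level identifications (`..._sp.`) are retained by default
— they usually occur without congeners, so dropping them discards real
occurrences — with `drop_low_resolution = TRUE` as the sensitivity
switch.

## Mixed models

Each response is modelled as

y_plot = β₀ + β_N·cumN + β_T·ΔT + β_A·ΔAI + β_B·baseline + u_site + ε,

with standardized predictors (mean 0, SD 1; parameters recorded for
back-transformation), the response's baseline value as a covariate to
absorb regression to the mean, and a site random intercept. Estimation is
REML via the profiled likelihood in θ = σ²_site/σ²_resid: for one grouping
factor the marginal covariance is block diagonal, so V⁻¹ and log|V| have
closed forms and the fit is a bounded one-dimensional search (Brent-type,
relative tolerance 1e-8, method-of-moments start, explicit θ = 0 endpoint
check) with an analytic GLS inner solve. This keeps the fit fully
deterministic and dependency-free; `nlme::lme` reproduces the estimates to
1e-6 in the test suite. t-tests use containment-style degrees of freedom
`n_obs − n_groups − (p − 1)`; exact small-sample df rules differ across
mixed-model software, so printed p-values are conventions, not
bit-targets. Collinearity is screened with VIFs (1/(1−R²) from regressing
each predictor on the others); residual screening reports standardized
residuals beyond 4 SD and per-site leave-one-out slope changes but never
drops data. Because ΔPD takes both signs, the transformed variant uses the
signed cube root `sign(x)|x|^{1/3}` — odd, monotone, zero-preserving.

Guild comparisons (lost / gained / conserved fixers per plot) use the same
machinery with guild as the fixed effect. All three pairwise contrasts are
read off by refitting under each reference level; the variance components
are estimated once under a canonical level ordering and shared across
refits, which makes shared contrasts agree to machine precision rather
than to optimizer tolerance.

## Phylogenetic signal in species fates

For each fixer species, the plots where it was conserved (PC), lost (PL)
and gained (PG) give a loss probability PL/(PC+PL+PG), a gain probability
PG/(PC+PL+PG), and the net plot-occupancy change
ΔP = (PG − PL)/(PC + PG + PL) ∈ [−1, 1]. The denominator counts plots
where the species occurred in at least one survey; the alternative
(baseline-occupied plots only, for the loss probability) is an option.
Pagel's λ for each statistic multiplies the off-diagonal entries of the
Brownian covariance matrix; the mean and rate are profiled out
analytically and λ is maximized on [0, 1] by a golden-section/parabolic
search with explicit endpoint checks (boundary ties resolve to the
endpoint). Significance is a likelihood-ratio test against λ = 0 on χ²₁,
with p = 1 reported when λ̂ sits at the zero boundary — the natural
statement that no signal was detectable. Star trees make the likelihood
flat in λ and are reported as degenerate with a warning; constant traits
are an error, not a λ of convenience.

## The synthetic generator

`simulate_dataset()` draws, under one seed and in fixed order: a Yule
(pure-birth) tree rescaled to a 150-My crown; fixer status as a union of
whole clades (default 5 clades, ~5% of species) with genus/family labels
cut from tree depth so the trait is genus-constant; per-site survey years
(resurveys 1995–2019, intervals ~44 ± 15 years); environmental series; and
paired surveys. The `paperlike` defaults encode the study conditions the
generator emulates: 53 sites × 19 plots, a 1500-species pool, baseline
plots holding ~3 fixer species among ~50 (≈6–7%), an exponential
deposition ramp whose rate grows e^0.055/yr — roughly a tenfold increase
over a 44-year interval — a warming trend of 0.025 °C/yr, and stationary
precipitation/PET. Loss operates on presence, not abundance:
`logit P(lost) = a + β_fixer·cumN·1[fixer] + β_nonfixer·cumN·1[non-fixer]
+ u_site`, with defaults (a = −1, β_fixer = 0.03, β_nonfixer = 0.006 per
g N m⁻², σ_site = 0.5) chosen once so that roughly three-quarters of plots
lose fixers and fixer richness roughly halves over a typical interval;
gains are background colonization with an optional aridity-linked term for
fixers. The `null` preset zeroes both deposition coefficients (site
effects remain) and `strong-signal` doubles the fixer coefficient.

What the generator deliberately does **not** emulate: spatial structure
and dispersal, observer and census-effort differences between surveys,
abundance dynamics, species' environmental niches beyond the deposition
response, and non-monotone deposition histories (real European deposition
peaked around 1990; the generator's ramp is monotone). Passing tests
therefore demonstrate that the estimators are correct and calibrated for
data of this structure — unbiased slope recovery, ~5% type-I error,
λ discrimination — not that any particular field dataset satisfies the
model.

## Numerical and design notes

* Name matching treats spaces and underscores as equivalent and is
  otherwise case-sensitive; trees with missing or negative branch lengths
  are rejected outright rather than defaulted.
* Zero-length branches are legal input (encoded polytomies) and preserved.
* Newick output always carries branch lengths, at 9 significant digits.
* The REML optimum is checked against the θ = 0 boundary explicitly, and
  an optimum pinned at the search ceiling triggers one interval expansion
  before being flagged as non-converged.
* Degrees of freedom, the deposition interval convention, the fate
  denominators, low-resolution handling and the PD root convention are
  all explicit arguments, so the sensitivity of any conclusion to these
  conventions can be probed directly.

## Problem sizes used in validation

The test suite validates metrics on 100 random trees of up to 40 tips
against brute-force oracles (tolerance 1e-9); slope recovery on 200
replicates of 50 sites × 20 plots at a true standardized slope of −0.010;
type-I error on 400 end-to-end null replicates of 50 sites × 6 plots ×
250 species (3σ binomial band around 5%); and λ recovery on 12 pairs of
Brownian/independent traits on 200-tip trees. The analysis scripts under
`analysis/` run the full 53-site, ~1000-plot configuration once and
smaller calibration batteries; these sizes are the package's validation
design and can be scaled up by editing the replicate counts.

## Worked example

```{r example}
sim <- simulate_dataset(sim_config("paperlike", seed = 42L,
                                   n_species = 300L, n_sites = 15L,
                                   plots_per_site = 8L,
                                   fixer_fraction = 0.1))
ec <- env_change_table(sim$env, sim$site_years)
ct <- build_change_table(sim$pairs, sim$traits, sim$tree, ec)
m <- fit_all_models(ct, responses = "delta_prop_rich")
m[m$term == "cum_n", c("estimate", "se", "t", "df", "p")]
```

A negative `cum_n` coefficient at this scale reflects the simulated
fixer-specific deposition penalty; under the `null` preset the same
pipeline returns slopes centred on zero.

## Known limitations

* A single random intercept only: no crossed or nested random effects, no
  random slopes, no spatial or temporal autocorrelation.
* λ is fitted to the raw fate proportions; these are bounded and
  heteroscedastic (species occupying few plots have noisier proportions),
  which the Gaussian likelihood ignores.
* Containment df is one defensible convention among several; inference
  near p ≈ 0.05 should not hinge on it.
* The grafting rules guarantee ultrametricity and determinism, not
  phylogenetic truth; analyses that depend on exact within-genus
  placement of grafted species should treat those placements as noise.
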