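---
title: "Models and methods in phenogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phenogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phenogs` is a simulation and analysis toolkit for UAV-assisted winter-wheat
breeding: it generates complete synthetic trial seasons with known genetic
ground truth, extracts vegetation-index (VI) features from 5-band canopy
reflectance, estimates line BLUEs and broad-sense heritability, fits
single-trait (ST) and multi-trait (MT) GBLUP models by Gibbs sampling, runs
the ST-CV1 and MT-CV2 cross-validation schemes, and trains a feedforward
deep network for phenomic prediction of grain yield (GY), test weight (TW)
and grain protein content (GPC). This vignette documents the models, the
tunable parameters, and the design decisions behind each stage.

## The synthetic-data generator

Every downstream method is exercised on data from `sim_config()` /
`simulate_dataset()`, which emulate a two-location hard-winter-wheat season:
an ELITE nursery (36 lines, RCBD, 3 replicates), an AYT nursery (126 lines,
RCBD, 2 replicates), both at two locations, and a preliminary (PYT) nursery
of 590 unreplicated lines plus 7 repeated checks in an augmented design with
22 blocks at the first location, genotyped at ~10k SNPs and overflown at
Feekes stages 6 (jointing), 8 (flag leaf), 10 (booting) and 11 (milky ripe).

**Genotypes.** Marker allele frequencies are uniform on the configured MAF
range (default 0.05–0.5) and dosages are binomial(2, p): unlinked loci in
Hardy–Weinberg proportions. There is deliberately *no* linkage
disequilibrium, pedigree structure, dominance or epistasis. A consequence
worth stressing: with unlinked markers the panel size *is* the effective
number of independent chromosome segments, which governs genomic prediction
accuracy. A 10k-marker unlinked panel therefore behaves like an unrealistically
polygenic genome, not like a real 10k SNP array (whose markers are strongly
correlated along chromosomes). Prediction experiments in the test-suite and
acceptance script use ~150-marker panels, emulating the effective segment
count of a dense wheat panel at these population sizes; shape parameters
(sample sizes, replicate structure) stay at trial scale.

**Genetic values.** Marker effects are multivariate normal across traits
with covariance proportional to the configured genetic correlation matrix —
an infinitesimal model chosen to match the GBLUP assumptions of the fitters,
so that recovery tests are well-posed. Breeding values are the centered
dosage matrix times the marker effects, rescaled per trait so the genetic
variance hits `h2 * phen_var` exactly (the same factor is applied to the
marker effects, preserving the additive identity). Default targets: h² =
0.5 (GY), 0.7 (TW), 0.45 (GPC) — GY and GPC less heritable than TW — with
genetic correlations +0.3 (GY,TW), −0.3 (GY,GPC), +0.1 (TW,GPC), the classic
weak negative yield–protein antagonism. These are package choices of
realistic magnitudes, not estimates from any particular dataset.

**Field phenotypes.** Each plot is
y = µ_t + location + block + g + (g×location) + e, with the residual plot
variance set from the heritability target and the trial's replicate count,
σ²_e = nRep · σ²_g (1 − h²)/h², so the *entry-mean* broad-sense
heritability matches its target. Trait means/SDs (GY 4500 ± 600 kg/ha,
TW 76 ± 2, GPC 12 ± 1%) put plots on familiar scales. Random-effect SDs
default to 0.25 (replicate/block), 0.3 (location) and 0.15 (g×location),
as fractions of the trait SD.

**Canopy reflectance.** Per plot and flight, a latent canopy vigor
v = loading(stage) · z + baseline(stage) + ε squashes through a logistic
s = σ(v), where z is the line's standardized GY breeding value and
ε ~ N(0, 0.3²). Bands are monotone affine maps of s, clipped to [0, 1]:
NIR = 0.25 + 0.35 s, Red = 0.25 − 0.18 s, Green = 0.12 + 0.08 s,
Blue = 0.06 + 0.04 s, RedEdge = 0.18 + 0.10 s. NIR rises and Red falls with
vigor, so NDVI-type indices increase with GY merit with stage-controlled
strength; senescence/water indices (PSRI, NDWI, IKAW) fall, matching their
field behavior. Default loadings 0.3 / 0.8 / 0.8 / 0.6 and baselines
−0.5 / +0.25 / +0.5 / 0 across Feekes 6/8/10/11 give the
mid-season-strongest correlation pattern typical of yield trials; both are
free parameters. At zero noise and loading 1 the logistic map is close
enough to linear that Pearson r(NDVI, GY breeding value) ≈ 0.99, and rank
correlation is exactly 1.

Because the latent vigor loads on the GY breeding value only, TW and GPC
are spectrally visible solely through their genetic correlation with GY:
phenomic accuracy for those traits on synthetic data is bounded near
|r_g(trait, GY)| and lands close to zero — a property of the generator, not
of the network.

What the generator does *not* emulate: LD and population structure, spatial
field trend, weather/soil processes, sensor calibration error, and any
location-specific reflectance signature. Tests passing on these simulations
therefore validate the estimators' internal consistency and the schemes'
relative ordering — not field-data performance.

## Vegetation indices

`vi_registry()` pins 20 indices computable from the five Altum-PT bands
(blue, green, red, red_edge, nir), each with its standard literature
definition and citation: NDVI, GNDVI, GCI, RECI, RVI, RVI_2, ARI, ARI_2,
PSRI, IKAW, NDWI, SAVI, SAVI_2, OSAVI, ENDVI, EVI, EVI_2, MCARI, TCARI and
TCARI/OSAVI. Where the literature carries variants (RVI_2, SAVI_2), the
registry records one explicit choice and `register_index()` makes an
alternative a one-line change. Denominators below 1e−9 in absolute value
yield NA for that record rather than a silent infinity. Normalized
differences are bounded in [−1, 1] and antisymmetric under band swap; pure
band ratios are invariant to a positive rescaling of all bands, which the
registry records per index (`ratio` flag).

`build_feature_matrix()` pivots the VI table to one row per plot with
`<index>_<stage>` columns (20 × 4 = 80 features for all flights), joining
plot-level targets and dropping incomplete plots with a logged count.

## BLUEs and heritability

Per trait, `fit_blues()` fits y = µ + block + genotype + e with genotype
fixed and block-within-trial random (the replicate of an RCBD, the
incomplete block of an augmented design — in the augmented case the
repeated checks estimate the block effects, and unreplicated entries are
block-adjusted, the standard augmented-design analysis).
`estimate_heritability()` refits with genotype random and environment
(location/trial/block) fixed, and reports
H² = σ²_g / (σ²_g + σ²_e / nRep) on the entry-mean basis.

Both models have a single random effect, so instead of a general mixed-model
engine the package profiles the REML criterion over the one variance ratio
λ = σ²_u/σ²_e and minimizes it by bounded scalar search on log λ
(interval 1e−10 to 1e8). Because the random effect is a single grouping
factor, Z′Z is diagonal and the Woodbury identity reduces every quantity to
per-group sums — fits are O(groups), not O(plots³). Fixed effects come from
the GLS back-solve at the optimum. Negative variance components cannot
occur; a boundary optimum (λ at 1e−10) is truncated to σ²_g = 0 and
flagged with a warning, as is any single-replicate fit. The test-suite
cross-checks both estimates against lme4 to ~1e−4.

With several locations the default fits each location separately and
averages per-line BLUEs (`combine = "per_location"`); a joint fit with
location fixed is available (`combine = "combined"`). Which pooling a given
field program uses is a program choice; both paths are first-class.

## Genomic prediction

**QC and GRM.** `qc_filter()` removes markers with >30% missing calls,
MAF <5% (both strict inequalities — a marker at exactly 30% or exactly 5%
survives) or no chromosome assignment; `impute_mean()` fills remaining
gaps with marker means. `compute_grm()` centers each marker and scales to
unit variance using the population (1/n) denominator, then G = XX′/p; this
makes the diagonal mean exactly 1 and G invariant to allele-coding flips.
The VanRaden 2p(1−p) denominator is available via `scale = "vanraden"`.
Standardized-marker GRMs with n > p are singular; eigenvalues below 1e−8
are treated as zero-variance directions, and explicit inverses (only in the
kriging extension) add a 1e−8 ridge.

**Single-trait model.** y = 1µ + g + e with g ~ N(0, σ²_g G). The Gibbs
sampler uses conjugate updates — normal for µ and g, scaled-inverse-χ²
(df 5, scale putting the prior mode at half the phenotypic variance) for
both variances. Writing G = U D U′ and h = U′g, the full conditional of h
is diagonal, so a sweep is a handful of vectorized operations; the
closed-form solution at fixed variances (`st_gblup_closed_form()`) is the
deterministic oracle the sampler is tested against (posterior-mean GEBVs
correlate ≥0.98 with the oracle; with variances frozen, RMS discrepancy
<0.01 at 20k draws). Reference chain lengths are 25,000 iterations with
5,000 burn-in.

**Multi-trait model.** vec(g) ~ MVN(0, Σ ⊗ G) with unstructured Σ and
diagonal R. The trait dimension is diagonalized per sweep by a generalized
eigendecomposition of Σ against R (whiten by R^{−1/2}, eigendecompose,
rotate), so the n×t genetic update is again fully vectorized. Σ has an
inverse-Wishart full conditional (df = t + 4, prior scale at half the
phenotypic covariance); R updates per trait by scaled-inverse-χ². Missing
entries — the masked primary trait of MT-CV2 validation lines — are imputed
by data augmentation each sweep, so masked lines receive posterior-mean
genetic values directly rather than by row deletion. Reference chains:
15,000 iterations, 5,000 burn-in. With Σ truly diagonal the MT fit
reproduces independent ST fits (r ≥ 0.97), and with genetic correlation
0.8 planted the posterior-mean correlation recovers it within ±0.15.

Thinning defaults to 5 (bounds chain storage without biasing means). All
draws go through R's RNG, so chains are bit-reproducible given the seed.

## Cross-validation schemes

`cv_scheme()` draws line-level 80/20 splits (training size = floor(0.8 n) —
a deterministic rounding rule), 100 replicates for ST-CV1 and 50 for MT-CV2
by default. ST-CV1 masks validation lines entirely: the ST model is fitted
on the training block of G and extended to masked lines by the conditional
mean of the joint model, ĝ_test = G_te,tr G_tr,tr⁻¹ ĝ_tr. MT-CV2 masks only
the primary trait; HTP covariates stay observed for everyone and the MT
model is fitted on all lines at once. Predictive ability is the Pearson
correlation between predicted genetic values and held-out observations.

Two pragmatic choices: replicate splits derive deterministically from the
scheme seed, so CV1 and CV2 runs sharing a seed are paired on identical
splits (variance reduction for scheme comparisons); and chains inside CV
loops default to 6,000 iterations / 2,000 burn-in — the oracle-equivalence
tests confirm the shortened chains reproduce posterior means, and full-length
chains remain one argument away.

## The phenomic deep network

The predictor is a feedforward fully connected network — default five
hidden layers of 64/128/256/512/1024 units — with each hidden layer ordered
dense → batch normalization → ReLU → dropout (rate 0.3), a single linear
output unit per trait, MSE loss and Adam (default learning rate 1e−3,
with {1e−2, 1e−3, 1e−4} the recommended search). Hidden layers use the
rectifier and the output is linear: the identity activation belongs to the
regression head only. One single-output model per trait is the default; a
multi-output head is available through `n_outputs`. The implementation is
plain R matrix code inside the package — forward pass, backpropagation
(including the batch-norm gradient), inverted dropout and Adam — which keeps
training bit-reproducible under a fixed seed in this single-threaded
setting.

Plots split 70/30 at random (no stratification by trial or location);
features are z-scored with parameters fit on the training split only, and
applied unchanged to any test data — including the forward-prediction
scenarios, where the model trains on all advanced-trial plots and predicts
preliminary-trial plots at plot level. There is no early stopping: the
epoch count is a tuned hyperparameter (`dnn_tune()` searches epochs ×
batch size on a validation fifth carved from the training split, breaking
ties toward fewer epochs, then smaller batches). Evaluation-mode inference
freezes batch-norm running statistics and disables dropout.

Metrics follow the usual regression conventions with one deliberate
particularity: RMSE uses the n − 1 denominator (and RMSE% = RMSE/ȳ·100),
which a regression test pins against the naive 1/n form.

Desk-scale note: the architecture is configurable, and the test-suite and
acceptance script run compact variants (e.g. 64-32 hidden units, ≤150
epochs, 80 features, a few hundred plots) so the whole stack trains in
seconds per model; the full-width default remains available.

## Problem sizes and numerical choices

The shipped checks use: 100–200 lines and 150–1000 markers for the Gibbs
samplers (150-marker panels wherever a *realistic* predictive ability
matters, per the effective-segment argument above); 50 simulation seeds for
heritability recovery; 20 seeds for Σ recovery; 30 paired CV replicates for
the scheme comparison; 500 plots for the network sanity checks; and 10–20
seeds for the forward-prediction contrast. Degenerate inputs are rejected
loudly (empty panels after QC, monomorphic markers, non-PSD correlation
targets, zero-variance traits, sub-3-line test sets); near-singular
matrices get explicit ridges (1e−8) rather than silent pseudo-inverses; VI
division guards return NA below |denominator| < 1e−9.

## Known limitations

The generator's idealizations (no LD, no spatial trend, no
location-specific spectral signature) mean absolute accuracies here do not
forecast field performance; what transfers is the ordering of schemes and
stages under shared conditions. The MT sampler assumes diagonal R, so
residual covariance between primary and HTP traits measured on the *same
plots* is not modeled — covariates enter as line-level BLUEs. The augmented
design analysis adjusts by block only (no row/column spatial correction),
and the forward-prediction scenarios score plot-level values, not
block-adjusted ones.
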