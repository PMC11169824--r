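# phenogs

Phenomic and genomic prediction for winter-wheat breeding with
high-throughput phenotyping (HTP), on fully synthetic, ground-truthed
breeding trials.

Modern wheat programs collect two complementary data streams on the same
plots: genome-wide SNP markers and multitemporal UAV canopy reflectance.
`phenogs` implements both prediction routes end to end:

- **Phenomic prediction** — a feedforward deep network maps multitemporal
  vegetation-index (VI) features to grain yield (GY), test weight (TW) and
  grain protein content (GPC), with the usual 70/30 plot split,
  epoch × batch-size tuning, and forward prediction from advanced nurseries
  to preliminary ones.
- **Genomic prediction** — single-trait GBLUP, y = 1µ + g + e with
  g ~ N(0, σ²g **G**) and **G** = XX′/p over centered, standardized markers,
  and a multi-trait extension with genetic values distributed
  MVN(0, **Σ** ⊗ **G**) (unstructured **Σ**, diagonal **R**), both fitted by
  Gibbs sampling. HTP traits enter the multi-trait model as line-level BLUE
  covariates, and the two cross-validation schemes compare them: **ST-CV1**
  (validation lines fully masked) versus **MT-CV2** (only the primary trait
  masked; HTP covariates observed for everyone).

Around the core sit the supporting stages a breeding analysis needs: a
synthetic-trial generator (RCBD and augmented designs, two locations, four
Feekes-stage flights, known breeding values), a 20-index VI registry with
explicit literature formulas, profile-REML BLUEs and broad-sense
heritability H² = σ²g/(σ²g + σ²e/nRep), marker QC (>30% missing, <5% MAF,
unmapped), and VCF/CSV I/O. Because no public accession of the motivating
field data exists, every analysis here runs on the package's own simulations,
where truth is known and every estimator can be checked against it.

## Worked example

```r
library(phenogs)

# a small single-location RCBD season: 120 lines, 3 replicates
cfg <- sim_config(
  n_lines = 120, n_markers = 150, n_locations = 1,
  trials = list(list(name = "T1", type = "rcbd", lines = 1:120,
                     n_reps = 3, locations = 1)),
  seed = 42)
geno <- simulate_genotypes(120, 150, seed = 42)
truth <- simulate_genetic_values(geno, cfg$h2, cfg$genetic_corr, seed = 42)
pheno <- simulate_field_trial(truth, cfg)
refl  <- simulate_reflectance(truth, cfg, pheno)

# heritability and BLUEs
estimate_heritability(pheno, "GY")
#> <pg_varcomp> s2g = 1.486e+05, s2e = 5.691e+05, nRep = 3.00, H2 = 0.439
blues <- blues_matrix(pheno)

# genomic prediction: ST-CV1 vs MT-CV2 with a GCI covariate
grm <- compute_grm(impute_mean(qc_filter(geno)$geno))
vi  <- compute_vi_table(refl)
gci <- vi_line_blues(vi, pheno, "GCI", "F8")
y   <- blues[, "GY"]
st  <- run_st_cv1(y, grm, cv_scheme("ST-CV1", n_reps = 10, seed = 1))
mt  <- run_mt_cv2(y, cbind(GCI_F8 = gci[names(y)]), grm,
                  cv_scheme("MT-CV2", n_reps = 10, seed = 1))
st
#> <pg_cvresult> ST-CV1: mean ability 0.413 (sd 0.150, 10 reps)
mt
#> <pg_cvresult> MT-CV2: mean ability 0.770 (sd 0.065, 10 reps); covariates: GCI_F8
```

The ST-CV1 number is the mean Pearson correlation between predicted
breeding values and held-out BLUEs over ten 80/20 line splits; the MT-CV2
number shows the gain from letting validation lines keep their canopy
covariate — here a large one, because the well-replicated GCI BLUE at flag
leaf is a strong spectral proxy for yield merit in these simulations. That
ST-versus-MT contrast is the central comparison the package exists to make.

```r
# phenomic prediction with the deep network
fm  <- build_feature_matrix(vi, pheno)          # 20 indices x 4 stages
fit <- train_predict(fm, "GY",
                     dnn_config(hidden_sizes = c(64, 32), epochs = 100,
                                dropout = 0.1, seed = 1))
fit$metrics
#> <pg_metrics> n = 109: R2 = 0.1948, RMSE = 745.5241, RMSE% = 17.33
```

Here R² is the held-out coefficient of determination on the 30% test plots
and RMSE% the error relative to the observed mean — the plot-level accuracy
of spectral features alone, with no marker data. (Plot-level yield in this
small noisy trial carries far more residual than the entry means the GBLUP
models see, so a modest plot-level R² is expected.)

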