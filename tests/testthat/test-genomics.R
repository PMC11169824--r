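toy_geno <- function(dosage, chrom = NULL) {
  m <- ncol(dosage)
  dimnames(dosage) <- list(sprintf("L%02d", seq_len(nrow(dosage))),
                           sprintf("M%02d", seq_len(m)))
  if (is.null(chrom)) chrom <- rep("1A", m)
  structure(list(dosage = dosage,
                 map = data.frame(id = colnames(dosage), chrom = chrom,
                                  pos = seq_len(m), stringsAsFactors = FALSE)),
            class = "pg_geno")
}

test_that("QC retains exactly the brute-force survivor set on a planted toy panel", {
  set.seed(71)
  n <- 10; m <- 20
  d <- matrix(rbinom(n * m, 2, 0.4), n, m)
  d[, 2] <- c(rep(NA, 4), d[5:10, 2])        # 40% missing -> removed
  d[, 5] <- c(rep(NA, 3), d[4:10, 5])        # exactly 30% -> retained
  d[, 8] <- c(1, rep(0, 9))                  # MAF 0.05 -> retained (strict <)
  d[, 11] <- c(rep(0, 10))                   # MAF 0 -> removed
  d[, 14] <- c(1, 1, rep(0, 8))              # MAF 0.10 -> retained
  chrom <- rep("2B", m); chrom[17] <- NA     # unmapped -> removed
  g <- toy_geno(d, chrom)
  res <- qc_filter(g)
  # independent brute-force enumeration
  survivors <- c()
  for (j in 1:m) {
    miss <- sum(is.na(d[, j])) / n
    p <- mean(d[, j], na.rm = TRUE) / 2
    maf <- min(p, 1 - p)
    if (!(miss > 0.30) && !(maf < 0.05) && !is.na(chrom[j]))
      survivors <- c(survivors, colnames(g$dosage)[j])
  }
  expect_setequal(colnames(res$geno$dosage), survivors)
  expect_equal(res$report$retained +
                 res$report$removed_missing + res$report$removed_maf +
                 res$report$removed_unmapped, m)
  expect_error(qc_filter(toy_geno(matrix(0, 4, 2))), "empty panel")
})

test_that("QC worked examples: frequency counting and missingness", {
  g <- toy_geno(matrix(c(0, 0, 1, 2), 4, 1))
  expect_equal(mean(g$dosage[, 1]) / 2, 0.375)  # 3 alt alleles / 8
  res <- qc_filter(toy_geno(cbind(c(0, 0, 1, 2), c(NA, NA, 1, 2))))
  expect_equal(colnames(res$geno$dosage), "M01") # 50% missing removed
})

test_that("mean imputation fills exactly the marker means", {
  g <- toy_geno(cbind(c(0, NA, 2), c(2, NA, NA), c(0, 1, 2)))
  gi <- impute_mean(g)
  expect_equal(unname(gi$dosage[2, 1]), 1.0)
  expect_equal(unname(gi$dosage[2:3, 2]), c(2, 2))
  expect_false(anyNA(gi$dosage))
  g2 <- toy_geno(cbind(c(0, 1, 2)))
  expect_identical(impute_mean(g2), g2)
  expect_error(impute_mean(toy_geno(cbind(c(0, 1, 2), c(NA, NA, NA)))),
               "entirely missing")
})

test_that("GRM algebra: hand case, symmetry, diagonal mean, flip invariance", {
  # one marker, dosages (2, 0): standardized (1, -1)
  g <- toy_geno(matrix(c(2, 0), 2, 1))
  grm <- compute_grm(g)
  expect_equal(unname(grm$X[, 1]), c(1, -1))
  expect_equal(unname(grm$G), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
  big <- simulate_genotypes(80, 400, seed = 73)
  G <- compute_grm(big)$G
  expect_lt(max(abs(G - t(G))), 1e-10)
  expect_equal(mean(diag(G)), 1, tolerance = 1e-12)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  flip <- big; flip$dosage <- 2L - flip$dosage
  expect_equal(compute_grm(flip)$G, G, tolerance = 1e-12)
  # duplicated line rows give identical G rows and equal diagonals
  dup <- big; dup$dosage[2, ] <- dup$dosage[1, ]
  Gd <- compute_grm(dup)$G
  expect_equal(unname(Gd[1, ]), unname(Gd[2, ]), tolerance = 1e-12)
  expect_equal(Gd[1, 1], Gd[2, 2], tolerance = 1e-12)
  mono <- toy_geno(cbind(c(1, 1, 1), c(0, 1, 2)))
  expect_error(compute_grm(mono), "monomorphic")
})

test_that("closed-form GBLUP obeys its worked example and limits", {
  G <- diag(2)
  y <- c(1, -1)
  cf <- st_gblup_closed_form(y, G, 1, 1)
  expect_equal(unname(cf$gebv), c(0.5, -0.5))
  # vanishing noise: gebv -> centered y
  cf0 <- st_gblup_closed_form(y, G, 1, 1e-10)
  expect_equal(unname(cf0$gebv), y - cf0$mu, tolerance = 1e-6)
  # vanishing signal: full shrinkage
  cfs <- st_gblup_closed_form(y, G, 1e-12, 1)
  expect_lt(max(abs(cfs$gebv)), 1e-10)
})

test_that("the ST Gibbs sampler matches the closed-form oracle and is reproducible", {
  lp <- sim_line_pheno(100, 500, h2 = c(GY = 0.5), seed = 75)
  y <- lp$Y[, 1]
  cfg <- gibbs_config(n_iter = 8000, burn_in = 2000, seed = 5)
  fit <- fit_st_gblup(y, lp$grm, cfg)
  oracle <- st_gblup_closed_form(y, lp$grm, 0.5, 0.5)
  expect_gte(cor(fit$gebv, oracle$gebv), 0.98)
  refit <- fit_st_gblup(y, lp$grm, cfg)
  expect_identical(fit$chains, refit$chains)
  expect_identical(fit$gebv, refit$gebv)
  # constant phenotype: no genetic signal
  fit0 <- fit_st_gblup(rep(2, 100), lp$grm,
                       gibbs_config(n_iter = 3000, burn_in = 1000, seed = 6))
  expect_lt(fit0$sigma2_g, 0.01)
  expect_lt(max(abs(fit0$gebv)), 0.05)
})

test_that("with variances frozen the Gibbs posterior mean converges to the oracle", {
  lp <- sim_line_pheno(100, 500, h2 = c(GY = 0.5), seed = 76)
  y <- lp$Y[, 1]
  fit <- fit_st_gblup(y, lp$grm,
                      gibbs_config(n_iter = 22000, burn_in = 2000, thin = 1,
                                   seed = 7),
                      fix_variances = list(sigma2_g = 0.5, sigma2_e = 0.5))
  oracle <- st_gblup_closed_form(y, lp$grm, 0.5, 0.5)
  expect_lt(sqrt(mean((fit$gebv - oracle$gebv)^2)), 0.01)
})

test_that("permuting line order permutes GEBVs identically", {
  lp <- sim_line_pheno(60, 300, h2 = c(GY = 0.5), seed = 77)
  y <- lp$Y[, 1]
  set.seed(1); perm <- sample(60)
  # exact equivariance of the deterministic solver
  cf <- st_gblup_closed_form(y, lp$grm, 0.5, 0.5)
  cf_p <- st_gblup_closed_form(y[perm], lp$grm$G[perm, perm], 0.5, 0.5)
  expect_equal(unname(cf_p$gebv), unname(cf$gebv[perm]), tolerance = 1e-10)
  # the sampler agrees up to Monte-Carlo error (its eigenbasis, and hence
  # its random-number mapping, is not permutation-stable)
  cfg <- gibbs_config(n_iter = 4000, burn_in = 1000, seed = 8)
  fit <- fit_st_gblup(y, lp$grm, cfg)
  fit_p <- fit_st_gblup(y[perm], lp$grm$G[perm, perm], cfg)
  expect_gte(cor(unname(fit_p$gebv), unname(fit$gebv[perm])), 0.995)
})

test_that("MT fits reduce to ST fits under diagonal truth", {
  lp <- sim_line_pheno(150, 600, h2 = c(A = 0.5, B = 0.6),
                       genetic_corr = diag(2), seed = 79)
  mt <- fit_mt_gblup(lp$Y, lp$grm,
                     gibbs_config(n_iter = 6000, burn_in = 2000, seed = 9))
  for (j in 1:2) {
    st <- fit_st_gblup(lp$Y[, j], lp$grm,
                       gibbs_config(n_iter = 6000, burn_in = 2000, seed = 10 + j))
    expect_gte(cor(mt$gebv[, j], st$gebv), 0.97)
  }
  expect_error(fit_mt_gblup(lp$Y[, 1, drop = FALSE], lp$grm), "at least 2")
})

test_that("MT masking uses the secondary trait and beats ST on masked lines", {
  # secondary trait equals the primary genetic value: ability approaches
  # the heritability ceiling
  lp <- sim_line_pheno(150, 600, h2 = c(A = 0.4, B = 0.9), seed = 80)
  g_a <- lp$truth$breeding_values[, 1]
  Y <- cbind(A = g_a + rnorm(150, 0, sqrt(0.6)), B = g_a)
  set.seed(81); mask <- sample(150, 30)
  Ym <- Y; Ym[mask, 1] <- NA
  mt <- fit_mt_gblup(Ym, lp$grm,
                     gibbs_config(n_iter = 5000, burn_in = 1500, seed = 11))
  mt_ab <- cor(mt$gebv[mask, 1], Y[mask, 1])
  st <- fit_st_gblup(Y[-mask, 1], lp$grm$G[-mask, -mask],
                     gibbs_config(n_iter = 5000, burn_in = 1500, seed = 12))
  st_ab <- cor(predict_gebv(st$gebv, lp$grm, setdiff(1:150, mask), mask),
               Y[mask, 1])
  expect_gt(mt_ab, st_ab)
  expect_gt(mt_ab, 0.45)   # near sqrt(h2) = 0.63 ceiling, far above ST
})
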