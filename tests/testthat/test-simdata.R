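test_that("simulated genotype panels have the configured shape and dosage support", {
  g <- simulate_genotypes(162, 1000, c(0.05, 0.5), seed = 1)
  expect_equal(dim(g$dosage), c(162, 1000))
  expect_true(all(g$dosage %in% 0:2))
  expect_equal(nrow(g$map), 1000)
  g2 <- simulate_genotypes(2, 1, c(0.5, 0.5), seed = 99)
  expect_true(all(g2$dosage %in% 0:2))
  expect_error(simulate_genotypes(10, 5, c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(10, 5, c(0.1, 0.6)), "maf_range")
})

test_that("empirical MAF distribution is uniform over the configured range", {
  g <- simulate_genotypes(500, 2000, c(0.05, 0.5), seed = 7)
  maf <- pmin(colMeans(g$dosage) / 2, 1 - colMeans(g$dosage) / 2)
  ks <- suppressWarnings(ks.test(maf, "punif", 0.05, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("genotype simulation is a pure function of the seed", {
  a <- simulate_genotypes(50, 100, seed = 3)
  b <- simulate_genotypes(50, 100, seed = 3)
  c <- simulate_genotypes(50, 100, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$dosage, c$dosage))
})

test_that("genetic values respect the additive identity and target correlations", {
  g <- simulate_genotypes(300, 800, seed = 5)
  rg <- matrix(c(1, 0.8, 0.8, 1), 2)
  tv <- simulate_genetic_values(g, h2 = c(A = 0.5, B = 0.7),
                                genetic_corr = rg, seed = 6)
  Xc <- scale(g$dosage, center = TRUE, scale = FALSE)
  expect_equal(unname(tv$breeding_values), unname(Xc %*% tv$marker_effects),
               tolerance = 1e-10)
  expect_equal(diag(tv$realized_genetic_corr), c(A = 1, B = 1))
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_genetic_values(g, c(A = .5, B = .5), bad),
               "positive semi-definite")
})

test_that("realized genetic correlations track the target over replicate seeds", {
  r_id <- r_08 <- numeric(20)
  rg <- matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3)
  for (i in 1:20) {
    g <- simulate_genotypes(500, 2000, seed = 100 + i)
    tv0 <- simulate_genetic_values(g, h2 = c(A = .5, B = .5, C = .5),
                                   genetic_corr = diag(3), seed = 200 + i)
    tv8 <- simulate_genetic_values(g, h2 = c(A = .5, B = .5, C = .5),
                                   genetic_corr = rg, seed = 200 + i)
    r_id[i] <- tv0$realized_genetic_corr[1, 2]
    r_08[i] <- tv8$realized_genetic_corr[1, 2]
  }
  expect_lt(abs(mean(r_id)), 0.1)
  expect_lt(abs(mean(r_08) - 0.8), 0.1)
})

test_that("field designs have the expected plot counts and integrity", {
  cfg <- rcbd_config(36, 200, n_reps = 3, seed = 11)
  g <- simulate_genotypes(36, 200, seed = 11)
  tv <- simulate_genetic_values(g, cfg$h2, cfg$genetic_corr, seed = 11)
  ph <- simulate_field_trial(tv, cfg)
  # an RCBD with 36 lines and 3 replicates has 108 plots
  expect_equal(nrow(ph), 108)
  tab <- table(ph$line, ph$replicate)
  expect_true(all(tab == 1))
  expect_false(any(duplicated(ph[c("line", "replicate", "location", "trial")])))
  expect_false(any(duplicated(ph$plot_id)))
})

test_that("augmented designs repeat every check in every block", {
  cfg <- sim_config(
    n_lines = 50, n_markers = 100, n_locations = 1,
    trials = list(list(name = "PYT", type = "augmented", lines = 8:50,
                       n_blocks = 5, checks = 1:3, locations = 1)),
    seed = 13)
  g <- simulate_genotypes(50, 100, seed = 13)
  tv <- simulate_genetic_values(g, cfg$h2, cfg$genetic_corr, seed = 13)
  ph <- simulate_field_trial(tv, cfg)
  checks <- sprintf("L%04d", 1:3)
  tab <- table(ph$line[ph$line %in% checks], ph$block[ph$line %in% checks])
  expect_true(all(tab == 1))
  expect_equal(dim(tab), c(3, 5))
  test_lines <- setdiff(unique(ph$line), checks)
  expect_true(all(table(ph$line[ph$line %in% test_lines]) == 1))
  expect_error(sim_config(
    n_lines = 50, n_markers = 100, n_locations = 1,
    trials = list(list(name = "PYT", type = "augmented", lines = 1:50,
                       n_blocks = 5, checks = integer(), locations = 1))),
    "check")
})

test_that("plot values reduce to mu + breeding value when noise is silenced", {
  cfg <- rcbd_config(30, 200, n_reps = 2, seed = 17,
                     h2 = c(GY = 1, TW = 1, GPC = 1),
                     rep_effect_sd = 0, loc_effect_sd = 0, gxl_sd = 0)
  g <- simulate_genotypes(30, 200, seed = 17)
  tv <- simulate_genetic_values(g, cfg$h2, cfg$genetic_corr, seed = 17)
  ph <- simulate_field_trial(tv, cfg)
  expected <- cfg$trait_mean["GY"] +
    cfg$trait_sd["GY"] * tv$breeding_values[ph$line, "GY"]
  expect_equal(ph$GY, unname(expected), tolerance = 1e-10)
})

test_that("genetic-variance share matches the h2 target across seeds", {
  shares <- matrix(NA_real_, 50, 2)
  for (i in 1:50) {
    g <- simulate_genotypes(500, 400, seed = 300 + i)
    tv <- simulate_genetic_values(g, h2 = c(A = 0.5, B = 0.7), seed = 400 + i)
    set.seed(500 + i)
    y1 <- tv$breeding_values[, 1] + rnorm(500, 0, sqrt(0.5))
    y2 <- tv$breeding_values[, 2] + rnorm(500, 0, sqrt(0.3))
    shares[i, ] <- c(var(tv$breeding_values[, 1]) / var(y1),
                     var(tv$breeding_values[, 2]) / var(y2))
  }
  expect_lt(abs(mean(shares[, 1]) - 0.5), 0.05)
  expect_lt(abs(mean(shares[, 2]) - 0.7), 0.05)
})

test_that("reflectance respects bounds, loadings, and determinism", {
  cfg <- rcbd_config(400, 300, n_reps = 1, seed = 19,
                     vigor_loadings = c(F6 = 0, F8 = 1, F10 = .5, F11 = .6),
                     stage_baseline = c(F6 = 0, F8 = 0, F10 = 0, F11 = 0),
                     reflectance_noise_sd = 0.3)
  g <- simulate_genotypes(400, 300, seed = 19)
  tv <- simulate_genetic_values(g, cfg$h2, cfg$genetic_corr, seed = 19)
  ph <- simulate_field_trial(tv, cfg)
  rf <- simulate_reflectance(tv, cfg, ph)
  bands <- as.matrix(rf[, c("blue", "green", "red", "red_edge", "nir")])
  expect_true(all(bands >= 0 & bands <= 1))
  bv <- tv$breeding_values[ph$line, "GY"]
  vi <- compute_vi_table(rf, "NDVI")
  r0 <- cor(vi$NDVI[vi$stage == "F6"], bv)
  expect_lt(abs(r0), 0.1)       # loading 0 decouples the stage from GY
  # zero noise, loading 1: monotone map preserves ordering
  cfg0 <- cfg; cfg0$reflectance_noise_sd <- 0
  rf0 <- simulate_reflectance(tv, cfg0, ph)
  vi0 <- compute_vi_table(rf0, "NDVI")
  s8 <- vi0$stage == "F8"
  expect_gte(cor(vi0$NDVI[s8], bv), 0.99)
  expect_equal(cor(vi0$NDVI[s8], bv, method = "spearman"), 1)
  expect_identical(simulate_reflectance(tv, cfg, ph), rf)
  cfg_bad <- cfg; cfg_bad$reflectance_noise_sd <- -1
  expect_error(simulate_reflectance(tv, cfg_bad, ph), "nonnegative")
})

test_that("dataset bundles are byte-identical under the same seed", {
  cfg <- rcbd_config(25, 60, n_reps = 2, seed = 23)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  o1 <- simulate_dataset(cfg, d1)
  o2 <- simulate_dataset(cfg, d2)
  for (f in names(o1$paths))
    expect_equal(unname(tools::md5sum(o1$paths[[f]])),
                 unname(tools::md5sum(o2$paths[[f]])), label = f)
  cfg3 <- rcbd_config(25, 60, n_reps = 2, seed = 24)
  o3 <- simulate_dataset(cfg3, file.path(tempdir(), "ds3"))
  expect_false(unname(tools::md5sum(o1$paths$genotypes)) ==
                 unname(tools::md5sum(o3$paths$genotypes)))
})
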