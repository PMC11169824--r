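test_that("index formulas reproduce hand-computed values", {
  b <- bands_fix(nir = 0.5, red = 0.1)
  expect_equal(compute_index(b, "NDVI"), (0.5 - 0.1) / (0.5 + 0.1))
  expect_equal(compute_index(b, "NDVI"), 0.6667, tolerance = 1e-4)
  expect_equal(compute_index(bands_fix(nir = 0.5, green = 0.1), "GCI"), 4.0)
  expect_equal(compute_index(bands_fix(nir = 0.3, red = 0.3), "NDVI"), 0)
  expect_equal(compute_index(b, "ARI"), 1 / 0.1 - 1 / 0.2)
  expect_equal(compute_index(b, "PSRI"), (0.1 - 0.1) / 0.2)
  expect_equal(compute_index(b, "NDWI"), (0.1 - 0.5) / (0.1 + 0.5))
  expect_error(compute_index(b, "NOPE"), "unknown")
  expect_error(compute_index(bands_fix(nir = 1.2), "NDVI"), "\\[0, 1\\]")
})

test_that("the catalog has 20 indices and degenerate denominators yield NA", {
  expect_length(vi_registry(), 20)
  zero <- bands_fix(green = 0, red = 0, red_edge = 0, nir = 0, blue = 0)
  expect_true(is.na(compute_index(zero, "NDVI")))
  expect_true(is.na(compute_index(zero, "GCI")))
})

test_that("normalized differences are bounded, antisymmetric, and ratio indices scale-invariant", {
  reg <- vi_registry()
  set.seed(42)
  for (i in 1:200) {
    b <- as.list(runif(5, 0.01, 1))
    names(b) <- c("blue", "green", "red", "red_edge", "nir")
    for (nm in names(reg)) {
      v <- reg[[nm]]$fun(b)
      if (reg[[nm]]$bounded && !is.na(v))
        expect_true(v >= -1 - 1e-12 && v <= 1 + 1e-12, label = nm)
      if (reg[[nm]]$ratio && !is.na(v)) {
        b2 <- lapply(b, function(x) x * 0.5)
        expect_equal(reg[[nm]]$fun(b2), v, tolerance = 1e-10, label = nm)
      }
    }
    # antisymmetry of the normalized difference under band swap
    swap <- b; swap$nir <- b$red; swap$red <- b$nir
    expect_equal(reg$NDVI$fun(swap), -reg$NDVI$fun(b), tolerance = 1e-12)
  }
})

test_that("the registry is user-extensible", {
  register_index("TESTIDX", function(b) b$nir * 2, ref = "test")
  expect_equal(compute_index(bands_fix(), "TESTIDX"), 1.0)
  reg <- vi_registry()
  .pg_env <- phenogs:::.pg_vi_env
  .pg_env$registry[["TESTIDX"]] <- NULL
  expect_length(vi_registry(), 20)
})

test_that("zonal means equal the brute-force mean over enumerated cells", {
  grid <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  mask <- matrix("p1", 2, 2)
  expect_equal(zonal_mean(grid, mask)$mean, 0.25)
  # constant grid
  expect_equal(zonal_mean(matrix(0.7, 3, 3), matrix("a", 3, 3))$mean, 0.7)
  # single-cell plot
  mask2 <- matrix(NA_character_, 2, 2); mask2[1, 2] <- "x"
  expect_equal(zonal_mean(grid, mask2)$mean, grid[1, 2])
  # random instance vs enumeration
  set.seed(8)
  g <- matrix(runif(30), 5, 6)
  m <- matrix(sample(c("a", "b", "c"), 30, TRUE), 5, 6)
  zm <- zonal_mean(g, m)
  for (p in c("a", "b", "c")) {
    acc <- 0; cnt <- 0
    for (i in 1:5) for (j in 1:6) if (m[i, j] == p) { acc <- acc + g[i, j]; cnt <- cnt + 1 }
    expect_equal(zm$mean[zm$plot_id == p], acc / cnt)
  }
  expect_error(zonal_mean(g, matrix("a", 2, 2)), "equal shape")
})

test_that("feature matrices have catalog-times-stages columns and drop incomplete plots", {
  cfg <- rcbd_config(40, 100, n_reps = 1, seed = 33)
  g <- simulate_genotypes(40, 100, seed = 33)
  tv <- simulate_genetic_values(g, cfg$h2, cfg$genetic_corr, seed = 33)
  ph <- simulate_field_trial(tv, cfg)
  rf <- simulate_reflectance(tv, cfg, ph)
  vi <- compute_vi_table(rf)
  fm <- build_feature_matrix(vi, ph)
  expect_equal(ncol(fm$x), 20 * 4)
  expect_equal(nrow(fm$x), nrow(ph))
  fm1 <- build_feature_matrix(vi, ph, stages = "F11")
  expect_equal(ncol(fm1$x), 20)
  expect_error(build_feature_matrix(vi, ph, stages = character(0)), "non-empty")
  ph2 <- ph; ph2$plot_id <- paste0("X", ph2$plot_id)
  expect_error(build_feature_matrix(vi, ph2), "common plot_ids")
})

test_that("stage-wise correlations recover planted relationships", {
  set.seed(51)
  n <- 500
  pheno <- data.frame(plot_id = sprintf("P%03d", 1:n), GY = rnorm(n))
  vi <- data.frame(plot_id = pheno$plot_id, stage = "F8",
                   SELF = pheno$GY, NEG = -pheno$GY, NOISE = rnorm(n))
  ct <- stagewise_trait_correlations(vi, pheno, targets = "GY")
  expect_equal(ct$r[ct$index == "SELF"], 1)
  expect_equal(ct$r[ct$index == "NEG"], -1)
  expect_lt(abs(ct$r[ct$index == "NOISE"]), 0.1)
  vi$FLAT <- 1
  expect_warning(ct2 <- stagewise_trait_correlations(vi, pheno, targets = "GY"),
                 "undefined")
  expect_true(is.na(ct2$r[ct2$index == "FLAT"]))
})
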