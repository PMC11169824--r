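make_trial <- function(n_lines, n_reps, seed, h2 = c(GY = .5, TW = .7, GPC = .45),
                       n_markers = 300, ...) {
  cfg <- rcbd_config(n_lines, n_markers, n_reps = n_reps, seed = seed,
                     h2 = h2, ...)
  g <- simulate_genotypes(n_lines, n_markers, seed = seed)
  tv <- simulate_genetic_values(g, cfg$h2, cfg$genetic_corr, seed = seed)
  list(cfg = cfg, tv = tv, pheno = simulate_field_trial(tv, cfg))
}

test_that("BLUEs equal line means on balanced designs with cancelling replicate effects", {
  # no noise at all: BLUE is exactly the plot mean
  tr <- make_trial(20, 2, seed = 61, h2 = c(GY = 1, TW = 1, GPC = 1),
                   rep_effect_sd = 0, loc_effect_sd = 0, gxl_sd = 0)
  bl <- fit_blues(tr$pheno, "GY")
  mu <- tapply(tr$pheno$GY, tr$pheno$line, mean)
  expect_equal(bl$estimate, as.numeric(mu[bl$line]), tolerance = 1e-7)
  # balanced RCBD with explicit +c/-c replicate effects: effects cancel in means
  set.seed(62)
  lines <- sprintf("L%02d", 1:15)
  truth <- rnorm(15)
  ph <- data.frame(location = "LOC1", trial = "T1",
                   block = rep(1:2, each = 15), replicate = rep(1:2, each = 15),
                   line = rep(lines, 2), plot_id = sprintf("P%03d", 1:30),
                   GY = rep(truth, 2) + rep(c(3, -3), each = 15))
  bl2 <- fit_blues(ph, "GY")
  expect_equal(bl2$estimate, as.numeric(tapply(ph$GY, ph$line, mean)[bl2$line]),
               tolerance = 1e-6)
  expect_equal(bl2$estimate, truth[match(bl2$line, lines)], tolerance = 1e-6)
  expect_error(fit_blues(ph, "YIELD"), "not found")
})

test_that("profile REML agrees with lme4 on BLUEs and variance components", {
  skip_if_not_installed("lme4")
  tr <- make_trial(40, 3, seed = 63)
  ph <- tr$pheno
  bl <- fit_blues(ph, "GY")
  m_fix <- lme4::lmer(GY ~ 0 + line + (1 | block), data = ph, REML = TRUE)
  fe <- lme4::fixef(m_fix)
  names(fe) <- sub("^line", "", names(fe))
  expect_equal(bl$estimate, unname(fe[bl$line]), tolerance = 1e-6)
  vc <- estimate_heritability(ph, "GY")
  m_rnd <- lme4::lmer(GY ~ factor(block) + (1 | line), data = ph, REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(m_rnd))
  expect_equal(vc$sigma2_g, v$vcov[v$grp == "line"], tolerance = 1e-4)
  expect_equal(vc$sigma2_e, v$vcov[v$grp == "Residual"], tolerance = 1e-4)
})

test_that("heritability follows its defining identity and limits", {
  # H2 = s2g / (s2g + s2e / nRep) at s2g = s2e = 1, nRep = 2 is 2/3
  vc <- structure(list(sigma2_g = 1, sigma2_e = 1, n_rep = 2), class = "pg_varcomp")
  expect_equal(vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e / vc$n_rep),
               0.6667, tolerance = 1e-4)
  # zero residual: H2 = 1 (noise-free trial)
  tr <- make_trial(25, 2, seed = 64, h2 = c(GY = 1, TW = 1, GPC = 1),
                   rep_effect_sd = 0, loc_effect_sd = 0, gxl_sd = 0)
  vc1 <- estimate_heritability(tr$pheno, "GY")
  expect_gt(vc1$H2, 0.999)
  # monotone in n_rep for fixed variance components
  h_of_nrep <- function(k) 1 / (1 + 2 / k)
  expect_true(all(diff(sapply(1:6, h_of_nrep)) > 0))
  # single-replicate estimates are flagged
  tr1 <- make_trial(25, 1, seed = 65)
  expect_warning(vc2 <- estimate_heritability(tr1$pheno, "GY"), "unreliable")
  expect_true(vc2$flagged)
})

test_that("REML heritability estimates recover the simulation target", {
  est <- numeric(50)
  for (i in 1:50) {
    tr <- make_trial(200, 3, seed = 700 + i, n_markers = 200)
    est[i] <- estimate_heritability(tr$pheno, "GY")$H2
  }
  expect_lt(abs(mean(est) - 0.5), 0.1)
  expect_true(all(est >= 0 & est <= 1))
})

test_that("REML bias shrinks as the line count grows", {
  est <- function(n, seeds) sapply(seeds, function(s)
    estimate_heritability(make_trial(n, 3, seed = s, n_markers = 150)$pheno,
                          "GY")$H2)
  e_small <- est(50, 901:915)
  e_large <- est(500, 901:908)
  expect_lte(abs(mean(e_large) - 0.5), abs(mean(e_small) - 0.5) + 0.05)
  expect_lt(abs(mean(e_large) - 0.5), 0.08)
})

test_that("BLUEs track true breeding values at moderate heritability", {
  rs <- sapply(1:10, function(i) {
    tr <- make_trial(200, 3, seed = 1000 + i, n_markers = 200,
                     h2 = c(GY = 0.7, TW = 0.7, GPC = 0.7))
    bl <- fit_blues(tr$pheno, "GY")
    cor(bl$estimate, tr$tv$breeding_values[bl$line, "GY"])
  })
  expect_gte(mean(rs), 0.8)
})

test_that("trait correlations on BLUEs behave at the identity and planted cases", {
  tr <- make_trial(200, 3, seed = 67,
                   h2 = c(GY = 0.8, TW = 0.8, GPC = 0.8))
  bm <- blues_matrix(tr$pheno)
  cm <- trait_correlation_matrix(bm)
  expect_equal(unname(diag(cm)), rep(1, 3))
  # defaults plant rg(GY, TW) = 0.3 and rg(GY, GPC) = -0.3 at high h2
  expect_lt(abs(cm["GY", "TW"] - 0.3), 0.2)
  expect_lt(cm["GY", "GPC"], 0)
  # independent traits stay near zero
  lp <- sim_line_pheno(200, 400, h2 = c(A = .6, B = .6), seed = 68)
  cm2 <- trait_correlation_matrix(lp$Y)
  expect_lt(abs(cm2[1, 2]), 0.15)
  # genetic correlation 0.8 shows through high-h2 BLUEs
  lp8 <- sim_line_pheno(200, 400, h2 = c(A = .8, B = .8),
                        genetic_corr = matrix(c(1, .8, .8, 1), 2), seed = 69)
  expect_lt(abs(trait_correlation_matrix(lp8$Y)[1, 2] - 0.8), 0.15)
  flat <- cbind(lp$Y, C = 1)
  expect_warning(trait_correlation_matrix(flat), "zero-variance")
})
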