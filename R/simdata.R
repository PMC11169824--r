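#' Configuration for a synthetic breeding-trial dataset
#'
#' Bundles every knob of the synthetic-data generator: the genotype panel,
#' the genetic architecture of the primary traits, the field designs of the
#' advanced (ELITE/AYT) and preliminary (PYT) nurseries, and the
#' multitemporal canopy-reflectance model.
#'
#' The defaults emulate a two-location hard-winter-wheat trial season:
#' 36 ELITE lines in an RCBD with 3 replicates, 126 AYT lines with 2
#' replicates (both nurseries at both locations), and 590 preliminary lines
#' plus 7 repeated elite checks in an augmented design with 22 blocks at the
#' first location only, genotyped at ~10k SNPs, overflown at Feekes growth
#' stages 6, 8, 10 and 11.
#'
#' @param n_lines total number of lines across nurseries.
#' @param n_markers number of biallelic SNP markers.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param trait_names primary trait names.
#' @param h2 named per-trait target broad-sense heritability on an
#'   entry-mean basis, each in (0, 1].
#' @param genetic_corr trait-by-trait genetic correlation matrix (symmetric
#'   PSD, unit diagonal).
#' @param trait_mean,trait_sd named per-trait phenotypic mean and standard
#'   deviation in trait units (GY kg/ha, TW kg/hL, GPC %).
#' @param n_locations number of locations.
#' @param trials list of trial descriptors. Each descriptor is a list with
#'   `name`, `type` ("rcbd" or "augmented"), `lines` (line indices),
#'   and `n_reps` (rcbd) or `n_blocks` plus `checks` (augmented);
#'   `locations` gives the location indices the trial is grown at.
#' @param flights growth-stage codes for the UAV flights.
#' @param vigor_loadings named per-stage coefficient linking the
#'   standardized GY breeding value to latent canopy vigor.
#' @param stage_baseline named per-stage baseline of latent canopy vigor.
#' @param reflectance_noise_sd standard deviation of plot-level vigor noise.
#' @param rep_effect_sd,block_effect_sd,loc_effect_sd,gxl_sd random-effect
#'   standard deviations expressed as fractions of the trait phenotypic SD.
#' @param seed integer seed; every simulator output is a pure function of
#'   (config, seed).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 752,
                       n_markers = 10009,
                       maf_range = c(0.05, 0.5),
                       trait_names = c("GY", "TW", "GPC"),
                       h2 = c(GY = 0.5, TW = 0.7, GPC = 0.45),
                       genetic_corr = default_genetic_corr(),
                       trait_mean = c(GY = 4500, TW = 76, GPC = 12),
                       trait_sd = c(GY = 600, TW = 2, GPC = 1),
                       n_locations = 2,
                       trials = default_trials(),
                       flights = c("F6", "F8", "F10", "F11"),
                       vigor_loadings = c(F6 = 0.3, F8 = 0.8, F10 = 0.8, F11 = 0.6),
                       stage_baseline = c(F6 = -0.5, F8 = 0.25, F10 = 0.5, F11 = 0),
                       reflectance_noise_sd = 0.3,
                       rep_effect_sd = 0.25,
                       block_effect_sd = 0.25,
                       loc_effect_sd = 0.3,
                       gxl_sd = 0.15,
                       seed = 1L) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    pg_stop("`maf_range` must lie within (0, 0.5] with lo <= hi")
  nt <- length(trait_names)
  if (is.null(names(h2))) names(h2) <- trait_names
  h2 <- h2[trait_names]
  if (any(is.na(h2)) || any(h2 <= 0) || any(h2 > 1))
    pg_stop("`h2` must supply a value in (0, 1] for every trait")
  if (!is.matrix(genetic_corr)) genetic_corr <- diag(nt)
  if (nrow(genetic_corr) != nt)
    pg_stop("`genetic_corr` dimension must match the number of traits")
  if (max(abs(diag(genetic_corr) - 1)) > 1e-8)
    pg_stop("`genetic_corr` must have unit diagonal")
  pg_check_psd(genetic_corr, "genetic_corr")
  dimnames(genetic_corr) <- list(trait_names, trait_names)
  pg_check_number(reflectance_noise_sd, "reflectance_noise_sd", lower = 0)
  missing_load <- setdiff(flights, names(vigor_loadings))
  if (length(missing_load))
    pg_stop("`vigor_loadings` missing for flights: ",
            paste(missing_load, collapse = ", "))
  if (is.null(names(stage_baseline))) names(stage_baseline) <- flights
  trait_mean <- trait_mean[trait_names]
  trait_sd <- trait_sd[trait_names]
  if (any(is.na(trait_mean)) || any(is.na(trait_sd)) || any(trait_sd <= 0))
    pg_stop("`trait_mean`/`trait_sd` must supply positive values per trait")
  for (tr in trials) {
    if (!tr$type %in% c("rcbd", "augmented"))
      pg_stop("trial type must be 'rcbd' or 'augmented'")
    if (tr$type == "augmented" && length(tr$checks) == 0)
      pg_stop("augmented design requires check lines")
    if (max(tr$lines, if (tr$type == "augmented") tr$checks else integer()) > n_lines)
      pg_stop("trial `", tr$name, "` references lines beyond n_lines")
  }
  structure(list(
    n_lines = n_lines, n_markers = n_markers, maf_range = maf_range,
    trait_names = trait_names, h2 = h2, genetic_corr = genetic_corr,
    trait_mean = trait_mean, trait_sd = trait_sd,
    n_locations = n_locations, trials = trials, flights = flights,
    vigor_loadings = vigor_loadings, stage_baseline = stage_baseline,
    reflectance_noise_sd = reflectance_noise_sd,
    rep_effect_sd = rep_effect_sd, block_effect_sd = block_effect_sd,
    loc_effect_sd = loc_effect_sd, gxl_sd = gxl_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_genetic_corr <- function() {
  m <- matrix(c(1, 0.3, -0.3,
                0.3, 1, 0.1,
                -0.3, 0.1, 1), 3, 3,
              dimnames = list(c("GY", "TW", "GPC"), c("GY", "TW", "GPC")))
  m
}

#' @rdname sim_config
#' @export
default_trials <- function() {
  list(
    list(name = "ELITE", type = "rcbd", lines = 1:36, n_reps = 3,
         locations = 1:2),
    list(name = "AYT", type = "rcbd", lines = 37:162, n_reps = 2,
         locations = 1:2),
    list(name = "PYT", type = "augmented", lines = 163:752, n_blocks = 22,
         checks = 1:7, locations = 1))
}

#' Simulate a SNP genotype panel
#'
#' Draws per-marker allele frequencies uniformly within `maf_range` and
#' dosages as binomial(2, freq), i.e. unlinked markers in Hardy-Weinberg
#' proportions. Markers are assigned round-robin to the 21 wheat
#' chromosomes with increasing positions.
#'
#' @param n_lines number of lines (>= 2).
#' @param n_markers number of markers (>= 1).
#' @param maf_range allele-frequency range within (0, 0.5].
#' @param seed integer seed.
#' @return an object of class `pg_geno`: list with `dosage`
#'   (lines x markers integer matrix in \{0,1,2\}, NA for missing) and
#'   `map` (marker id, chromosome, position).
#' @export
simulate_genotypes <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                               seed = 1L) {
  if (n_lines < 2 || n_markers < 1)
    pg_stop("need n_lines >= 2 and n_markers >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    pg_stop("`maf_range` must lie within (0, 0.5] with lo <= hi")
  set.seed(pg_seed(seed, "genotypes"))
  freq <- stats::runif(n_markers, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n_lines * n_markers, 2L, rep(freq, each = n_lines)),
                nrow = n_lines, ncol = n_markers)
  chroms <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  chrom <- chroms[((seq_len(n_markers) - 1L) %% 21L) + 1L]
  pos <- ((seq_len(n_markers) - 1L) %/% 21L + 1L) * 1000L
  ids <- sprintf("S%s_%07d", chrom, pos)
  lines <- sprintf("L%04d", seq_len(n_lines))
  dimnames(dos) <- list(lines, ids)
  structure(list(
    dosage = dos,
    map = data.frame(id = ids, chrom = chrom, pos = pos,
                     stringsAsFactors = FALSE),
    freq = freq), class = "pg_geno")
}

#' @export
print.pg_geno <- function(x, ...) {
  cat(sprintf("<pg_geno> %d lines x %d markers (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Simulate correlated additive genetic values
#'
#' Marker effects are drawn from a zero-mean multivariate normal with
#' trait covariance proportional to `genetic_corr` (an infinitesimal
#' model, matching the GBLUP assumptions of the downstream fitters).
#' Breeding values are the centered dosages times the marker effects,
#' rescaled per trait so the genetic variance equals `h2 * phen_var`
#' exactly; the same factor is applied to the marker effects so the
#' additive identity `BV = X_c B` is preserved.
#'
#' @param geno a `pg_geno` panel (complete, from [simulate_genotypes()]).
#' @param h2 per-trait heritability targets in (0, 1].
#' @param genetic_corr trait-by-trait correlation matrix (symmetric PSD).
#' @param seed integer seed.
#' @param phen_var per-trait total phenotypic variance on the entry-mean
#'   scale (default 1, i.e. standardized trait units).
#' @return class `pg_truevals`: breeding_values (line x trait),
#'   marker_effects (marker x trait), sigma2_g, realized_h2,
#'   realized_genetic_corr, phen_var.
#' @export
simulate_genetic_values <- function(geno, h2, genetic_corr = NULL, seed = 1L,
                                    phen_var = NULL) {
  stopifnot(inherits(geno, "pg_geno"))
  nt <- length(h2)
  if (nt < 1) pg_stop("need at least one trait")
  if (is.null(names(h2))) names(h2) <- paste0("T", seq_len(nt))
  if (any(h2 <= 0) || any(h2 > 1)) pg_stop("`h2` values must lie in (0, 1]")
  if (is.null(genetic_corr)) genetic_corr <- diag(nt)
  if (nrow(genetic_corr) != nt)
    pg_stop("`genetic_corr` dimension must match the number of traits")
  pg_check_psd(genetic_corr, "genetic_corr")
  if (is.null(phen_var)) phen_var <- rep(1, nt)
  set.seed(pg_seed(seed, "genvalues"))
  X <- geno$dosage
  if (anyNA(X)) pg_stop("genotypes must be complete (impute first)")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  m <- ncol(X)
  B <- matrix(stats::rnorm(m * nt), m, nt) %*% pg_psd_sqrt(genetic_corr)
  BV <- Xc %*% B
  v <- apply(BV, 2, stats::var)
  if (any(v <= 0)) pg_stop("degenerate genetic variance; increase markers/lines")
  target <- h2 * phen_var
  f <- sqrt(target / v)
  BV <- sweep(BV, 2, f, "*")
  B <- sweep(B, 2, f, "*")
  colnames(BV) <- colnames(B) <- names(h2)
  rownames(BV) <- rownames(X)
  rg <- if (nt > 1) stats::cor(BV) else matrix(1, 1, 1)
  structure(list(
    breeding_values = BV, marker_effects = B,
    sigma2_g = target, phen_var = phen_var,
    realized_h2 = h2, h2 = h2,
    realized_genetic_corr = rg, genetic_corr = genetic_corr),
    class = "pg_truevals")
}

# Residual plot variance that makes the entry-mean broad-sense heritability
# hit its target for a trial with n_rep replicates:
# H2 = s2g / (s2g + s2e/nRep)  =>  s2e = nRep * s2g * (1 - H2) / H2.
residual_var_for_h2 <- function(sigma2_g, h2, n_rep) {
  n_rep * sigma2_g * (1 - h2) / h2
}

#' Simulate plot-level phenotypes under the configured field designs
#'
#' Each plot record is y = mu + location + replicate (or block) + breeding
#' value + genotype-by-location deviation + residual. RCBD trials assign
#' every line to every replicate; augmented trials partition the
#' unreplicated test lines across blocks and repeat every check in every
#' block. The residual plot variance is set per trait from the heritability
#' target and the trial's replicate count so the entry-mean H2 matches.
#'
#' @param true_vals a `pg_truevals` object (standardized trait units).
#' @param config a [sim_config()]; trait means/SDs convert to trait units.
#' @return a `data.frame` with columns location, trial, block, replicate,
#'   line, plot_id and one column per trait.
#' @export
simulate_field_trial <- function(true_vals, config) {
  stopifnot(inherits(true_vals, "pg_truevals"), inherits(config, "sim_config"))
  traits <- config$trait_names
  BV <- true_vals$breeding_values[, traits, drop = FALSE]
  lines <- rownames(BV)
  set.seed(pg_seed(config$seed, "fieldtrial"))
  nt <- length(traits)
  loc_names <- sprintf("LOC%d", seq_len(config$n_locations))
  loc_eff <- matrix(stats::rnorm(config$n_locations * nt, 0, config$loc_effect_sd),
                    config$n_locations, nt)
  gxl <- array(stats::rnorm(nrow(BV) * config$n_locations * nt, 0, config$gxl_sd),
               dim = c(nrow(BV), config$n_locations, nt))
  out <- list()
  plot_counter <- 0L
  for (tr in config$trials) {
    for (loc in tr$locations) {
      if (tr$type == "rcbd") {
        idx <- tr$lines
        n_rep <- tr$n_reps
        rep_eff <- matrix(stats::rnorm(n_rep * nt, 0, config$rep_effect_sd),
                          n_rep, nt)
        recs <- expand.grid(line_idx = idx, rep = seq_len(n_rep),
                            KEEP.OUT.ATTRS = FALSE)
        blk <- recs$rep
        blk_eff_rows <- rep_eff[recs$rep, , drop = FALSE]
      } else {
        test_idx <- setdiff(tr$lines, tr$checks)
        n_blk <- tr$n_blocks
        blk_of_test <- rep(seq_len(n_blk), length.out = length(test_idx))
        chk <- expand.grid(line_idx = tr$checks, block = seq_len(n_blk),
                           KEEP.OUT.ATTRS = FALSE)
        recs <- rbind(
          data.frame(line_idx = test_idx, rep = 1L, block = blk_of_test),
          data.frame(line_idx = chk$line_idx, rep = chk$block, block = chk$block))
        blk <- recs$block
        blk_eff <- matrix(stats::rnorm(n_blk * nt, 0, config$block_effect_sd),
                          n_blk, nt)
        blk_eff_rows <- blk_eff[recs$block, , drop = FALSE]
        n_rep <- 1L
      }
      np <- nrow(recs)
      sig_e <- sqrt(residual_var_for_h2(true_vals$sigma2_g, config$h2, n_rep))
      Y <- matrix(NA_real_, np, nt)
      for (t in seq_len(nt)) {
        y_std <- loc_eff[loc, t] + blk_eff_rows[, t] +
          BV[recs$line_idx, t] + gxl[cbind(recs$line_idx, loc, t)] +
          stats::rnorm(np, 0, sig_e[t])
        Y[, t] <- config$trait_mean[t] + config$trait_sd[t] * y_std
      }
      colnames(Y) <- traits
      ids <- sprintf("P%06d", plot_counter + seq_len(np))
      plot_counter <- plot_counter + np
      out[[length(out) + 1L]] <- data.frame(
        location = loc_names[loc], trial = tr$name, block = blk,
        replicate = recs$rep, line = lines[recs$line_idx], plot_id = ids,
        Y, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate multitemporal 5-band canopy reflectance per plot
#'
#' For each plot and flight, a latent canopy vigor
#' v = loading(stage) * z + baseline(stage) + noise is squashed through a
#' logistic into s in (0, 1), where z is the plot's line GY breeding value
#' standardized across lines. Band reflectances are monotone affine maps of
#' s — NIR increases with vigor, Red decreases, the remaining bands are
#' gentle affine maps — all clipped to \[0, 1\]. NDVI-type indices therefore
#' correlate with GY with stage-controlled strength.
#'
#' @param true_vals a `pg_truevals` object.
#' @param config a [sim_config()].
#' @param pheno plot table from [simulate_field_trial()] (defines the plots).
#' @return data.frame with columns plot_id, stage, blue, green, red,
#'   red_edge, nir.
#' @export
simulate_reflectance <- function(true_vals, config, pheno) {
  stopifnot(inherits(true_vals, "pg_truevals"), inherits(config, "sim_config"))
  if (config$reflectance_noise_sd < 0) pg_stop("noise sd must be nonnegative")
  missing_load <- setdiff(config$flights, names(config$vigor_loadings))
  if (length(missing_load))
    pg_stop("vigor loading undefined for stage(s): ",
            paste(missing_load, collapse = ", "))
  set.seed(pg_seed(config$seed, "reflectance"))
  bv <- true_vals$breeding_values[, "GY"]
  z_all <- (bv - mean(bv)) / stats::sd(bv)
  z <- z_all[pheno$line]
  out <- list()
  for (stage in config$flights) {
    v <- config$vigor_loadings[[stage]] * z +
      (if (stage %in% names(config$stage_baseline))
        config$stage_baseline[[stage]] else 0) +
      stats::rnorm(length(z), 0, config$reflectance_noise_sd)
    s <- stats::plogis(v)
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    out[[stage]] <- data.frame(
      plot_id = pheno$plot_id, stage = stage,
      blue = clip01(0.06 + 0.04 * s),
      green = clip01(0.12 + 0.08 * s),
      red = clip01(0.25 - 0.18 * s),
      red_edge = clip01(0.18 + 0.10 * s),
      nir = clip01(0.25 + 0.35 * s),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate and write a complete synthetic dataset bundle
#'
#' Runs the full generator (genotypes, genetic values, field phenotypes,
#' reflectance) and writes genotypes as plain-text VCF v4.2, phenotypes,
#' reflectance and breeding-value ground truth as CSV. Re-running with the
#' same config (including seed) is byte-identical.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if absent).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0)
    pg_stop("output directory is not writable: ", dir)
  geno <- simulate_genotypes(config$n_lines, config$n_markers,
                             config$maf_range, seed = config$seed)
  tv <- simulate_genetic_values(geno, config$h2, config$genetic_corr,
                                seed = config$seed)
  pheno <- simulate_field_trial(tv, config)
  refl <- simulate_reflectance(tv, config, pheno)
  paths <- list(
    genotypes = file.path(dir, "genotypes.vcf"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    reflectance = file.path(dir, "reflectance.csv"),
    truth = file.path(dir, "truth.csv"))
  write_vcf(geno, paths$genotypes)
  pg_write_csv(pheno, paths$phenotypes)
  pg_write_csv(refl, paths$reflectance)
  truth <- data.frame(line = rownames(tv$breeding_values),
                      tv$breeding_values, stringsAsFactors = FALSE)
  pg_write_csv(truth, paths$truth)
  invisible(list(geno = geno, true_values = tv, pheno = pheno,
                 reflectance = refl, paths = paths))
}

# Deterministic CSV writer (fixed eol, no rownames) so identical configs
# yield identical file bytes.
pg_write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
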