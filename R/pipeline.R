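#' Write a genotype panel as plain-text VCF v4.2
#'
#' Unphased GT-only records (0/0, 0/1, 1/1, ./.), REF/ALT fixed to A/T.
#' Output is deterministic: identical panels yield identical bytes.
#'
#' @param geno a `pg_geno`.
#' @param path output file path (.vcf).
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "pg_geno"))
  d <- geno$dosage
  lines_ids <- rownames(d)
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- codes[d[ok] + 1L]
  chrom <- geno$map$chrom
  chrom[is.na(chrom)] <- "."
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(chrom[j], geno$map$pos[j], geno$map$id[j], "A", "T", ".",
            "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=phenogs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", lines_ids), collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a genotype matrix from VCF or dosage CSV
#'
#' VCF records are parsed with the `vcfR` package; GT fields map to allele
#' dosages 0/1/2 with `./.` (or any missing allele) as NA. Multi-allelic
#' sites are rejected with their ids. A CSV is read as a line x marker
#' dosage table whose first column holds line ids.
#'
#' @param path a `.vcf` (optionally gzipped) or `.csv` file.
#' @return a `pg_geno`.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) pg_stop("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))            # single-record files drop to a vector
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      pg_stop("multi-allelic site(s) rejected: ",
              paste(fix[multi, "ID"], collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- chartr("|", "/", gt)
    lookup <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
    dos <- matrix(unname(lookup[gt]), nrow(gt), ncol(gt))
    bad <- !is.na(gt) & gt != "./." & !gt %in% names(lookup)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      pg_stop(sprintf("malformed GT at record %d, sample %d: '%s'",
                      idx[1], idx[2], gt[bad][1]))
    }
    dos <- t(dos)
    dimnames(dos) <- list(colnames(gt), rownames(gt))
    chrom <- fix[, "CHROM"]
    chrom[chrom == "."] <- NA
    map <- data.frame(id = fix[, "ID"], chrom = chrom,
                      pos = as.integer(fix[, "POS"]),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- tab[[1]]
    if (!all(dos[!is.na(dos)] %in% 0:2))
      pg_stop("dosage CSV entries must be 0/1/2 or missing")
    map <- data.frame(id = colnames(dos), chrom = NA_character_,
                      pos = NA_integer_, stringsAsFactors = FALSE)
  }
  structure(list(dosage = dos, map = map), class = "pg_geno")
}

#' Line-level BLUEs of a vegetation index
#'
#' Treats one (index, stage) column of the VI table as a trait, joins the
#' plot design columns, and runs [fit_blues()], yielding the line-level
#' HTP-trait values used as covariates in the multi-trait model.
#'
#' @param vi VI table from [compute_vi_table()].
#' @param pheno plot phenotype table (for the design columns).
#' @param index index name.
#' @param stage flight code.
#' @inheritParams fit_blues
#' @return named vector of line BLUEs.
#' @export
vi_line_blues <- function(vi, pheno, index, stage,
                          combine = c("per_location", "combined")) {
  combine <- match.arg(combine)
  if (!index %in% names(vi)) pg_stop("index `", index, "` not in VI table")
  sub <- vi[vi$stage == stage, c("plot_id", index)]
  if (!nrow(sub)) pg_stop("no VI rows for stage ", stage)
  merged <- merge(pheno[c("location", "trial", "block", "replicate",
                          "line", "plot_id")], sub, by = "plot_id")
  bl <- fit_blues(merged, index, combine)
  stats::setNames(bl$estimate, bl$line)
}

#' Run the full synthetic-trial analysis pipeline
#'
#' Orchestrates simulation, vegetation-index feature extraction, BLUEs and
#' heritability, the genomic cross-validation schemes, and the phenomic
#' DNN, in dependency order, writing CSV tables plus a machine-readable
#' JSON summary. A stage failure halts downstream stages but preserves
#' completed outputs. Every output carries the originating seed and a
#' config hash; two runs with equal hashes are identical.
#'
#' @param config a [sim_config()] defining the synthetic trials.
#' @param out_dir output directory.
#' @param stages subset of
#'   `c("simulate", "features", "blues", "genomics", "cv", "dnn")`.
#' @param cv_reps CV replicates per scheme (reduced default for a desk run).
#' @param cv_vi,cv_stage HTP covariate (index, flight) for MT-CV2.
#' @param dnn_cfg a [dnn_config()] for the phenomic model.
#' @param chains a [gibbs_config()] used inside the CV loops.
#' @return invisibly, the summary list (also written as summary.json).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "features", "blues",
                                    "genomics", "cv", "dnn"),
                         cv_reps = 10,
                         cv_vi = "GCI", cv_stage = "F8",
                         dnn_cfg = dnn_config(hidden_sizes = c(64, 32),
                                              epochs = 60, seed = 1L),
                         chains = gibbs_config(n_iter = 6000,
                                               burn_in = 2000)) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  summary <- list(seed = config$seed,
                  config_hash = unname(tools::md5sum(cfg_json)),
                  stages = list())
  t0 <- Sys.time()
  log_stage <- function(name, n_records) {
    message(sprintf("[%s] %s: %d records (%.1fs elapsed)",
                    format(Sys.time(), "%H:%M:%S"), name, n_records,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  state <- list()
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(TRUE)
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     message(sprintf("stage '%s' failed: %s; halting downstream stages",
                                     name, conditionMessage(e)))
                     summary$stages[[name]] <<- list(status = "failed",
                                                     error = conditionMessage(e))
                     FALSE
                   })
    ok
  }
  ok <- run_stage("simulate", function() {
    state$data <<- simulate_dataset(config, out_dir)
    summary$stages$simulate <<- list(
      status = "ok", n_lines = config$n_lines, n_markers = config$n_markers,
      n_plots = nrow(state$data$pheno))
    log_stage("simulate", nrow(state$data$pheno))
  })
  if (ok) ok <- run_stage("features", function() {
    state$vi <<- compute_vi_table(state$data$reflectance)
    pg_write_csv(state$vi, file.path(out_dir, "vi_table.csv"))
    corr <- stagewise_trait_correlations(state$vi, state$data$pheno)
    pg_write_csv(corr, file.path(out_dir, "vi_trait_correlations.csv"))
    summary$stages$features <<- list(status = "ok", n_rows = nrow(state$vi),
                                     n_indices = length(setdiff(names(state$vi),
                                                                c("plot_id", "stage"))))
    log_stage("features", nrow(state$vi))
  })
  if (ok) ok <- run_stage("blues", function() {
    adv <- state$data$pheno[state$data$pheno$trial != "PYT", ]
    state$blues <<- blues_matrix(adv, config$trait_names)
    pg_write_csv(data.frame(line = rownames(state$blues), state$blues),
                 file.path(out_dir, "blues.csv"))
    h2 <- lapply(config$trait_names, function(tr)
      estimate_heritability(adv, tr))
    names(h2) <- config$trait_names
    vc <- data.frame(trait = config$trait_names,
                     sigma2_g = sapply(h2, `[[`, "sigma2_g"),
                     sigma2_e = sapply(h2, `[[`, "sigma2_e"),
                     H2 = sapply(h2, `[[`, "H2"))
    pg_write_csv(vc, file.path(out_dir, "variance_components.csv"))
    summary$stages$blues <<- list(status = "ok",
                                  H2 = stats::setNames(vc$H2, vc$trait))
    log_stage("blues", nrow(state$blues))
  })
  if (ok) ok <- run_stage("genomics", function() {
    adv_lines <- rownames(state$blues)
    g <- state$data$geno
    g$dosage <- g$dosage[adv_lines, , drop = FALSE]
    qc <- qc_filter(g)
    state$grm <<- compute_grm(impute_mean(qc$geno))
    summary$stages$genomics <<- list(status = "ok",
                                     markers_retained = qc$report$retained,
                                     markers_removed = qc$report$n_input -
                                       qc$report$retained)
    log_stage("genomics", qc$report$retained)
  })
  if (ok) ok <- run_stage("cv", function() {
    adv_lines <- rownames(state$grm$G)
    res <- list()
    for (tr in config$trait_names) {
      y <- state$blues[adv_lines, tr]
      st <- run_st_cv1(y, state$grm,
                       cv_scheme("ST-CV1", n_reps = cv_reps,
                                 seed = config$seed, chains = chains))
      cov <- vi_line_blues(state$vi, state$data$pheno, cv_vi, cv_stage)
      covm <- matrix(cov[adv_lines], ncol = 1,
                     dimnames = list(adv_lines, paste0(cv_vi, "_", cv_stage)))
      mt <- run_mt_cv2(y, covm, state$grm,
                       cv_scheme("MT-CV2", n_reps = cv_reps,
                                 seed = config$seed, chains = chains))
      res[[tr]] <- list(st_cv1 = st$mean, st_cv1_sd = st$sd,
                        mt_cv2 = mt$mean, mt_cv2_sd = mt$sd)
      reps <- data.frame(trait = tr, rep = seq_len(cv_reps),
                         st_cv1 = st$abilities, mt_cv2 = mt$abilities)
      pg_write_csv(reps, file.path(out_dir, paste0("cv_", tr, ".csv")))
    }
    summary$stages$cv <<- c(list(status = "ok"), res)
    log_stage("cv", cv_reps * length(config$trait_names))
  })
  if (ok) run_stage("dnn", function() {
    adv <- state$data$pheno[state$data$pheno$trial != "PYT", ]
    res <- list()
    for (tr in config$trait_names) {
      fm <- build_feature_matrix(state$vi, adv)
      tp <- train_predict(fm, tr, dnn_cfg)
      res[[tr]] <- list(r2 = tp$metrics$r2, rmse = tp$metrics$rmse,
                        rmse_pct = tp$metrics$rmse_pct)
      pg_write_csv(tp$predictions,
                   file.path(out_dir, paste0("dnn_pred_", tr, ".csv")))
    }
    summary$stages$dnn <<- c(list(status = "ok"), res)
    log_stage("dnn", length(config$trait_names))
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
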