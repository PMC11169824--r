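#' Cross-validation scheme descriptor
#'
#' ST-CV1 masks validation lines entirely (genotype-only prediction with a
#' single-trait model, 100 replicates by default); MT-CV2 masks only the
#' primary trait of validation lines while the HTP covariates stay
#' observed for everyone (multi-trait model, 50 replicates by default).
#' Each replicate draws a random 80/20 line split; training size is
#' floor(train_fraction * n). Replicate splits are derived
#' deterministically from the scheme seed, so CV1 and CV2 runs sharing a
#' seed are paired on identical splits.
#'
#' @param name `"ST-CV1"` or `"MT-CV2"`.
#' @param train_fraction training fraction in (0, 1), default 0.8.
#' @param n_reps replicates (default 100 for CV1, 50 for CV2).
#' @param seed integer seed.
#' @param chains a [gibbs_config()] used inside the loop; the default is
#'   the reduced 2,000 burn-in / 6,000 iteration setting (the full-length
#'   chains remain available by passing an explicit config).
#' @return class `pg_cvscheme` list.
#' @export
cv_scheme <- function(name = c("ST-CV1", "MT-CV2"), train_fraction = 0.8,
                      n_reps = NULL, seed = 1L,
                      chains = gibbs_config(n_iter = 6000, burn_in = 2000)) {
  name <- match.arg(name)
  pg_check_number(train_fraction, "train_fraction", lower = 0, upper = 1,
                  strict_lower = TRUE, strict_upper = TRUE)
  if (is.null(n_reps)) n_reps <- if (name == "ST-CV1") 100L else 50L
  pg_check_number(n_reps, "n_reps", lower = 1)
  structure(list(name = name, train_fraction = train_fraction,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 chains = chains), class = "pg_cvscheme")
}

#' Predictive ability
#'
#' Pearson correlation between predicted genetic values and observed
#' phenotypes in the validation set.
#'
#' @param gebv predicted values.
#' @param observed held-out observations (same length, >= 3).
#' @return correlation coefficient in \[-1, 1\].
#' @export
predictive_ability <- function(gebv, observed) {
  if (length(gebv) != length(observed)) pg_stop("lengths must match")
  if (length(gebv) < 3) pg_stop("need at least 3 pairs")
  if (stats::sd(gebv) == 0 || stats::sd(observed) == 0)
    pg_stop("zero-variance input: predictive ability undefined")
  stats::cor(gebv, observed)
}

cv_split <- function(n, train_fraction, seed, rep_i) {
  set.seed(pg_seed(seed, paste0("cvsplit", rep_i)))
  n_train <- floor(train_fraction * n)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

cv_result <- function(abilities, scheme, covariates = NULL) {
  structure(list(abilities = abilities, mean = mean(abilities),
                 sd = stats::sd(abilities), scheme = scheme,
                 covariates = covariates), class = "pg_cvresult")
}

#' @export
print.pg_cvresult <- function(x, ...) {
  cat(sprintf("<pg_cvresult> %s: mean ability %.3f (sd %.3f, %d reps)%s\n",
              x$scheme$name, x$mean, x$sd, length(x$abilities),
              if (!is.null(x$covariates))
                paste0("; covariates: ", paste(x$covariates, collapse = ","))
              else ""))
  invisible(x)
}

#' Single-trait cross-validation (ST-CV1)
#'
#' Per replicate: draw a random line-level 80/20 split, fit the
#' single-trait GBLUP on the training lines' phenotypes and the training
#' block of G, extend genetic values to the masked lines through the joint
#' model ([predict_gebv()]), and score the Pearson correlation against the
#' held-out observations.
#'
#' @param y named BLUE vector (one entry per line, complete).
#' @param grm `pg_grm` over the same lines.
#' @param scheme a [cv_scheme()] with name "ST-CV1".
#' @return class `pg_cvresult` with the per-replicate abilities.
#' @export
run_st_cv1 <- function(y, grm, scheme = cv_scheme("ST-CV1")) {
  G <- if (inherits(grm, "pg_grm")) grm$G else grm
  n <- length(y)
  if (n != nrow(G)) pg_stop("length(y) must match nrow(G)")
  if (anyNA(y)) pg_stop("`y` must be complete")
  n_test <- n - floor(scheme$train_fraction * n)
  if (n_test < 3)
    pg_stop("test sets of fewer than 3 lines cannot be scored; increase n")
  abilities <- vapply(seq_len(scheme$n_reps), function(i) {
    sp <- cv_split(n, scheme$train_fraction, scheme$seed, i)
    cfg <- scheme$chains
    cfg$seed <- pg_seed(scheme$seed, paste0("stfit", i))
    fit <- fit_st_gblup(y[sp$train], G[sp$train, sp$train], cfg)
    pred <- predict_gebv(fit$gebv, G, sp$train, sp$test)
    predictive_ability(pred, y[sp$test])
  }, numeric(1))
  cv_result(abilities, scheme)
}

#' Multi-trait cross-validation with HTP covariates (MT-CV2)
#'
#' Per replicate: mask the primary trait on the 20% validation lines, keep
#' the HTP covariates observed for all lines, fit the multi-trait GBLUP on
#' the full line set (masked entries handled by data augmentation), and
#' score the masked lines' posterior-mean genetic values against their
#' held-out observations.
#'
#' @param primary named BLUE vector of the primary trait (complete; the
#'   masking is done internally per replicate).
#' @param covariates line x covariate matrix of HTP-trait BLUEs, observed
#'   for all lines.
#' @param grm `pg_grm` over the same lines.
#' @param scheme a [cv_scheme()] with name "MT-CV2".
#' @return class `pg_cvresult` with the per-replicate abilities.
#' @export
run_mt_cv2 <- function(primary, covariates, grm,
                       scheme = cv_scheme("MT-CV2")) {
  G <- if (inherits(grm, "pg_grm")) grm$G else grm
  covariates <- as.matrix(covariates)
  n <- length(primary)
  if (n != nrow(G) || n != nrow(covariates))
    pg_stop("primary, covariates and G must cover the same lines")
  if (anyNA(covariates))
    pg_stop("covariates must be observed for every line (CV2 contract)")
  if (anyNA(primary)) pg_stop("`primary` must be complete (masking is internal)")
  n_test <- n - floor(scheme$train_fraction * n)
  if (n_test < 3)
    pg_stop("test sets of fewer than 3 lines cannot be scored; increase n")
  cov_names <- colnames(covariates)
  if (is.null(cov_names)) cov_names <- paste0("COV", seq_len(ncol(covariates)))
  abilities <- vapply(seq_len(scheme$n_reps), function(i) {
    sp <- cv_split(n, scheme$train_fraction, scheme$seed, i)
    Y <- cbind(primary = primary, covariates)
    Y[sp$test, 1] <- NA
    cfg <- scheme$chains
    cfg$seed <- pg_seed(scheme$seed, paste0("mtfit", i))
    fit <- fit_mt_gblup(Y, G, cfg)
    predictive_ability(fit$gebv[sp$test, 1], primary[sp$test])
  }, numeric(1))
  cv_result(abilities, scheme, covariates = cov_names)
}
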