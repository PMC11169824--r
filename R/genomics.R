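#' Marker quality control
#'
#' Removes markers with more than `max_missing` missing genotypes, minor
#' allele frequency below `min_maf`, or (optionally) no chromosome
#' assignment. Both thresholds are strict inequalities: a marker at
#' exactly 30% missingness or exactly 5% MAF is retained. Rules are
#' applied in the order missingness, MAF, unmapped; a marker is counted
#' once, under the first rule it violates.
#'
#' @param geno a `pg_geno` object.
#' @param max_missing maximum tolerated missing fraction (default 0.30).
#' @param min_maf minimum tolerated minor allele frequency (default 0.05).
#' @param drop_unmapped drop markers with NA chromosome (default TRUE).
#' @return list with `geno` (filtered panel) and `report` (class
#'   `pg_qcreport`: per-rule removal counts; removed + retained equals the
#'   input marker count).
#' @export
qc_filter <- function(geno, max_missing = 0.30, min_maf = 0.05,
                      drop_unmapped = TRUE) {
  stopifnot(inherits(geno, "pg_geno"))
  X <- geno$dosage
  if (!all(X[!is.na(X)] %in% 0:2)) pg_stop("dosages must be coded 0/1/2")
  m <- ncol(X)
  miss_frac <- colMeans(is.na(X))
  p_alt <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0  # all-missing marker: treated as MAF 0 after the missingness rule
  unmapped <- if (drop_unmapped) is.na(geno$map$chrom) else rep(FALSE, m)
  bad_miss <- miss_frac > max_missing
  bad_maf <- !bad_miss & maf < min_maf
  bad_unmap <- !bad_miss & !bad_maf & unmapped
  keep <- !(bad_miss | bad_maf | bad_unmap)
  if (!any(keep)) pg_stop("QC removed every marker: empty panel")
  out <- geno
  out$dosage <- X[, keep, drop = FALSE]
  out$map <- geno$map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  if (!is.null(geno$freq)) out$freq <- geno$freq[keep]
  report <- structure(list(
    n_input = m,
    removed_missing = sum(bad_miss),
    removed_maf = sum(bad_maf),
    removed_unmapped = sum(bad_unmap),
    retained = sum(keep),
    max_missing = max_missing, min_maf = min_maf), class = "pg_qcreport")
  list(geno = out, report = report)
}

#' @export
print.pg_qcreport <- function(x, ...) {
  cat(sprintf(paste0("<pg_qcreport> %d markers in; removed %d (missing > %g%%), ",
                     "%d (MAF < %g%%), %d (unmapped); %d retained\n"),
              x$n_input, x$removed_missing, 100 * x$max_missing,
              x$removed_maf, 100 * x$min_maf, x$removed_unmapped, x$retained))
  invisible(x)
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing dosage by its marker mean (a simple stand-in for
#' haplotype-based imputation, applied after [qc_filter()]).
#'
#' @param geno a `pg_geno` object.
#' @return the panel with no missing values (dosage becomes numeric).
#' @export
impute_mean <- function(geno) {
  stopifnot(inherits(geno, "pg_geno"))
  X <- geno$dosage
  if (!anyNA(X)) return(geno)
  mu <- colMeans(X, na.rm = TRUE)
  all_missing <- which(is.nan(mu))
  if (length(all_missing))
    pg_stop("marker(s) entirely missing (should have been filtered): ",
            paste(colnames(X)[all_missing], collapse = ", "))
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  geno$dosage <- X
  geno
}

#' Genomic relationship matrix
#'
#' Centers each marker column and scales it to unit variance (population
#' 1/n variance denominator, so the diagonal mean of G is exactly 1), then
#' \deqn{G = X X' / p} over the p standardized markers. The VanRaden
#' 2p(1-p) allele-frequency denominator is available as an option.
#'
#' @param geno a `pg_geno` object with no missing values.
#' @param scale `"sd"` (default; observed column SD) or `"vanraden"`
#'   (binomial 2p(1-p) scaling).
#' @return class `pg_grm`: list with `G` (n x n), `X` (standardized
#'   markers), `p` (marker count).
#' @export
compute_grm <- function(geno, scale = c("sd", "vanraden")) {
  stopifnot(inherits(geno, "pg_geno"))
  scale <- match.arg(scale)
  X <- geno$dosage
  if (anyNA(X)) pg_stop("GRM requires complete genotypes; run impute_mean()")
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  if (scale == "sd") {
    s <- sqrt(colMeans(X^2) - mu^2)      # population (1/n) SD
  } else {
    pa <- mu / 2
    s <- sqrt(2 * pa * (1 - pa))
  }
  mono <- which(s < 1e-12)
  if (length(mono))
    pg_stop("monomorphic marker(s) (zero variance): ",
            paste(colnames(X)[mono], collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  G <- tcrossprod(Xs) / p
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(X), rownames(X))
  structure(list(G = G, X = Xs, p = p, scale = scale), class = "pg_grm")
}

#' @export
print.pg_grm <- function(x, ...) {
  cat(sprintf("<pg_grm> %d lines, %d markers, diag mean %.4f\n",
              nrow(x$G), x$p, mean(diag(x$G))))
  invisible(x)
}

# Eigendecomposition of G with a numerical guard: when the smallest
# eigenvalue is below -tol the matrix is rejected; tiny negative
# eigenvalues are clamped to zero and those components carry no genetic
# variance. A ridge is applied only where an explicit inverse is needed.
grm_eigen <- function(G, tol = 1e-8) {
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -tol)
    pg_stop(sprintf("G is not PSD (min eigenvalue %.3g)", min(e$values)))
  e$values <- pmax(e$values, 0)
  e
}

#' Closed-form single-trait GBLUP at fixed variance components
#'
#' The deterministic mixed-model oracle: with known variances the
#' posterior mean of the genetic values is
#' \deqn{\hat g = \sigma^2_g G (\sigma^2_g G + \sigma^2_e I)^{-1} (y - \hat\mu)}
#' with \eqn{\hat\mu} the generalized-least-squares intercept.
#'
#' @param y trait vector (complete).
#' @param grm a `pg_grm` object (or a plain G matrix).
#' @param sigma2_g,sigma2_e positive variance components.
#' @return list with `gebv` and `mu`.
#' @export
st_gblup_closed_form <- function(y, grm, sigma2_g, sigma2_e) {
  G <- if (inherits(grm, "pg_grm")) grm$G else grm
  if (anyNA(y)) pg_stop("`y` must be complete")
  if (length(y) != nrow(G)) pg_stop("length(y) must match nrow(G)")
  pg_check_number(sigma2_g, "sigma2_g", lower = 0, strict_lower = TRUE)
  pg_check_number(sigma2_e, "sigma2_e", lower = 0, strict_lower = TRUE)
  V <- sigma2_g * G + diag(sigma2_e, nrow(G))
  Vi <- tryCatch(solve(V), error = function(e)
    pg_stop("singular mixed-model system: ", conditionMessage(e)))
  one <- rep(1, length(y))
  mu <- sum(Vi %*% y) / sum(Vi)
  gebv <- as.numeric(sigma2_g * G %*% Vi %*% (y - mu))
  names(gebv) <- rownames(G)
  list(gebv = gebv, mu = mu)
}

#' Gibbs-sampler configuration
#'
#' Chain settings for the Bayesian GBLUP fitters. The defaults outside
#' cross-validation are 5,000 burn-in / 25,000 total iterations for the
#' single-trait model and 5,000 / 15,000 for the multi-trait model;
#' [cv_scheme()] substitutes shorter chains inside CV loops.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in burn-in iterations (< n_iter).
#' @param thin keep-every interval (>= 1).
#' @param df_prior prior degrees of freedom for the scaled-inverse
#'   chi-squared variance priors (single-trait) and the base for the
#'   inverse-Wishart prior (multi-trait: df = n_traits + 4).
#' @param seed integer seed; chains are reproducible given the seed.
#' @return class `pg_gibbs` list.
#' @export
gibbs_config <- function(n_iter = 25000, burn_in = 5000, thin = 5,
                         df_prior = 5, seed = 1L) {
  pg_check_number(n_iter, "n_iter", lower = 10)
  pg_check_number(burn_in, "burn_in", lower = 0)
  if (burn_in >= n_iter) pg_stop("burn_in must be smaller than n_iter")
  pg_check_number(thin, "thin", lower = 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), df_prior = df_prior,
                 seed = as.integer(seed)), class = "pg_gibbs")
}

# Scaled-inverse-chi2 draw: df * scale / chi2_df.
rinvchisq <- function(df, scale) df * scale / stats::rchisq(1, df)

#' Single-trait Bayesian GBLUP by Gibbs sampling
#'
#' Samples the model y = 1 mu + g + e with g ~ N(0, sigma2_g G) and
#' e ~ N(0, sigma2_e I) using conjugate updates: normal full conditionals
#' for mu and the genetic values, scaled-inverse-chi-squared for both
#' variances (df 5; scale set so the prior mode assigns half the
#' phenotypic variance to genetics). The genetic values are updated in the
#' eigenbasis of G, where their full conditional is diagonal, so each
#' sweep is a handful of vectorized operations.
#'
#' @param y trait vector, complete for all fitted lines.
#' @param grm a `pg_grm` (or G matrix) for the same lines.
#' @param cfg a [gibbs_config()].
#' @param fix_variances optional list(sigma2_g=, sigma2_e=) to freeze the
#'   variance components (used by the sampler-vs-oracle checks).
#' @return class `pg_stfit`: posterior means `mu`, `gebv`, `sigma2_g`,
#'   `sigma2_e`, and `chains` (thinned post-burn-in draws of mu and the
#'   variances).
#' @export
fit_st_gblup <- function(y, grm, cfg = gibbs_config(),
                         fix_variances = NULL) {
  G <- if (inherits(grm, "pg_grm")) grm$G else grm
  if (anyNA(y)) pg_stop("`y` must be complete for training lines")
  n <- length(y)
  if (n != nrow(G)) pg_stop("length(y) must match nrow(G)")
  stopifnot(inherits(cfg, "pg_gibbs"))
  eg <- grm_eigen(G)
  d <- eg$values
  U <- eg$vectors
  act <- d > 1e-8                     # zero-variance eigencomponents carry h_k = 0
  vy <- stats::var(y)
  if (vy == 0) vy <- 1e-12
  df0 <- cfg$df_prior
  S0 <- 0.5 * vy * (df0 + 2) / df0    # prior mode at half the phenotypic variance
  set.seed(pg_seed(cfg$seed, "stgblup"))
  fixed <- !is.null(fix_variances)
  sigma2_g <- if (fixed) fix_variances$sigma2_g else 0.5 * vy
  sigma2_e <- if (fixed) fix_variances$sigma2_e else 0.5 * vy
  mu <- mean(y)
  h <- rep(0, n)
  Uty <- as.numeric(crossprod(U, y))
  Ut1 <- as.numeric(crossprod(U, rep(1, n)))
  keep_iters <- seq(cfg$burn_in + 1L, cfg$n_iter, by = cfg$thin)
  n_keep <- length(keep_iters)
  sum_g <- rep(0, n); sum_mu <- 0
  chains <- matrix(NA_real_, n_keep, 3,
                   dimnames = list(NULL, c("mu", "sigma2_g", "sigma2_e")))
  ki <- 0L
  for (it in seq_len(cfg$n_iter)) {
    g <- as.numeric(U %*% h)
    mu <- stats::rnorm(1, mean(y - g), sqrt(sigma2_e / n))
    yt <- Uty - mu * Ut1
    post_var <- 1 / (1 / sigma2_e + 1 / (sigma2_g * d[act]))
    post_mean <- post_var * yt[act] / sigma2_e
    h[act] <- stats::rnorm(sum(act), post_mean, sqrt(post_var))
    if (!fixed) {
      ss_g <- sum(h[act]^2 / d[act])
      sigma2_g <- rinvchisq(df0 + sum(act), (ss_g + df0 * S0) / (df0 + sum(act)))
      g <- as.numeric(U %*% h)
      ss_e <- sum((y - mu - g)^2)
      sigma2_e <- rinvchisq(df0 + n, (ss_e + df0 * S0) / (df0 + n))
    }
    if (!is.finite(sigma2_g) || !is.finite(sigma2_e) || anyNA(h))
      pg_stop(sprintf("divergent chain at iteration %d (non-finite draws)", it))
    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      ki <- ki + 1L
      g <- as.numeric(U %*% h)
      sum_g <- sum_g + g
      sum_mu <- sum_mu + mu
      chains[ki, ] <- c(mu, sigma2_g, sigma2_e)
    }
  }
  gebv <- sum_g / n_keep
  names(gebv) <- rownames(G)
  structure(list(mu = sum_mu / n_keep, gebv = gebv,
                 sigma2_g = mean(chains[, "sigma2_g"]),
                 sigma2_e = mean(chains[, "sigma2_e"]),
                 chains = chains, cfg = cfg), class = "pg_stfit")
}

#' @export
print.pg_stfit <- function(x, ...) {
  cat(sprintf("<pg_stfit> %d lines; mu = %.4g, s2g = %.4g, s2e = %.4g\n",
              length(x$gebv), x$mu, x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Extend fitted genetic values to unphenotyped lines
#'
#' Conditional (kriging) extension of the joint GBLUP model: for lines
#' without phenotypes, \eqn{\hat g_{new} = G_{new,tr} G_{tr,tr}^{-1} \hat g_{tr}},
#' the posterior conditional mean given the fitted lines' genetic values.
#'
#' @param gebv_train named vector of fitted genetic values.
#' @param grm_full `pg_grm` (or G matrix) covering training and new lines.
#' @param train_idx indices (or names) of the training lines in G.
#' @param new_idx indices (or names) of the lines to predict.
#' @return named vector of predicted genetic values for `new_idx`.
#' @export
predict_gebv <- function(gebv_train, grm_full, train_idx, new_idx) {
  G <- if (inherits(grm_full, "pg_grm")) grm_full$G else grm_full
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  Gnt <- G[new_idx, train_idx, drop = FALSE]
  ridge <- diag(1e-8, nrow(Gtt))
  out <- as.numeric(Gnt %*% solve(Gtt + ridge, gebv_train))
  names(out) <- rownames(G)[if (is.character(new_idx)) match(new_idx, rownames(G)) else new_idx]
  out
}
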