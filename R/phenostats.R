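# Profile REML for the one-random-effect linear mixed model
#   y = X beta + Z u + e,  u ~ N(0, sigma2_e * lambda * I_q),  e ~ N(0, sigma2_e I)
# where Z is the incidence of a single grouping factor, so Z'Z is diagonal
# and every quantity reduces to per-group sums (Woodbury identity). The
# single variance ratio lambda is profiled out and maximized by bounded
# scalar optimization on log(lambda).
reml_onefactor <- function(y, X, f) {
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; f <- factor(f[ok])
  n <- length(y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  counts <- as.numeric(table(f))
  ZtX <- rowsum(X, f)
  Zty <- as.numeric(rowsum(y, f))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  crit <- function(loglam) {
    lam <- exp(loglam)
    d <- 1 / (counts + 1 / lam)
    XtViX <- XtX - crossprod(ZtX, d * ZtX)
    XtViy <- Xty - crossprod(ZtX, d * Zty)
    ytViy <- yty - sum(d * Zty^2)
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
    ypy <- ytViy - sum(XtViy * beta)
    if (ypy <= 0) return(1e10)
    logdetV <- sum(log1p(lam * counts))
    logdetXtViX <- 2 * sum(log(diag(ch)))
    0.5 * (logdetV + logdetXtViX + (n - p) * log(ypy))
  }

  if (nlevels(f) < 2) {
    opt <- list(minimum = log(1e-10))
    boundary <- TRUE
  } else {
    opt <- stats::optimize(crit, interval = log(c(1e-10, 1e8)))
    boundary <- opt$minimum <= log(1e-10) + 1e-6 ||
      opt$minimum >= log(1e8) - 1e-6
  }
  lam <- exp(opt$minimum)
  d <- 1 / (counts + 1 / lam)
  XtViX <- XtX - crossprod(ZtX, d * ZtX)
  XtViy <- Xty - crossprod(ZtX, d * Zty)
  ytViy <- yty - sum(d * Zty^2)
  beta <- solve(XtViX, XtViy)
  ypy <- as.numeric(ytViy - sum(XtViy * beta))
  sigma2_e <- ypy / (n - p)
  sigma2_u <- lam * sigma2_e
  if (lam <= 1e-9) sigma2_u <- 0    # truncate at zero on the boundary
  r_groups <- Zty - as.numeric(ZtX %*% beta)
  u <- d * r_groups                  # BLUPs of the random effect
  vcov_beta <- sigma2_e * solve(XtViX)
  list(beta = as.numeric(beta), beta_names = colnames(X),
       vcov_beta = vcov_beta, sigma2_u = sigma2_u, sigma2_e = sigma2_e,
       lambda = lam, u = u, u_levels = levels(f), n = n, p = p,
       boundary = boundary)
}

#' Best linear unbiased estimates (BLUEs) of line means
#'
#' Fits, per trait, the plot-level model with genotype as a fixed effect
#' and block-within-trial (the replicate in an RCBD, the incomplete block
#' in an augmented design) as a single random effect, by profile REML.
#' With several locations the default fits each location separately and
#' averages the per-location BLUEs; `combine = "combined"` instead fits
#' all locations jointly with location as an additional fixed effect.
#' With a single block level the model degenerates to ordinary least
#' squares on raw plot values.
#'
#' @param pheno plot phenotype table from [simulate_field_trial()] (columns
#'   location, trial, block, replicate, line, plot_id, traits).
#' @param trait trait column name.
#' @param combine `"per_location"` (default) or `"combined"`.
#' @return data.frame: line, estimate, se (NA for the averaged path when a
#'   line was seen in several locations), n_locations.
#' @export
fit_blues <- function(pheno, trait, combine = c("per_location", "combined")) {
  combine <- match.arg(combine)
  if (!trait %in% names(pheno))
    pg_stop("trait `", trait, "` not found in phenotype table")
  if (length(unique(pheno$line)) < 2) pg_stop("need at least 2 lines")
  blk <- interaction(pheno$trial, pheno$block, drop = TRUE)
  if (combine == "combined" || length(unique(pheno$location)) == 1) {
    lf <- factor(pheno$line)
    X <- stats::model.matrix(~ 0 + lf)
    colnames(X) <- levels(lf)
    if (length(unique(pheno$location)) > 1) {
      locf <- factor(pheno$location)
      X <- cbind(X, stats::model.matrix(~locf)[, -1, drop = FALSE])
    }
    fit <- reml_onefactor(pheno[[trait]], X,
                          interaction(pheno$location, blk, drop = TRUE))
    keep <- fit$beta_names %in% levels(lf)
    est <- fit$beta[keep]
    nm <- fit$beta_names[keep]
    se <- sqrt(diag(fit$vcov_beta))[keep]
    out <- data.frame(line = nm, estimate = est, se = se,
                      n_locations = length(unique(pheno$location)),
                      stringsAsFactors = FALSE)
  } else {
    per <- lapply(split(pheno, pheno$location), function(sub)
      fit_blues(sub, trait, combine = "combined"))
    all_lines <- sort(unique(unlist(lapply(per, function(d) d$line))))
    est <- sapply(all_lines, function(l) {
      vals <- unlist(lapply(per, function(d) d$estimate[d$line == l]))
      mean(vals)
    })
    nl <- sapply(all_lines, function(l)
      sum(vapply(per, function(d) l %in% d$line, logical(1))))
    ses <- sapply(all_lines, function(l) {
      vals <- unlist(lapply(per, function(d) d$se[d$line == l]))
      sqrt(sum(vals^2)) / length(vals)
    })
    out <- data.frame(line = all_lines, estimate = as.numeric(est),
                      se = as.numeric(ses), n_locations = as.integer(nl),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Line-by-trait BLUE matrix
#'
#' Convenience wrapper running [fit_blues()] for several traits and
#' returning a line x trait matrix, the natural input for genomic
#' prediction and trait-correlation analyses.
#'
#' @inheritParams fit_blues
#' @param traits trait column names (default GY, TW, GPC when present).
#' @return numeric matrix, rownames = line ids.
#' @export
blues_matrix <- function(pheno, traits = NULL,
                         combine = c("per_location", "combined")) {
  combine <- match.arg(combine)
  if (is.null(traits))
    traits <- intersect(c("GY", "TW", "GPC"), names(pheno))
  per <- lapply(traits, function(tr) fit_blues(pheno, tr, combine))
  lines <- sort(unique(unlist(lapply(per, function(d) d$line))))
  m <- sapply(seq_along(traits), function(i)
    per[[i]]$estimate[match(lines, per[[i]]$line)])
  m <- matrix(m, nrow = length(lines),
              dimnames = list(lines, traits))
  m
}

#' Broad-sense heritability by REML variance components
#'
#' Refits the plot model with the genotype effect random (environment,
#' i.e. location/replicate combination, as fixed) and computes the
#' entry-mean broad-sense heritability
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / n_{Rep})}
#' where nRep is the (mean) number of plots per line. Negative variance
#' estimates are truncated at zero (the profile optimum sits on the
#' boundary) with a warning.
#'
#' @inheritParams fit_blues
#' @param n_rep replicate count used in the entry-mean divisor; defaults
#'   to the mean number of plots per line in the data.
#' @return class `pg_varcomp`: list with sigma2_g, sigma2_e, n_rep, H2,
#'   lambda, flagged (TRUE when the estimate is unreliable: a single
#'   replicate or a boundary fit).
#' @export
estimate_heritability <- function(pheno, trait, n_rep = NULL) {
  if (!trait %in% names(pheno))
    pg_stop("trait `", trait, "` not found in phenotype table")
  env <- interaction(pheno$location, pheno$trial, pheno$block, drop = TRUE)
  X <- if (nlevels(env) > 1) stats::model.matrix(~env) else
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- reml_onefactor(pheno[[trait]], X, factor(pheno$line))
  if (is.null(n_rep)) n_rep <- mean(table(pheno$line))
  flagged <- n_rep < 2 || fit$boundary
  if (fit$boundary && fit$sigma2_u == 0)
    warning("genetic variance estimate truncated at 0 (boundary REML fit)")
  if (n_rep < 2)
    warning("single replicate: heritability estimate is unreliable")
  H2 <- fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e / n_rep)
  structure(list(sigma2_g = fit$sigma2_u, sigma2_e = fit$sigma2_e,
                 n_rep = n_rep, H2 = H2, lambda = fit$lambda,
                 flagged = flagged), class = "pg_varcomp")
}

#' @export
print.pg_varcomp <- function(x, ...) {
  cat(sprintf("<pg_varcomp> s2g = %.4g, s2e = %.4g, nRep = %.2f, H2 = %.3f%s\n",
              x$sigma2_g, x$sigma2_e, x$n_rep, x$H2,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Pairwise Pearson correlations among trait BLUEs
#'
#' @param blues line x trait matrix (e.g. from [blues_matrix()]) or a
#'   data.frame of trait columns.
#' @return trait x trait correlation matrix; zero-variance traits give NA
#'   rows/columns with a warning.
#' @export
trait_correlation_matrix <- function(blues) {
  m <- as.matrix(blues)
  if (!is.numeric(m)) pg_stop("`blues` must be numeric")
  if (nrow(m) < 3) pg_stop("need at least 3 lines")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance trait(s): ",
            paste(colnames(m)[which(sds == 0)], collapse = ", "))
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}
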