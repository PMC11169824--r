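#' Multi-trait Bayesian GBLUP with HTP-trait covariates
#'
#' Gibbs sampler for the multi-trait model
#' \deqn{y_t = 1\mu_t + g_t + e_t,\qquad
#'       vec(g) \sim MVN(0, \Sigma \otimes G),\qquad
#'       vec(e) \sim MVN(0, R \otimes I)}
#' with an unstructured genetic covariance \eqn{\Sigma} (inverse-Wishart
#' full conditional, df = n_traits + 4, scale proportional to the
#' phenotypic covariance) and a diagonal residual covariance R (per-trait
#' scaled-inverse-chi-squared). Genetic values are updated in the
#' eigenbasis of G; within each sweep a generalized eigendecomposition of
#' \eqn{\Sigma} against R diagonalizes the trait dimension as well, so the
#' whole n-by-t genetic update is vectorized.
#'
#' Missing entries (typically the primary trait of validation lines under
#' the MT-CV2 scheme) are imputed by data augmentation each sweep, so
#' posterior-mean genetic values are returned for all lines including
#' masked ones.
#'
#' @param Y line x trait matrix. Secondary (covariate) traits must be
#'   observed for all lines; the primary trait may carry NAs.
#' @param grm a `pg_grm` (or G matrix) over the same lines.
#' @param cfg a [gibbs_config()] (paper-scale default for MT fits is
#'   `gibbs_config(n_iter = 15000, burn_in = 5000)`).
#' @return class `pg_mtfit`: posterior means `mu` (per trait), `gebv`
#'   (line x trait), `Sigma`, `R` (diagonal, as a vector), `genetic_corr`
#'   (posterior-mean genetic correlation matrix), and `chains` (thinned
#'   draws of the Sigma elements and R).
#' @export
fit_mt_gblup <- function(Y, grm, cfg = gibbs_config(n_iter = 15000,
                                                    burn_in = 5000)) {
  G <- if (inherits(grm, "pg_grm")) grm$G else grm
  Y <- as.matrix(Y)
  n <- nrow(Y); t_n <- ncol(Y)
  if (t_n < 2) pg_stop("multi-trait model needs at least 2 traits")
  if (n != nrow(G)) pg_stop("nrow(Y) must match nrow(G)")
  stopifnot(inherits(cfg, "pg_gibbs"))
  traits <- colnames(Y)
  if (is.null(traits)) traits <- paste0("T", seq_len(t_n))
  miss <- is.na(Y)
  if (any(colSums(!miss) < 3))
    pg_stop("every trait needs at least 3 observed lines")
  eg <- grm_eigen(G)
  d <- eg$values; U <- eg$vectors
  act <- d > 1e-8
  n_act <- sum(act)
  da <- d[act]
  # priors
  cc <- stats::complete.cases(Y)
  Sy <- if (sum(cc) >= t_n + 2) stats::cov(Y[cc, , drop = FALSE]) else
    diag(apply(Y, 2, stats::var, na.rm = TRUE), t_n)
  Sy <- Sy + diag(1e-8 * mean(diag(Sy)), t_n)
  df0 <- t_n + 4
  S0 <- 0.5 * Sy * (df0 - t_n - 1)
  dfe <- 5
  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  S0e <- 0.5 * vy * (dfe + 2) / dfe
  set.seed(pg_seed(cfg$seed, "mtgblup"))
  # initialization
  mu <- colMeans(Y, na.rm = TRUE)
  for (j in seq_len(t_n)) Y[miss[, j], j] <- mu[j]
  Sigma <- 0.5 * Sy
  r_diag <- 0.5 * vy
  H <- matrix(0, n, t_n)
  any_miss <- any(miss)
  Ut1 <- as.numeric(crossprod(U, rep(1, n)))
  UtY <- crossprod(U, Y)              # refreshed when imputation changes Y
  keep_iters <- seq(cfg$burn_in + 1L, cfg$n_iter, by = cfg$thin)
  n_keep <- length(keep_iters)
  sum_g <- matrix(0, n, t_n); sum_mu <- rep(0, t_n)
  sum_Sigma <- matrix(0, t_n, t_n); sum_R <- rep(0, t_n)
  ut <- upper.tri(Sigma, diag = TRUE)
  sig_names <- outer(traits, traits, paste, sep = ":")[ut]
  chains <- matrix(NA_real_, n_keep, sum(ut) + t_n,
                   dimnames = list(NULL, c(paste0("Sigma_", sig_names),
                                           paste0("R_", traits))))
  ki <- 0L
  for (it in seq_len(cfg$n_iter)) {
    g <- U %*% H
    # trait intercepts
    mu <- stats::rnorm(t_n, colMeans(Y - g), sqrt(r_diag / n))
    # genetic values in the (G-eigenbasis x Sigma/R-eigenbasis)
    Ytil <- UtY - tcrossprod(Ut1, mu)
    rih <- 1 / sqrt(r_diag)
    Sstar <- Sigma * tcrossprod(rih)
    es <- eigen(Sstar, symmetric = TRUE)
    lam <- pmax(es$values, 1e-12)
    V <- es$vectors
    Tm <- sqrt(r_diag) * V             # R^{1/2} V
    B <- (Ytil[act, , drop = FALSE] * rep(rih, each = n_act)) %*% V
    P <- 1 + outer(1 / da, 1 / lam)
    M <- B / P + matrix(stats::rnorm(n_act * t_n), n_act, t_n) / sqrt(P)
    H[act, ] <- M %*% t(Tm)
    if (!all(act)) H[!act, ] <- 0
    # genetic covariance (inverse-Wishart full conditional)
    Sh <- crossprod(H[act, , drop = FALSE] / sqrt(da))
    Sc <- Sh + S0
    Sci <- tryCatch(solve(Sc), error = function(e)
      pg_stop(sprintf("Sigma update failed at iteration %d (non-PD scale)", it)))
    Sci <- (Sci + t(Sci)) / 2
    W <- stats::rWishart(1, df0 + n_act, Sci)[, , 1]
    Sigma <- solve(W)
    Sigma <- (Sigma + t(Sigma)) / 2
    # residual variances (diagonal R)
    g <- U %*% H
    resid <- Y - rep(1, n) %*% t(mu) - g
    ss <- colSums(resid^2)
    r_diag <- vapply(seq_len(t_n), function(j)
      rinvchisq(dfe + n, (ss[j] + dfe * S0e[j]) / (dfe + n)), numeric(1))
    if (!all(is.finite(Sigma)) || !all(is.finite(r_diag)))
      pg_stop(sprintf("divergent chain at iteration %d (non-finite draws)", it))
    # data augmentation for masked entries
    if (any_miss) {
      for (j in seq_len(t_n)) {
        mj <- miss[, j]
        if (any(mj))
          Y[mj, j] <- mu[j] + g[mj, j] +
            stats::rnorm(sum(mj), 0, sqrt(r_diag[j]))
      }
      UtY <- crossprod(U, Y)
    }
    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      ki <- ki + 1L
      sum_g <- sum_g + g
      sum_mu <- sum_mu + mu
      sum_Sigma <- sum_Sigma + Sigma
      sum_R <- sum_R + r_diag
      chains[ki, ] <- c(Sigma[ut], r_diag)
    }
  }
  gebv <- sum_g / n_keep
  dimnames(gebv) <- list(rownames(G), traits)
  Sig <- sum_Sigma / n_keep
  dimnames(Sig) <- list(traits, traits)
  gc_mat <- stats::cov2cor(Sig)
  structure(list(mu = stats::setNames(sum_mu / n_keep, traits),
                 gebv = gebv, Sigma = Sig,
                 R = stats::setNames(sum_R / n_keep, traits),
                 genetic_corr = gc_mat, chains = chains, cfg = cfg,
                 n_masked = colSums(miss)), class = "pg_mtfit")
}

#' @export
print.pg_mtfit <- function(x, ...) {
  cat(sprintf("<pg_mtfit> %d lines x %d traits; masked: %s\n",
              nrow(x$gebv), ncol(x$gebv),
              paste(x$n_masked, collapse = "/")))
  cat("posterior-mean genetic correlations:\n")
  print(round(x$genetic_corr, 3))
  invisible(x)
}
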