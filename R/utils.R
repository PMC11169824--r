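#' @keywords internal
"_PACKAGE"

# Deterministic child seed: fold a salt string into a base seed, keeping the
# result a valid 32-bit R integer. Used so each simulation stage draws from
# its own reproducible stream.
pg_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629L)
}

pg_stop <- function(...) stop(..., call. = FALSE)

pg_check_number <- function(x, name, lower = -Inf, upper = Inf,
                            strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    pg_stop(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    pg_stop(sprintf("`%s` = %g is outside the allowed range", name, x))
  invisible(x)
}

# Symmetric PSD check with tolerance; returns eigenvalues invisibly.
pg_check_psd <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    pg_stop(sprintf("`%s` must be a square matrix", name))
  if (max(abs(m - t(m))) > 1e-8)
    pg_stop(sprintf("`%s` must be symmetric", name))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    pg_stop(sprintf("`%s` is not positive semi-definite (min eigenvalue %.3g)",
                    name, min(ev)))
  invisible(ev)
}

# Matrix square root of a PSD matrix (eigen based; tolerates zero eigenvalues,
# unlike chol()).
pg_psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
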