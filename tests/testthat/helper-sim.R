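# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# Line-level (entry-mean) phenotypes with known heritability and genetic
# correlation: y_t = g_t + e_t with var(g_t) = h2_t and var(e_t) = 1 - h2_t.
sim_line_pheno <- function(n_lines, n_markers, h2, genetic_corr = NULL,
                           seed = 1) {
  geno <- simulate_genotypes(n_lines, n_markers, seed = seed)
  tv <- simulate_genetic_values(geno, h2, genetic_corr, seed = seed + 1)
  set.seed(phenogs:::pg_seed(seed, "linepheno"))
  E <- sapply(seq_along(h2), function(j)
    rnorm(n_lines, 0, sqrt(1 - h2[j])))
  Y <- tv$breeding_values + E
  colnames(Y) <- names(tv$h2)
  list(geno = geno, grm = compute_grm(qc_filter(geno)$geno), truth = tv, Y = Y)
}

# A small single-location RCBD config over all lines.
rcbd_config <- function(n_lines, n_markers, n_reps = 3, seed = 1,
                        h2 = c(GY = 0.5, TW = 0.7, GPC = 0.45), ...) {
  sim_config(
    n_lines = n_lines, n_markers = n_markers, n_locations = 1,
    h2 = h2,
    trials = list(list(name = "T1", type = "rcbd", lines = seq_len(n_lines),
                       n_reps = n_reps, locations = 1)),
    seed = seed, ...)
}

# Feature-matrix fixture with a purely linear, noiseless target.
linear_feature_fixture <- function(n = 500, p = 40, seed = 9,
                                   permute = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("F", seq_len(p))))
  y <- as.numeric(x %*% rnorm(p))
  if (permute) y <- sample(y)
  structure(list(x = x, y = matrix(y, ncol = 1, dimnames = list(NULL, "GY")),
                 plot_id = sprintf("P%04d", seq_len(n)), stages = "F8",
                 n_dropped = 0L),
            class = "pg_features")
}

# Band fixture for index tests.
bands_fix <- function(blue = 0.05, green = 0.1, red = 0.1,
                      red_edge = 0.2, nir = 0.5) {
  c(blue = blue, green = green, red = red, red_edge = red_edge, nir = nir)
}
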