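#' The vegetation-index registry
#'
#' Twenty vegetation indices computable from the five Altum-PT bands
#' (blue, green, red, red_edge, nir), using their standard literature
#' definitions. Each entry carries the formula, its literature source, and
#' whether the index is a pure band ratio (invariant to multiplying all
#' bands by a positive constant) or involves additive constants.
#'
#' Registry entries are plain functions of the five named band values; the
#' registry is user-extensible via [register_index()], so an alternative
#' formula variant is a one-line change.
#'
#' @return named list of registry entries (`fun`, `ratio`, `bounded`, `ref`).
#' @export
vi_registry <- function() .pg_vi_env$registry

.pg_vi_env <- new.env(parent = emptyenv())

vi_entry <- function(fun, ratio, bounded, ref) {
  list(fun = fun, ratio = ratio, bounded = bounded, ref = ref)
}

# Division guard: denominators below 1e-9 in absolute value yield NA for
# that index rather than a silent infinity.
vi_div <- function(num, den) ifelse(abs(den) < 1e-9, NA_real_, num / den)

.pg_vi_defaults <- function() list(
  NDVI = vi_entry(function(b) vi_div(b$nir - b$red, b$nir + b$red),
                  TRUE, TRUE, "Rouse et al. 1974"),
  GNDVI = vi_entry(function(b) vi_div(b$nir - b$green, b$nir + b$green),
                   TRUE, TRUE, "Gitelson et al. 1996"),
  GCI = vi_entry(function(b) vi_div(b$nir, b$green) - 1,
                 TRUE, FALSE, "Gitelson et al. 2003"),
  RECI = vi_entry(function(b) vi_div(b$nir, b$red_edge) - 1,
                  TRUE, FALSE, "Gitelson et al. 2003"),
  RVI = vi_entry(function(b) vi_div(b$nir, b$red),
                 TRUE, FALSE, "Jordan 1969"),
  RVI_2 = vi_entry(function(b) vi_div(b$nir, b$green),
                   TRUE, FALSE, "simple ratio, green variant"),
  ARI = vi_entry(function(b) vi_div(1, b$green) - vi_div(1, b$red_edge),
                 FALSE, FALSE, "Gitelson et al. 2001"),
  ARI_2 = vi_entry(function(b) b$nir * (vi_div(1, b$green) - vi_div(1, b$red_edge)),
                   FALSE, FALSE, "Gitelson et al. 2001"),
  PSRI = vi_entry(function(b) vi_div(b$red - b$green, b$red_edge),
                  TRUE, FALSE, "Merzlyak et al. 1999"),
  IKAW = vi_entry(function(b) vi_div(b$red - b$blue, b$red + b$blue),
                  TRUE, TRUE, "Kawashima & Nakatani 1998"),
  NDWI = vi_entry(function(b) vi_div(b$green - b$nir, b$green + b$nir),
                  TRUE, TRUE, "McFeeters 1996"),
  SAVI = vi_entry(function(b) vi_div(1.5 * (b$nir - b$red), b$nir + b$red + 0.5),
                  FALSE, FALSE, "Huete 1988, L = 0.5"),
  SAVI_2 = vi_entry(function(b) vi_div(b$nir, b$red + 0.5),
                    FALSE, FALSE, "Major et al. 1990, b/a = 0.5"),
  OSAVI = vi_entry(function(b) vi_div(1.16 * (b$nir - b$red), b$nir + b$red + 0.16),
                   FALSE, FALSE, "Rondeaux et al. 1996"),
  ENDVI = vi_entry(function(b) vi_div(b$nir + b$green - 2 * b$blue,
                                      b$nir + b$green + 2 * b$blue),
                   TRUE, TRUE, "enhanced ND, blue-corrected"),
  EVI = vi_entry(function(b) vi_div(2.5 * (b$nir - b$red),
                                    b$nir + 6 * b$red - 7.5 * b$blue + 1),
                 FALSE, FALSE, "Huete et al. 2002"),
  EVI_2 = vi_entry(function(b) vi_div(2.5 * (b$nir - b$red),
                                      b$nir + 2.4 * b$red + 1),
                   FALSE, FALSE, "Jiang et al. 2008"),
  MCARI = vi_entry(function(b) ((b$red_edge - b$red) -
                                  0.2 * (b$red_edge - b$green)) *
                     vi_div(b$red_edge, b$red),
                   FALSE, FALSE, "Daughtry et al. 2000"),
  TCARI = vi_entry(function(b) 3 * ((b$red_edge - b$red) -
                                      0.2 * (b$red_edge - b$green) *
                                      vi_div(b$red_edge, b$red)),
                   FALSE, FALSE, "Haboudane et al. 2002"),
  TCARI_OSAVI = vi_entry(function(b) {
    tcari <- 3 * ((b$red_edge - b$red) -
                    0.2 * (b$red_edge - b$green) * vi_div(b$red_edge, b$red))
    osavi <- vi_div(1.16 * (b$nir - b$red), b$nir + b$red + 0.16)
    vi_div(tcari, osavi)
  }, FALSE, FALSE, "Haboudane et al. 2002"))

#' @rdname vi_registry
#' @param name index name.
#' @param fun function of a list of bands (blue, green, red, red_edge, nir).
#' @param ratio is the index invariant to positive rescaling of all bands?
#' @param bounded is the index a normalized difference bounded in \[-1, 1\]?
#' @param ref literature citation string.
#' @export
register_index <- function(name, fun, ratio = FALSE, bounded = FALSE,
                           ref = "user-supplied") {
  .pg_vi_env$registry[[name]] <- vi_entry(fun, ratio, bounded, ref)
  invisible(name)
}

pg_bands <- c("blue", "green", "red", "red_edge", "nir")

check_bands <- function(bands) {
  if (is.null(names(bands)) || !all(pg_bands %in% names(bands)))
    pg_stop("bands must be named: ", paste(pg_bands, collapse = ", "))
  b <- as.list(bands[pg_bands])
  vals <- unlist(b, use.names = FALSE)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    pg_stop("band reflectances must lie in [0, 1]")
  b
}

#' Compute a vegetation index from five band reflectances
#'
#' @param bands named numeric vector or list with elements blue, green,
#'   red, red_edge, nir, each in \[0, 1\] (vectors allowed, equal length).
#' @param name index name present in [vi_registry()].
#' @return the index value(s); NA where a denominator is degenerate.
#' @examples
#' compute_index(c(blue = .05, green = .1, red = .1, red_edge = .2, nir = .5),
#'               "NDVI")
#' @export
compute_index <- function(bands, name) {
  reg <- vi_registry()
  if (!name %in% names(reg))
    pg_stop("unknown vegetation index: ", name)
  b <- check_bands(bands)
  reg[[name]]$fun(b)
}

#' Compute the full vegetation-index table from plot reflectance
#'
#' @param reflectance data.frame with columns plot_id, stage and the five
#'   band columns (as written by [simulate_reflectance()]).
#' @param indices index names (default: the full registry).
#' @return data.frame keyed by (plot_id, stage) with one column per index.
#' @export
compute_vi_table <- function(reflectance, indices = names(vi_registry())) {
  need <- c("plot_id", "stage", pg_bands)
  miss <- setdiff(need, names(reflectance))
  if (length(miss)) pg_stop("reflectance table missing columns: ",
                            paste(miss, collapse = ", "))
  b <- check_bands(as.list(reflectance[pg_bands]))
  reg <- vi_registry()
  unknown <- setdiff(indices, names(reg))
  if (length(unknown)) pg_stop("unknown vegetation index: ",
                               paste(unknown, collapse = ", "))
  vals <- lapply(indices, function(nm) reg[[nm]]$fun(b))
  names(vals) <- indices
  cbind(reflectance[c("plot_id", "stage")],
        as.data.frame(vals, optional = TRUE))
}

#' Plot-level zonal means of a gridded band raster
#'
#' @param grid numeric matrix (one band's pixel values).
#' @param mask integer/character matrix of the same shape assigning each
#'   cell to a plot; cells with NA (or 0 / "") belong to no plot.
#' @return data.frame (plot_id, mean) with the arithmetic mean of grid
#'   values over each plot's cells.
#' @export
zonal_mean <- function(grid, mask) {
  if (!is.matrix(grid) || !identical(dim(grid), dim(mask)))
    pg_stop("`grid` and `mask` must be matrices of equal shape")
  m <- as.vector(mask)
  keep <- !is.na(m) & m != 0 & m != ""
  if (!any(keep)) pg_stop("mask assigns no cell to any plot")
  means <- tapply(as.vector(grid)[keep], m[keep], mean)
  empty <- names(means)[is.na(means)]
  if (length(empty)) pg_stop("empty mask for plot(s): ",
                             paste(empty, collapse = ", "))
  data.frame(plot_id = names(means), mean = as.numeric(means),
             stringsAsFactors = FALSE)
}

#' Assemble a multitemporal feature matrix for phenomic prediction
#'
#' Pivots the VI table wide — one row per plot, one column per
#' (index, stage) combination named `<index>_<stage>` — restricted to the
#' requested stages, and joins the plot-level target traits. Plots missing
#' any requested feature or target are dropped with a message.
#'
#' @param vi VI table from [compute_vi_table()].
#' @param pheno plot phenotype table (plot_id + trait columns).
#' @param stages stage subset (default: all stages present).
#' @param targets trait columns to carry (default GY, TW, GPC when present).
#' @return class `pg_features`: list with `x` (plot x feature matrix),
#'   `y` (plot x target matrix), `plot_id`, `stages`, `n_dropped`.
#' @export
build_feature_matrix <- function(vi, pheno, stages = NULL, targets = NULL) {
  if (is.null(stages)) stages <- unique(vi$stage)
  if (length(stages) == 0) pg_stop("stage subset must be non-empty")
  bad <- setdiff(stages, unique(vi$stage))
  if (length(bad)) pg_stop("stages absent from VI table: ",
                           paste(bad, collapse = ", "))
  if (is.null(targets))
    targets <- intersect(c("GY", "TW", "GPC"), names(pheno))
  if (!length(targets)) pg_stop("no target trait columns found in `pheno`")
  idx_cols <- setdiff(names(vi), c("plot_id", "stage"))
  vi <- vi[vi$stage %in% stages, , drop = FALSE]
  wide <- stats::reshape(vi, direction = "wide", idvar = "plot_id",
                         timevar = "stage", sep = "_")
  feat_cols <- setdiff(names(wide), "plot_id")
  common <- intersect(wide$plot_id, pheno$plot_id)
  if (!length(common)) pg_stop("no common plot_ids between VI and phenotype tables")
  wide <- wide[match(common, wide$plot_id), , drop = FALSE]
  ph <- pheno[match(common, pheno$plot_id), targets, drop = FALSE]
  x <- as.matrix(wide[feat_cols])
  y <- as.matrix(ph)
  complete <- stats::complete.cases(x) & stats::complete.cases(y)
  n_dropped <- sum(!complete) + length(setdiff(union(vi$plot_id, pheno$plot_id),
                                               common))
  if (n_dropped > 0)
    message(sprintf("build_feature_matrix: dropped %d incomplete plot(s)",
                    n_dropped))
  x <- x[complete, , drop = FALSE]
  y <- y[complete, , drop = FALSE]
  rownames(x) <- rownames(y) <- common[complete]
  structure(list(x = x, y = y, plot_id = common[complete],
                 stages = stages, n_dropped = n_dropped),
            class = "pg_features")
}

#' @export
print.pg_features <- function(x, ...) {
  cat(sprintf("<pg_features> %d plots x %d features (stages: %s); targets: %s\n",
              nrow(x$x), ncol(x$x), paste(x$stages, collapse = ","),
              paste(colnames(x$y), collapse = ",")))
  invisible(x)
}

#' Stage-wise Pearson correlations of HTP traits with primary traits
#'
#' Correlates each (index, stage) column with each primary trait across
#' plots (or lines, if line-level BLUEs are supplied with matching ids).
#' Zero-variance columns yield NA with a warning rather than an error.
#'
#' @param vi VI table from [compute_vi_table()].
#' @param pheno table with plot_id (or line) and trait columns.
#' @param targets trait names (default GY, TW, GPC when present).
#' @return long data.frame: index, stage, trait, r, n.
#' @export
stagewise_trait_correlations <- function(vi, pheno, targets = NULL) {
  if (is.null(targets))
    targets <- intersect(c("GY", "TW", "GPC"), names(pheno))
  key <- if ("plot_id" %in% names(pheno)) "plot_id" else "line"
  common <- intersect(vi$plot_id, pheno[[key]])
  if (length(common) < 3) pg_stop("need at least 3 common plots/lines")
  idx_cols <- setdiff(names(vi), c("plot_id", "stage"))
  out <- list()
  for (stage in unique(vi$stage)) {
    sub <- vi[vi$stage == stage, , drop = FALSE]
    sub <- sub[match(common, sub$plot_id), , drop = FALSE]
    ph <- pheno[match(common, pheno[[key]]), targets, drop = FALSE]
    for (ic in idx_cols) for (tr in targets) {
      xv <- sub[[ic]]; yv <- ph[[tr]]
      ok <- is.finite(xv) & is.finite(yv)
      r <- if (sum(ok) < 3 || stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
        warning(sprintf("undefined correlation for %s at %s vs %s", ic, stage, tr))
        NA_real_
      } else stats::cor(xv[ok], yv[ok])
      out[[length(out) + 1L]] <- data.frame(
        index = ic, stage = stage, trait = tr, r = r, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
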