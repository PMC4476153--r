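#' Standard major axis (SMA) fit
#'
#' Symmetric line fitting for the male-vs-female Z comparison:
#' `slope = sign(r) * SD(y) / SD(x)`, intercept through the centroid. The
#' SMA slope is the geometric mean of the y-on-x least-squares slope and the
#' reciprocal of the x-on-y slope, and inverts exactly under swapping the
#' axes.
#'
#' @param x,y paired scores (e.g. mean male Z and female Z), n >= 3,
#'   both non-constant.
#' @return list of class `sma_fit`: `slope`, `intercept`, `r`, `n`.
#' @export
#' @examples
#' sma_fit(c(1, 2, 3), c(2, 4, 6))  # slope 2, intercept 0
sma_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  if (sdx == 0 || sdy == 0) stop("constant input: SMA slope undefined")
  r <- stats::cor(x, y)
  slope <- sign(r) * sdy / sdx
  if (slope == 0) slope <- sdy / sdx  # r exactly 0: conventionally positive
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r = r, n = length(x)),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("SMA fit: slope ", format(x$slope), ", intercept ",
      format(x$intercept), ", r ", format(x$r), ", n ", x$n, "\n", sep = "")
  invisible(x)
}

#' Standardized residuals from an SMA fit
#'
#' The degree-of-change-in-sex-bias score: the signed deviation of each gene
#' from the fitted male/female line, divided by the SD of those deviations
#' (so the emitted standardized residuals have SD 1). By default the
#' vertical deviation `y - (a + b x)` is used; `orthogonal = TRUE` uses the
#' signed perpendicular distance instead (identical up to a monotone rescale
#' for a fixed line, so rank-based downstream statistics do not change).
#'
#' @param fit an [sma_fit()].
#' @param x,y the scores the fit was computed from (vectors named by gene).
#' @param orthogonal use signed perpendicular distance.
#' @return data.frame: `gene`, `residual`, `standardized`, `modulus`.
#' @export
standardized_residuals <- function(fit, x, y, orthogonal = FALSE) {
  stopifnot(length(x) == length(y))
  genes <- names(x) %||% seq_along(x)
  res <- y - (fit$intercept + fit$slope * x)
  if (orthogonal) res <- res / sqrt(1 + fit$slope^2)
  s <- stats::sd(res[is.finite(res)])
  std <- if (is.na(s) || s == 0) res * 0 else res / s
  data.frame(gene = genes, residual = res, standardized = std,
             modulus = abs(std), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Genomic clustering of sex-bias residuals
#'
#' Runs the neighborhood battery with standardized residuals in place of Z:
#' the three neighbor-correlation modes, the sign-run randomization test and
#' (optionally) a distance-decay profile.
#'
#' @param residuals named vector of standardized residuals (by gene).
#' @param map a [gene_map()].
#' @param max_gap,radius neighborhood parameters (bp).
#' @param n_rand randomizations for the run test.
#' @param seed RNG seed.
#' @param min_gaps optional grid for [distance_decay()] (skipped if NULL).
#' @return list: `downstream`, `flank_pair`, `window`
#'   (correlation results), `run_test` (an `mc_result`), `decay` (or NULL).
#' @export
residual_clustering <- function(residuals, map, max_gap = 1e5, radius = 1e5,
                                n_rand = 1000, seed = NULL,
                                min_gaps = NULL) {
  map <- .check_map(map)
  res <- list(
    downstream = neighbor_correlation(residuals, map, mode = "downstream",
                                      max_gap = max_gap),
    flank_pair = neighbor_correlation(residuals, map, mode = "flank_pair",
                                      max_gap = max_gap),
    window = neighbor_correlation(residuals, map, mode = "window",
                                  radius = radius))
  sub <- map[map$gene %in% names(residuals), ]
  s <- sign(residuals[sub$gene])
  res$run_test <- run_randomization_test(s, sub$chrom, n_rand = n_rand,
                                         seed = seed)
  res$decay <- if (!is.null(min_gaps))
    distance_decay(residuals, map, min_gaps, n_rand = n_rand, seed = seed)
  res
}

#' X-chromosome tests of sex-biased change
#'
#' (a) Mann-Whitney comparison of the modulus of the standardized residual
#' between X-linked genes and autosomal genes; (b) 2x2 chi-square of
#' X-membership against membership of the top `top_fraction` most extreme
#' moduli (set size exactly `ceiling(top_fraction * n)`); (c) when a
#' `z_table` stratum is supplied, a per-tissue Mann-Whitney of Z between X
#' and autosomes.
#'
#' @param residuals data.frame from [standardized_residuals()] (or a named
#'   modulus vector).
#' @param map a [gene_map()].
#' @param x_chrom name of the X chromosome in the map.
#' @param top_fraction tail definition for the extreme-change test.
#' @param z optional named per-gene Z vector for the median-Z contrast.
#' @return list: `modulus_test` (U, P, medians), `extreme_test` (table,
#'   chi2, P, `n_top`), `z_test` (or NULL).
#' @export
x_chromosome_tests <- function(residuals, map, x_chrom = "chrX",
                               top_fraction = 0.05, z = NULL) {
  map <- .check_map(map)
  if (!x_chrom %in% map$chrom) stop("no genes on ", x_chrom, " in map")
  mod <- if (is.data.frame(residuals))
    stats::setNames(residuals$modulus, residuals$gene) else residuals
  genes <- intersect(names(mod), map$gene)
  mod <- mod[genes]
  on_x <- map$chrom[match(genes, map$gene)] == x_chrom
  if (!any(on_x)) stop("no scored genes on ", x_chrom)
  mw <- mann_whitney(mod[on_x], mod[!on_x])
  n_top <- ceiling(top_fraction * length(mod))
  top <- rank(-mod, ties.method = "first") <= n_top
  tab <- table(X = factor(on_x, levels = c(FALSE, TRUE)),
               top = factor(top, levels = c(FALSE, TRUE)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- list(
    modulus_test = list(U = mw$U, p_value = mw$p_value,
                        median_x = stats::median(mod[on_x]),
                        median_autosome = stats::median(mod[!on_x])),
    extreme_test = list(table = tab, chi2 = unname(ct$statistic),
                        p_value = ct$p.value, n_top = n_top))
  if (!is.null(z)) {
    zg <- intersect(names(z), map$gene)
    zx <- map$chrom[match(zg, map$gene)] == x_chrom
    zmw <- mann_whitney(z[zg][zx], z[zg][!zx])
    out$z_test <- list(U = zmw$U, p_value = zmw$p_value,
                       median_x = stats::median(z[zg][zx]),
                       median_autosome = stats::median(z[zg][!zx]))
  }
  out
}
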