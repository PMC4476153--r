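#' Spearman rank correlation with flagged degenerate cases
#'
#' Rho uses average ranks for ties. The P value uses the t approximation for
#' n > 10 and the exact null distribution (via [stats::cor.test()]) for
#' smaller samples. Constant input gives an undefined rho, flagged rather
#' than raised.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `defined`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          defined = FALSE), class = "correlation_result"))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (n > 10) {
    if (abs(rho) >= 1) 0
    else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    suppressWarnings(stats::cor.test(x, y, method = "spearman")$p.value)
  }
  structure(list(rho = rho, p_value = p, n = n, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Spearman rho = ", format(x$rho), ", P = ", format(x$p_value),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Focal/neighbor Z pairs under one of the three neighborhood definitions
#'
#' Builds the (focal statistic, neighbor statistic) pairs behind the
#' neighbor correlations. Modes: `"downstream"` pairs each focal gene with
#' its nearest downstream neighbor (non-overlapping pairs by default;
#' `overlapping_only = TRUE` selects instead the overlapping pairs);
#' `"flank_pair"` requires both an upstream and a downstream neighbor within
#' `max_gap` and averages their scores; `"window"` averages all neighbors
#' within `radius`, dropping focal genes that overlap an adjacent gene while
#' keeping overlapping non-focal neighbors.
#'
#' @param z named numeric vector of per-gene scores (genes absent from `z`,
#'   e.g. zero-flag excluded genes, are ignored entirely).
#' @param map a [gene_map()].
#' @param mode `"downstream"`, `"flank_pair"` or `"window"`.
#' @param max_gap,convention see [nearest_downstream()].
#' @param radius window half-width for `"window"` mode.
#' @param overlapping_only for `"downstream"`/`"flank_pair"`: keep only pairs
#'   involving an overlap (the overlapping-gene analyses).
#' @return data.frame with `focal`, `focal_z`, `neighbor_z`, `n_neighbors`.
#' @export
neighbor_pairs <- function(z, map, mode = c("downstream", "flank_pair", "window"),
                           max_gap = 1e5, convention = "body_gap",
                           radius = 1e5, overlapping_only = FALSE) {
  mode <- match.arg(mode)
  map <- .check_map(map)
  map <- map[map$gene %in% names(z), ]
  class(map) <- c("gene_map", "data.frame")
  if (!nrow(map))
    return(data.frame(focal = character(0), focal_z = numeric(0),
                      neighbor_z = numeric(0), n_neighbors = integer(0)))
  if (mode == "downstream") {
    pr <- downstream_pairs(map, max_gap = max_gap, convention = convention)
    pr <- pr[if (overlapping_only) pr$overlapping else !pr$overlapping, ]
    data.frame(focal = pr$focal, focal_z = unname(z[pr$focal]),
               neighbor_z = unname(z[pr$neighbor]),
               n_neighbors = rep(1L, nrow(pr)), stringsAsFactors = FALSE)
  } else if (mode == "flank_pair") {
    nxt <- .downstream_index(map)
    prv <- rep(NA_integer_, nrow(map))
    has <- which(!is.na(nxt))
    prv[nxt[has]] <- has                      # inverse of the downstream map
    i <- which(!is.na(nxt) & !is.na(prv))
    if (!length(i)) return(.empty_neighbor_pairs())
    gap_up <- .body_gap(map, prv[i], i)
    gap_dn <- .body_gap(map, i, nxt[i])
    d_up <- if (convention == "body_gap") pmax(gap_up, 0L) else
      abs(map$start[i] - map$start[prv[i]])
    d_dn <- if (convention == "body_gap") pmax(gap_dn, 0L) else
      abs(map$start[nxt[i]] - map$start[i])
    any_ov <- gap_up < 0 | gap_dn < 0
    keep <- d_up <= max_gap & d_dn <= max_gap & (any_ov == overlapping_only)
    i <- i[keep]; up <- prv[i]; dn <- nxt[i]
    data.frame(focal = map$gene[i], focal_z = unname(z[map$gene[i]]),
               neighbor_z = (unname(z[map$gene[up]]) +
                             unname(z[map$gene[dn]])) / 2,
               n_neighbors = rep(2L, length(i)), stringsAsFactors = FALSE)
  } else {
    ov_adj <- .overlaps_adjacent(map)
    gr <- .map_granges(map)
    hits <- GenomicRanges::findOverlaps(gr, gr, maxgap = radius,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- qh != sh
    qh <- qh[keep]; sh <- sh[keep]
    zz <- z[map$gene]
    mean_z <- tapply(zz[sh], factor(qh, levels = seq_len(nrow(map))),
                     mean)
    cnt <- tabulate(qh, nbins = nrow(map))
    sel <- cnt > 0 & !ov_adj
    data.frame(focal = map$gene[sel], focal_z = unname(zz[sel]),
               neighbor_z = as.numeric(mean_z[sel]), n_neighbors = cnt[sel],
               stringsAsFactors = FALSE)
  }
}

.empty_neighbor_pairs <- function() {
  data.frame(focal = character(0), focal_z = numeric(0),
             neighbor_z = numeric(0), n_neighbors = integer(0),
             stringsAsFactors = FALSE)
}

#' Neighbor Z correlation
#'
#' Spearman correlation between focal and neighbor scores under one of the
#' three neighborhood definitions of [neighbor_pairs()]. Fewer than 3 pairs
#' gives an undefined, flagged result.
#'
#' @inheritParams neighbor_pairs
#' @return a `correlation_result` (with the pair table attached as
#'   `attr(, "pairs")`).
#' @export
neighbor_correlation <- function(z, map, mode = "downstream", max_gap = 1e5,
                                 convention = "body_gap", radius = 1e5,
                                 overlapping_only = FALSE) {
  pr <- neighbor_pairs(z, map, mode = mode, max_gap = max_gap,
                       convention = convention, radius = radius,
                       overlapping_only = overlapping_only)
  res <- spearman_cor(pr$focal_z, pr$neighbor_z)
  attr(res, "pairs") <- pr
  res
}

#' Rank-binned means of focal/neighbor scores
#'
#' Pairs are ordered by focal score and cut into consecutive bins of
#' `bin_size`; the last bin may be partial and is flagged.
#'
#' @param focal_z,neighbor_z paired scores.
#' @param bin_size genes per bin (default 500).
#' @return data.frame: `bin`, `n`, `focal_mean`, `neighbor_mean`,
#'   `neighbor_sem`, `partial`.
#' @export
bin_means <- function(focal_z, neighbor_z, bin_size = 500) {
  stopifnot(length(focal_z) == length(neighbor_z), bin_size >= 1)
  o <- order(focal_z)
  focal_z <- focal_z[o]; neighbor_z <- neighbor_z[o]
  bin <- (seq_along(focal_z) - 1L) %/% bin_size + 1L
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  out <- data.frame(
    bin = unique(bin),
    n = as.integer(table(bin)),
    focal_mean = as.numeric(tapply(focal_z, bin, mean)),
    neighbor_mean = as.numeric(tapply(neighbor_z, bin, mean)),
    neighbor_sem = as.numeric(tapply(neighbor_z, bin, sem)))
  out$partial <- out$n < bin_size
  out
}

#' Sign runs and edges along chromosomes
#'
#' Zeros are removed ("too indecisive"); within each chromosome the
#' remaining +1/-1 sequence is decomposed into maximal runs (clusters). An
#' edge is a switch between adjacent unequal signs, so the total edge count
#' equals the number of clusters minus the number of chromosomes holding at
#' least one non-zero gene. `"+++-+++"` has two edges and clusters of sizes
#' 3, 1, 3.
#'
#' @param signs numeric vector in `{-1, 0, 1}` in map order.
#' @param chrom chromosome of each entry (single chromosome assumed when
#'   missing).
#' @param map optional [gene_map()] aligned with `signs`, used to attach the
#'   genomic span of every cluster.
#' @return list of class `run_spectrum`: `edge_count`, `clusters`
#'   (data.frame `chrom`, `sign`, `size`, and `span_bp` when `map` given),
#'   `n_used`, `n_chrom`.
#' @export
run_edges <- function(signs, chrom = NULL, map = NULL) {
  stopifnot(all(signs %in% c(-1, 0, 1)))
  if (is.null(chrom)) chrom <- rep("chr", length(signs))
  stopifnot(length(chrom) == length(signs))
  keep <- signs != 0
  cl <- list(); edges <- 0L; nchr <- 0L
  for (ch in unique(chrom)) {
    sel <- keep & chrom == ch
    s <- signs[sel]
    if (!length(s)) next
    nchr <- nchr + 1L
    r <- rle(s)
    edges <- edges + length(r$lengths) - 1L
    cdf <- data.frame(chrom = ch, sign = r$values, size = r$lengths)
    if (!is.null(map)) {
      idx <- which(sel)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      cdf$span_start <- map$start[idx[starts]]
      cdf$span_end <- map$end[idx[ends]]
      cdf$span_bp <- cdf$span_end - cdf$span_start + 1L
    }
    cl[[ch]] <- cdf
  }
  clusters <- if (length(cl)) do.call(rbind, cl) else
    data.frame(chrom = character(0), sign = numeric(0), size = integer(0))
  rownames(clusters) <- NULL
  structure(list(edge_count = edges, clusters = clusters,
                 n_used = sum(keep), n_chrom = nchr),
            class = "run_spectrum")
}

#' Exact Monte Carlo P value
#'
#' The unbiased empirical type-I error estimate `(N+1)/(M+1)`, where `N`
#' null statistics out of `M` are as or more extreme than the observation.
#'
#' @param N count of as-or-more-extreme null statistics (0 <= N <= M).
#' @param M number of randomizations (>= 1).
#' @return the probability as a plain numeric.
#' @export
#' @examples
#' empirical_p(0, 10000)  # 9.999e-05
empirical_p <- function(N, M) {
  if (M < 1 || N < 0 || N > M) stop("need 0 <= N <= M, M >= 1")
  (N + 1) / (M + 1)
}

#' Run-edge randomization test for sign clustering
#'
#' Permutes signs within each chromosome (preserving the per-chromosome
#' counts of +, - and 0), recomputes total edges, and reports a one-tailed
#' empirical P for fewer-edges-than-expected (clustering) together with the
#' null envelope.
#'
#' @inheritParams run_edges
#' @param n_rand number of randomizations.
#' @param seed RNG seed (optional).
#' @return list of class `mc_result`: observed statistic, `N`, `M`,
#'   `empirical_p`, `direction`, and `envelope` (null mean, sd,
#'   mean -/+ 1.96 sd).
#' @export
run_randomization_test <- function(signs, chrom = NULL, n_rand = 10000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom)) chrom <- rep("chr", length(signs))
  obs <- run_edges(signs, chrom)$edge_count
  groups <- split(seq_along(signs), chrom)
  null_edges <- vapply(seq_len(n_rand), function(i) {
    s <- signs
    for (idx in groups) s[idx] <- s[sample(idx)]
    run_edges(s, chrom)$edge_count
  }, numeric(1))
  .mc_result(obs, null_edges, direction = "less")
}

.mc_result <- function(obs, null_stats, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  N <- if (direction == "less") sum(null_stats <= obs) else
    sum(null_stats >= obs)
  M <- length(null_stats)
  mu <- mean(null_stats); sdv <- stats::sd(null_stats)
  structure(list(observed = obs, N = N, M = M,
                 empirical_p = empirical_p(N, M), direction = direction,
                 envelope = list(mean = mu, sd = sdv,
                                 lower = mu - 1.96 * sdv,
                                 upper = mu + 1.96 * sdv)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo: observed ", format(x$observed), ", null ",
      format(x$envelope$mean), " +/- ", format(x$envelope$sd),
      ", empirical P (", x$direction, ") = ", format(x$empirical_p),
      " [N=", x$N, ", M=", x$M, "]\n", sep = "")
  invisible(x)
}

#' Cluster-size spectrum against a randomization null
#'
#' Counts sign clusters by size for the observed arrangement and for
#' `n_rand` within-chromosome permutations; per size, the empirical P is the
#' fraction of randomizations with as many or more clusters of that size.
#' Cluster genomic spans are attached when a map is given (for
#' cluster-length comparisons between + and - clusters).
#'
#' @inheritParams run_randomization_test
#' @param map optional [gene_map()] aligned with `signs`.
#' @return list of class `cluster_spectrum`: `observed` (counts by size),
#'   `null_mean`, `null_q025`, `null_q975`, `p_value` per size, `clusters`
#'   (observed cluster table), `n_rand`.
#' @export
cluster_spectrum_test <- function(signs, chrom = NULL, n_rand = 1000,
                                  seed = NULL, map = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom)) chrom <- rep("chr", length(signs))
  rs <- run_edges(signs, chrom, map = map)
  groups <- split(seq_along(signs), chrom)
  # largest possible cluster: the most non-zero genes on one chromosome
  max_size <- max(1L, vapply(groups, function(i) sum(signs[i] != 0),
                             integer(1)))
  count_by_size <- function(sizes, upto) tabulate(sizes, nbins = upto)
  null_counts <- matrix(0L, n_rand, max_size)
  for (i in seq_len(n_rand)) {
    s <- signs
    for (idx in groups) s[idx] <- s[sample(idx)]
    sz <- run_edges(s, chrom)$clusters$size
    if (length(sz)) null_counts[i, ] <- count_by_size(sz, max_size)
  }
  obs <- count_by_size(rs$clusters$size, max_size)
  p <- vapply(seq_len(max_size), function(k)
    empirical_p(sum(null_counts[, k] >= obs[k]), n_rand), numeric(1))
  structure(list(observed = obs, size = seq_len(max_size),
                 null_mean = colMeans(null_counts),
                 null_q025 = apply(null_counts, 2, stats::quantile, 0.025),
                 null_q975 = apply(null_counts, 2, stats::quantile, 0.975),
                 p_value = p, clusters = rs$clusters, n_rand = n_rand),
            class = "cluster_spectrum")
}

#' Distance-decay profile of the neighbor correlation
#'
#' For each minimum distance `x` in `min_gaps`, every focal gene is paired
#' with the nearest downstream gene at least `x` bp away (body gap) and the
#' Spearman rho of the resulting pairs is computed. A null envelope (mean
#' +/- 1.96 sd over `n_rand` shuffles of the scores across loci, genome-wide
#' by default or within chromosomes) is attached per grid point.
#'
#' @param z named per-gene scores.
#' @param map a [gene_map()].
#' @param min_gaps strictly increasing vector of minimum distances (bp).
#' @param n_rand randomizations for the envelope.
#' @param seed RNG seed.
#' @param per_chromosome shuffle within chromosomes instead of genome-wide.
#' @return data.frame of class `decay_profile`: `min_gap`, `n`, `rho`, `p`,
#'   `null_mean`, `null_sd`, `lower`, `upper`, `defined`.
#' @export
distance_decay <- function(z, map, min_gaps, n_rand = 1000, seed = NULL,
                           per_chromosome = FALSE) {
  if (is.unsorted(min_gaps, strictly = TRUE))
    stop("min_gaps must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  map <- .check_map(map)
  map <- map[map$gene %in% names(z), ]
  zz <- z[map$gene]
  n <- nrow(map)
  chrom_idx <- split(seq_len(n), map$chrom)
  rk <- rank(zz)
  # permuted rank matrix reused across grid points
  perms <- matrix(0, n, n_rand)
  for (r in seq_len(n_rand)) {
    if (per_chromosome) {
      p <- seq_len(n)
      for (idx in chrom_idx) p[idx] <- idx[sample(length(idx))]
      perms[, r] <- rk[p]
    } else perms[, r] <- rk[sample(n)]
  }
  rows <- lapply(min_gaps, function(x) {
    fi <- integer(0); ni <- integer(0)
    for (idx in chrom_idx) {
      st <- map$start[idx]
      # nearest downstream gene with body gap >= x: first start >= end+1+x
      pos <- findInterval(map$end[idx] + x, st) + 1L
      ok <- pos <= length(idx)
      fi <- c(fi, idx[ok]); ni <- c(ni, idx[pos[ok]])
    }
    if (length(fi) < 3)
      return(data.frame(min_gap = x, n = length(fi), rho = NA_real_,
                        p = NA_real_, null_mean = NA_real_,
                        null_sd = NA_real_, lower = NA_real_,
                        upper = NA_real_, defined = FALSE))
    res <- spearman_cor(zz[fi], zz[ni])
    null_rho <- vapply(seq_len(n_rand), function(r)
      stats::cor(rank(perms[fi, r]), rank(perms[ni, r])), numeric(1))
    mu <- mean(null_rho); sdv <- stats::sd(null_rho)
    data.frame(min_gap = x, n = res$n, rho = res$rho, p = res$p_value,
               null_mean = mu, null_sd = sdv, lower = mu - 1.96 * sdv,
               upper = mu + 1.96 * sdv, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("decay_profile", "data.frame")
  out
}

#' Monte Carlo comparison of a subset's correlation against random subsets
#'
#' Draws `n_draws` random subsets of the pair pool of the same size as the
#' observed subset, computes Spearman rho for each, and reports the
#' one-tailed (greater) empirical P: the fraction of draws with rho as great
#' or greater than observed, via `(N+1)/(M+1)`.
#'
#' @param pool data.frame of pairs with columns `focal_z`, `neighbor_z`.
#' @param subset_rho observed rho of the subset of interest.
#' @param subset_size its number of pairs (must not exceed the pool).
#' @param n_draws number of random subsets.
#' @param seed RNG seed.
#' @return an `mc_result` (direction `"greater"`).
#' @export
subset_mc <- function(pool, subset_rho, subset_size, n_draws = 10000,
                      seed = NULL) {
  if (subset_size > nrow(pool)) stop("subset larger than pool")
  if (!is.null(seed)) set.seed(seed)
  rx <- rank(pool$focal_z); ry <- rank(pool$neighbor_z)
  null_rho <- vapply(seq_len(n_draws), function(i) {
    idx <- sample(nrow(pool), subset_size)
    stats::cor(rank(rx[idx]), rank(ry[idx]))
  }, numeric(1))
  .mc_result(subset_rho, null_rho, direction = "greater")
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Thin wrapper around [stats::wilcox.test()] exposing the U statistic and
#' the two-sided P value.
#'
#' @param a,b non-empty numeric samples.
#' @return list: `U`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with the family size `m` recorded.
#'
#' @param p vector of P values.
#' @param m family size (defaults to `length(p)`).
#' @return adjusted P values with attribute `family_size`.
#' @export
bonferroni <- function(p, m = length(p)) {
  structure(pmin(1, m * p), family_size = m)
}
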