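#' Per-gene sign matrix and Z sum across tissues
#'
#' Converts Z scores to a digital classification (+1 for Z > 0, -1 for
#' Z < 0, 0 kept as is) for each of the requested tissues, and sums them per
#' gene. Only genes with a score in every requested tissue are kept. By
#' default the six male tissues are used (more replicates, steadier data).
#'
#' @param z_table a `z_table` from [compute_z_table()].
#' @param tissues tissues to include.
#' @param sex stratum to analyze (default `"male"`).
#' @param drop_zero_flag treat zero-flag genes' scores as 0 (kept, per the
#'   "leave the Z = 0 class as is" rule) — they are not removed here.
#' @return list of class `z_sum_table`: `signs` (genes x tissues matrix of
#'   -1/0/+1), `z_sum` (named vector), `tissues`, `sex`.
#' @export
z_sum <- function(z_table, tissues = NULL, sex = "male",
                  drop_zero_flag = FALSE) {
  sub <- z_table[z_table$sex == sex, ]
  if (is.null(tissues)) tissues <- unique(sub$tissue)
  sub <- sub[sub$tissue %in% tissues & !sub$degenerate, ]
  sub$s <- ifelse(sub$zero_flag, 0, sign(sub$Z_mod))
  tab <- stats::xtabs(s ~ gene + tissue, data = sub)
  present <- stats::xtabs(~ gene + tissue, data = sub)
  keep <- rowSums(present[, tissues, drop = FALSE] > 0) == length(tissues)
  signs <- matrix(as.numeric(tab[keep, tissues, drop = FALSE]),
                  ncol = length(tissues),
                  dimnames = list(rownames(tab)[keep], tissues))
  structure(list(signs = signs, z_sum = rowSums(signs),
                 tissues = tissues, sex = sex),
            class = "z_sum_table")
}

#' Expected proportion and count of fully concerted genes
#'
#' Under a null of independent evolution across tissues, the expected
#' proportion of genes with the same sign in every tissue is the product of
#' the per-tissue proportions of that sign.
#'
#' @param proportions per-tissue proportion of the sign of interest.
#' @param n_genes total gene count.
#' @return list: `expected_proportion`, `expected_count`.
#' @export
#' @examples
#' concerted_expectation(rep(0.5, 6), 13027)$expected_proportion  # 0.5^6
concerted_expectation <- function(proportions, n_genes) {
  stopifnot(all(proportions >= 0 & proportions <= 1), n_genes >= 0)
  p <- prod(proportions)
  list(expected_proportion = p, expected_count = p * n_genes)
}

#' Z-sum distribution against an independence null
#'
#' Randomizes each tissue's sign column independently (preserving the
#' per-tissue counts of +, - and 0), accumulates the null Z-sum histogram,
#' and compares the observed histogram by chi-square over the
#' `2 * n_tissues + 1` categories. The empirical P compares the observed
#' chi-square with the chi-square of each randomization against the same
#' expected histogram (calibrated by construction); the asymptotic tail
#' probability at `df = 2 * n_tissues` is reported alongside. Cells with
#' expected count < 5 are pooled into their inner neighbor and logged.
#'
#' @param zsum a `z_sum_table` from [z_sum()] (or a plain sign matrix).
#' @param n_rand randomizations.
#' @param seed RNG seed.
#' @return list of class `zsum_test`: `observed`, `expected`, `chi2`, `df`,
#'   `p_asymptotic`, `empirical_p`, `concerted_fold` (observed/expected in
#'   the |sum| = n_tissues cells), `pooled` (logical, cells were pooled).
#' @export
zsum_distribution_test <- function(zsum, n_rand = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  signs <- if (inherits(zsum, "z_sum_table")) zsum$signs else as.matrix(zsum)
  k <- ncol(signs); g <- nrow(signs)
  cats <- seq(-k, k)
  hist_of <- function(s) tabulate(rowSums(s) + k + 1L, nbins = 2L * k + 1L)
  obs <- hist_of(signs)
  null_hists <- matrix(0, n_rand, 2L * k + 1L)
  for (i in seq_len(n_rand)) {
    s <- apply(signs, 2, sample)
    null_hists[i, ] <- hist_of(s)
  }
  expected <- colMeans(null_hists)
  # pool sparse outer cells inward so the chi-square is well behaved
  pool <- expected < 5
  grp <- seq_along(cats)
  if (any(pool)) {
    mid <- k + 1L
    for (j in seq_along(cats)) {
      jj <- j
      while (pool[jj] && jj != mid) jj <- jj + sign(mid - jj)
      grp[j] <- jj
    }
  }
  agg <- function(h) as.numeric(tapply(h, grp, sum))
  O <- agg(obs); E <- agg(expected)
  chi2 <- sum((O - E)^2 / E)
  null_chi2 <- apply(null_hists, 1, function(h) {
    Hn <- agg(h); sum((Hn - E)^2 / E)
  })
  extreme <- obs[1] + obs[2L * k + 1L]
  exp_extreme <- expected[1] + expected[2L * k + 1L]
  structure(list(observed = stats::setNames(obs, cats),
                 expected = stats::setNames(expected, cats),
                 chi2 = chi2, df = 2L * k,
                 p_asymptotic = stats::pchisq(chi2, df = 2L * k,
                                              lower.tail = FALSE),
                 empirical_p = empirical_p(sum(null_chi2 >= chi2), n_rand),
                 concerted_fold = if (exp_extreme > 0)
                   extreme / exp_extreme else NA_real_,
                 pooled = any(pool), n_genes = g),
            class = "zsum_test")
}

#' Cluster scan of concerted genes along the map
#'
#' Concerted genes (|Z sum| equal to the tissue count) are labelled +1/-1 by
#' their shared sign, all other genes 0. Maximal runs of adjacent same-sign
#' concerted genes (any intervening gene, including zero class, breaks a
#' run) are counted by size and compared against randomizations of the gene
#' order that preserve the number of concerted genes of each sign. Per size
#' and sign, the empirical P counts randomizations with as many or more
#' clusters of that size.
#'
#' @param concert named vector in `{-1, 0, 1}` ordered along the map
#'   (e.g. `ifelse(abs(zs$z_sum) == 6, sign(zs$z_sum), 0)` reordered).
#' @param chrom chromosome per gene (runs never span chromosomes).
#' @param n_rand randomizations (default 1000).
#' @param seed RNG seed.
#' @param per_chromosome permute within chromosomes instead of genome-wide.
#' @return data.frame: `sign`, `size`, `observed`, `null_mean`, `N`, `M`,
#'   `empirical_p` for sizes >= 2.
#' @export
concerted_cluster_scan <- function(concert, chrom = NULL, n_rand = 1000,
                                   seed = NULL, per_chromosome = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(concert %in% c(-1, 0, 1)))
  if (is.null(chrom)) chrom <- rep("chr", length(concert))
  counts <- function(v) {
    out <- matrix(0L, 2, 0)
    sizes <- list(pos = integer(0), neg = integer(0))
    for (ch in unique(chrom)) {
      r <- rle(v[chrom == ch])
      sizes$pos <- c(sizes$pos, r$lengths[r$values == 1])
      sizes$neg <- c(sizes$neg, r$lengths[r$values == -1])
    }
    sizes
  }
  obs <- counts(concert)
  max_size <- max(2L, unlist(obs))
  tab <- function(sz) tabulate(sz, nbins = max_size)
  obs_tab <- rbind(pos = tab(obs$pos), neg = tab(obs$neg))
  null_ge <- array(0L, dim = c(2, max_size))
  null_sum <- array(0, dim = c(2, max_size))
  idx_groups <- if (per_chromosome) split(seq_along(concert), chrom) else
    list(seq_along(concert))
  for (i in seq_len(n_rand)) {
    v <- concert
    for (idx in idx_groups) v[idx] <- v[idx[sample(length(idx))]]
    nt <- counts(v)
    nt_tab <- rbind(tab(nt$pos), tab(nt$neg))
    null_ge <- null_ge + (nt_tab >= obs_tab)
    null_sum <- null_sum + nt_tab
  }
  sizes <- 2:max_size
  out <- do.call(rbind, lapply(c(1, 2), function(r)
    data.frame(sign = if (r == 1) "positive" else "negative",
               size = sizes, observed = obs_tab[r, sizes],
               null_mean = null_sum[r, sizes] / n_rand,
               N = null_ge[r, sizes], M = n_rand,
               empirical_p = (null_ge[r, sizes] + 1) / (n_rand + 1))))
  rownames(out) <- NULL
  out
}

#' Tissue-specific upregulation flags
#'
#' Strict: Z > `threshold` in exactly one tissue and Z <= 0 in all others.
#' Relaxed: Z > `threshold` in exactly one tissue with Z < `threshold`
#' elsewhere. Strict implies relaxed.
#'
#' @param signs_or_z genes x tissues matrix of Z scores.
#' @param threshold the upregulation cutoff (default 1).
#' @return data.frame: `gene`, `tissue` (the single qualifying tissue, NA if
#'   none), `strict`, `relaxed`.
#' @export
tsu_classify <- function(signs_or_z, threshold = 1) {
  zmat <- as.matrix(signs_or_z)
  above <- zmat > threshold
  n_above <- rowSums(above)
  which_t <- apply(above, 1, function(r) if (sum(r) == 1) which(r) else NA)
  one <- n_above == 1
  relaxed <- one & vapply(seq_len(nrow(zmat)), function(i) {
    if (!one[i]) return(FALSE)
    all(zmat[i, -which_t[i]] < threshold)
  }, logical(1))
  strict <- one & vapply(seq_len(nrow(zmat)), function(i) {
    if (!one[i]) return(FALSE)
    all(zmat[i, -which_t[i]] <= 0)
  }, logical(1))
  data.frame(gene = rownames(zmat) %||% seq_len(nrow(zmat)),
             tissue = colnames(zmat)[which_t],
             strict = strict, relaxed = relaxed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Do TSU genes sit next to genes upregulated in the same tissue?
#'
#' For each tissue, the observed number of TSU genes whose nearest
#' downstream neighbor has Z > 0 in the focal tissue is compared with the
#' expectation from that tissue's genome-wide Z > 0 proportion. The tissue
#' contributions (both cells) are summed into a chi-square with
#' `df = n_tissues - 1`; per-tissue df = 1 P values and their Fisher
#' combination (`-2 sum(ln p)`, `df = 2k`) are reported. Computed separately
#' for TSU genes whose neighbor is within `radius` and beyond it.
#'
#' @param tsu a [tsu_classify()] table (the `relaxed` set is used by
#'   default; set `flag = "strict"` otherwise).
#' @param zmat genes x tissues matrix of Z scores (same genes as the map).
#' @param map a [gene_map()].
#' @param radius proximity split (default 100 kb).
#' @param flag `"relaxed"` or `"strict"`.
#' @return list with elements `near` and `far`, each a list (`per_tissue`
#'   data.frame, `chi2`, `df`, `p_value`, `fisher_chi2`, `fisher_df`,
#'   `fisher_p`).
#' @export
tsu_neighbor_test <- function(tsu, zmat, map, radius = 1e5,
                              flag = c("relaxed", "strict")) {
  flag <- match.arg(flag)
  map <- .check_map(map)
  zmat <- as.matrix(zmat)
  pr <- downstream_pairs(map, max_gap = Inf)
  near <- stats::setNames(pmax(pr$gap_bp, 0) <= radius, pr$focal)
  near[is.na(near)] <- TRUE   # overlapping neighbor counts as near
  nb <- stats::setNames(pr$neighbor, pr$focal)
  eval_side <- function(want_near) {
    rows <- lapply(colnames(zmat), function(ts) {
      cand <- tsu$gene[tsu[[flag]] & !is.na(tsu$tissue) & tsu$tissue == ts]
      cand <- cand[cand %in% names(nb)]
      cand <- cand[near[cand] == want_near]
      nn <- nb[cand]
      ok <- nn %in% rownames(zmat)
      cand <- cand[ok]; nn <- nn[ok]
      n <- length(cand)
      prop <- mean(zmat[, ts] > 0, na.rm = TRUE)
      obs <- sum(zmat[nn, ts] > 0, na.rm = TRUE)
      data.frame(tissue = ts, n = n, observed = obs, expected = n * prop,
                 stringsAsFactors = FALSE)
    })
    pt <- do.call(rbind, rows)
    pt <- pt[pt$n > 0, ]
    if (!nrow(pt))
      return(list(per_tissue = pt, chi2 = NA_real_, df = NA_integer_,
                  p_value = NA_real_, fisher_chi2 = NA_real_,
                  fisher_df = NA_integer_, fisher_p = NA_real_))
    e2 <- pt$n - pt$expected
    contrib <- (pt$observed - pt$expected)^2 / pt$expected +
      ((pt$n - pt$observed) - e2)^2 / pmax(e2, .Machine$double.eps)
    pt$chi2 <- contrib
    pt$p_value <- stats::pchisq(contrib, df = 1, lower.tail = FALSE)
    chi2 <- sum(contrib); df <- nrow(pt) - 1L
    fch <- -2 * sum(log(pmax(pt$p_value, .Machine$double.xmin)))
    fdf <- 2L * nrow(pt)
    list(per_tissue = pt, chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df = max(df, 1L), lower.tail = FALSE),
         fisher_chi2 = fch, fisher_df = fdf,
         fisher_p = stats::pchisq(fch, df = fdf, lower.tail = FALSE))
  }
  list(near = eval_side(TRUE), far = eval_side(FALSE))
}

#' Two-cell chi-square for peak overlap by Z sign
#'
#' Given the number of Z-positive and Z-negative genes and the observed
#' counts overlapping at least one peak, expectations are margin-derived
#' (`E_plus = N_plus * (O_plus + O_minus) / (N_plus + N_minus)`) and the
#' chi-square sums `(O - E)^2 / E` over the two overlap cells only (df = 1).
#' Counts may be non-integer (e.g. averaged over replicate peak sets).
#'
#' @param N_plus,N_minus gene counts by sign.
#' @param O_plus,O_minus counts overlapping at least one peak.
#' @return list of class `two_cell_counts`: `E_plus`, `E_minus`, `chi2`,
#'   `df`, `p_value` plus the inputs.
#' @export
#' @examples
#' two_cell_chisq(5923, 6495, 5108, 4981.5)$p_value  # ~3.8e-9
two_cell_chisq <- function(N_plus, N_minus, O_plus, O_minus) {
  stopifnot(N_plus >= 0, N_minus >= 0, O_plus >= 0, O_minus >= 0,
            O_plus <= N_plus, O_minus <= N_minus)
  tot <- O_plus + O_minus
  E_plus <- N_plus * tot / (N_plus + N_minus)
  E_minus <- N_minus * tot / (N_plus + N_minus)
  if (E_plus == 0 || E_minus == 0) stop("zero expectation")
  chi2 <- (O_plus - E_plus)^2 / E_plus + (O_minus - E_minus)^2 / E_minus
  structure(list(N_plus = N_plus, N_minus = N_minus, O_plus = O_plus,
                 O_minus = O_minus, E_plus = E_plus, E_minus = E_minus,
                 chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "two_cell_counts")
}

#' Peak enrichment of sign clusters
#'
#' Flags every cluster that overlaps at least one interval (e.g. gained or
#' depleted H3K4me3 peaks) and tests sign x flag association with a 2x2
#' chi-square (no continuity correction).
#'
#' @param clusters cluster table with `chrom`, `sign`, `span_start`,
#'   `span_end` (as from [run_edges()] with a map).
#' @param peaks BED-convention intervals (`chrom`, `start`, `end`).
#' @return list: `table` (2x2), `chi2`, `df`, `p_value`, `flags`, `defined`.
#' @export
cluster_peak_enrichment <- function(clusters, peaks) {
  if (!nrow(clusters))
    return(list(table = NULL, chi2 = NA_real_, df = NA, p_value = NA_real_,
                flags = logical(0), defined = FALSE))
  stopifnot(all(c("span_start", "span_end") %in% names(clusters)))
  fake_map <- gene_map(data.frame(gene = paste0("cl", seq_len(nrow(clusters))),
                                  chrom = clusters$chrom,
                                  start = clusters$span_start,
                                  end = clusters$span_end, strand = "+"))
  flags <- gene_interval_overlap(fake_map, peaks)
  # gene_interval_overlap sorts; map flags back to input order
  flags <- flags[paste0("cl", seq_len(nrow(clusters)))]
  tab <- table(sign = factor(clusters$sign, levels = c(-1, 1)),
               overlap = factor(flags, levels = c(FALSE, TRUE)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, flags = unname(flags), defined = TRUE)
}

#' Correlation of Z with a per-gene scalar track
#'
#' Spearman correlation between one tissue's Z scores and a per-gene scalar
#' annotation (e.g. hmC or mC percentage), over the genes present in both.
#'
#' @param z named per-gene Z scores for one tissue.
#' @param track named per-gene scalar values.
#' @return a `correlation_result`.
#' @export
scalar_track_correlation <- function(z, track) {
  shared <- intersect(names(z), names(track))
  spearman_cor(z[shared], track[shared])
}
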