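#' Summarize current (human) expression across replicates
#'
#' @param replicates numeric vector of per-replicate expression values
#'   (RPKM-like, non-negative).
#' @return list with `E_c` (arithmetic mean), `V_c` (unbiased sample
#'   variance; 0 with `single_replicate = TRUE` when only one value is
#'   available, as for the single female samples).
#' @export
#' @examples
#' summarize_current(c(4, 6))  # E_c 5, V_c 2
summarize_current <- function(replicates) {
  if (!length(replicates)) stop("no replicates supplied")
  stopifnot(all(is.finite(replicates)))
  single <- length(replicates) == 1L
  list(E_c = mean(replicates),
       V_c = if (single) 0 else stats::var(replicates),
       single_replicate = single)
}

#' Expression-divergence Z score
#'
#' `Z = (E_c - E_a) / sqrt(V_c + V_a)`: the difference between current and
#' ancestral expression in standard-deviation units, where the denominator
#' pools replicate (measurement) variance and ancestral-reconstruction
#' variance. Vectorized. When the denominator is zero the score is 0 if
#' `E_c == E_a` and a signed infinity sentinel otherwise (flagged and meant
#' to be excluded from rank statistics).
#'
#' @param E_c,V_c current mean and variance.
#' @param E_a,V_a ancestral mean and variance.
#' @return numeric vector of Z scores (possibly `Inf`/`-Inf` sentinels).
#' @export
#' @examples
#' z_score(5, 1, 3, 3)  # (5-3)/sqrt(4) = 1
z_score <- function(E_c, V_c, E_a, V_a) {
  if (any(V_c < 0) || any(V_a < 0)) stop("negative variance")
  den <- sqrt(V_c + V_a)
  num <- E_c - E_a
  ifelse(den > 0, num / den, sign(num) * ifelse(num == 0, 0, Inf))
}

#' Median-correct Z scores within a tissue/sex stratum
#'
#' `Z_mod = Z_raw - median(Z_raw)`. Forcing the median change to zero
#' encodes the assumption of no net transcriptome growth or shrinkage; as a
#' monotone shift it leaves all rank statistics untouched. Non-finite
#' sentinels are ignored when computing the median and stay non-finite.
#'
#' @param z numeric vector of raw Z scores.
#' @return list with `Z_mod`, `M` (the median offset), `sign`
#'   (+1 / -1 / 0 from `Z_mod`).
#' @export
median_correct <- function(z) {
  if (!length(z)) stop("no Z scores supplied")
  M <- stats::median(z[is.finite(z)])
  zm <- z - M
  list(Z_mod = zm, M = M, sign = sign(zm))
}

#' Fold change and sign of expression change
#'
#' @param E_c,E_a current and ancestral means.
#' @param Z_mod median-corrected Z (source of the sign).
#' @return data.frame with `fold_change` (`E_c/E_a`, `NA` and
#'   `fold_defined = FALSE` when `E_a <= 0`) and `sign`.
#' @export
change_metrics <- function(E_c, E_a, Z_mod) {
  defined <- E_a > 0
  data.frame(fold_change = ifelse(defined, E_c / E_a, NA_real_),
             fold_defined = defined,
             sign = sign(Z_mod))
}

#' Expression-profile summary for one gene
#'
#' Tissues with mean expression below `floor` (default 2 RPKM) are set to
#' zero before anything is computed. Breadth is the proportion of tissues
#' expressed; `mean_rate` averages over expressed tissues only; `peak_rate`
#' is the maximum; tau is the specificity index
#' `sum_j (1 - log(e_j)/log(e_max)) / (n - 1)`, 0 for uniform expression and
#' 1 for single-tissue expression. Zero-expression tissues contribute their
#' limit term 1 (they are maximally "off"). With no expressed tissue, tau is
#' `NA` and flagged.
#'
#' @param e numeric vector of per-tissue expression (>= 2 tissues).
#' @param floor expression floor in the same units (default 2).
#' @return list: `breadth`, `mean_rate`, `peak_rate`, `tau`, `n_tissues`,
#'   `defined`.
#' @export
#' @examples
#' expression_profile(c(100, 10))$tau  # 1 - log(10)/log(100) = 0.5
expression_profile <- function(e, floor = 2) {
  if (length(e) < 2) stop("need at least 2 tissues")
  stopifnot(all(is.finite(e)), all(e >= 0))
  e <- ifelse(e < floor, 0, e)
  n <- length(e)
  expressed <- e > 0
  if (!any(expressed))
    return(list(breadth = 0, mean_rate = NA_real_, peak_rate = 0,
                tau = NA_real_, n_tissues = n, defined = FALSE))
  emax <- max(e)
  terms <- ifelse(expressed, 1 - log(e) / log(emax), 1)
  if (emax == 1) terms[expressed] <- ifelse(e[expressed] == emax, 0, 1)
  list(breadth = mean(expressed),
       mean_rate = mean(e[expressed]),
       peak_rate = emax,
       tau = sum(terms) / (n - 1),
       n_tissues = n,
       defined = TRUE)
}

#' Per-gene Z table for a multi-species expression dataset
#'
#' The end-to-end divergence computation: for every tissue/sex stratum
#' present in the dataset, species mean expression is computed per gene, a
#' Brownian-motion model is fitted on the tree, the human-chimp ancestral
#' state is reconstructed ([ancestral_table()]), the current human mean and
#' replicate variance are summarized, and the Z score, per-stratum median
#' correction, sign and fold change are derived. Genes with `E_c = 0` and
#' `E_a <= 0` are flagged `zero_flag` (no expression, indecisive) and are
#' excluded from the median by default; downstream rank statistics drop them
#' unless told otherwise.
#'
#' @param dataset an expression dataset as produced by
#'   [simulate_expression()] or [read_expression()]: list with `expr`
#'   (genes x samples matrix) and `samples` (sample sheet).
#' @param tree rooted `phylo` whose tips match the dataset's species.
#' @param rate,method,mean_uncertainty passed to [ancestral_table()]
#'   (defaults mirror a per-gene ML analysis of raw expression values).
#' @param retain_zeros include zero-flagged genes in the median computation.
#' @return data.frame of class `z_table`: `gene`, `tissue`, `sex`, `E_c`,
#'   `V_c`, `E_a`, `V_a`, `Z_raw`, `Z_mod`, `sign`, `fold_change`,
#'   `zero_flag`, `degenerate`, `single_replicate`.
#' @export
compute_z_table <- function(dataset, tree, rate = "per_gene", method = "ML",
                            mean_uncertainty = TRUE, retain_zeros = FALSE) {
  expr <- dataset$expr
  samples <- dataset$samples
  stopifnot(is.matrix(expr), all(colnames(expr) == samples$sample))
  node <- hc_ancestor(tree)
  strata <- unique(samples[, c("tissue", "sex")])
  out <- vector("list", nrow(strata))
  for (k in seq_len(nrow(strata))) {
    ts <- strata$tissue[k]; sx <- strata$sex[k]
    sel <- samples$tissue == ts & samples$sex == sx
    sub <- samples[sel, ]
    # species means across replicates
    tipmat <- sapply(split(seq_len(nrow(sub)), sub$species), function(ii)
      rowMeans(expr[, sub$sample[ii], drop = FALSE]))
    if (!all(colnames(tipmat) %in% tree$tip.label))
      stop("species in sample sheet not found in tree: ",
           paste(setdiff(colnames(tipmat), tree$tip.label), collapse = ", "))
    anc <- ancestral_table(tipmat, tree, node, rate = rate, method = method,
                           mean_uncertainty = mean_uncertainty)
    hum <- expr[, sub$sample[sub$species == "human"], drop = FALSE]
    nrep <- ncol(hum)
    E_c <- rowMeans(hum)
    V_c <- if (nrep >= 2) apply(hum, 1, stats::var) else rep(0, nrow(hum))
    Z <- z_score(E_c, V_c, anc$E_a, anc$V_a)
    zero_flag <- E_c == 0 & anc$E_a <= 0
    degenerate <- !is.finite(Z)
    use <- if (retain_zeros) !degenerate else !degenerate & !zero_flag
    M <- stats::median(Z[use])
    Zm <- Z - M
    out[[k]] <- data.frame(
      gene = rownames(expr), tissue = ts, sex = sx,
      E_c = E_c, V_c = V_c, E_a = anc$E_a, V_a = anc$V_a,
      Z_raw = Z, Z_mod = Zm, sign = sign(Zm),
      fold_change = ifelse(anc$E_a > 0, E_c / anc$E_a, NA_real_),
      zero_flag = zero_flag, degenerate = degenerate,
      single_replicate = nrep == 1L,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("z_table", "data.frame")
  res
}

# One stratum of a z_table as a named Z vector, default-excluding zero-flag
# and degenerate genes. Used by the spatial statistics.
.z_vector <- function(z_table, tissue, sex, use = "Z_mod",
                      drop_zero = TRUE) {
  sub <- z_table[z_table$tissue == tissue & z_table$sex == sex, ]
  if (!nrow(sub)) stop("no rows for tissue ", tissue, ", sex ", sex)
  keep <- !sub$degenerate
  if (drop_zero) keep <- keep & !sub$zero_flag
  stats::setNames(sub[[use]][keep], sub$gene[keep])
}
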