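#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the data regime of the primate study the pipeline is
#' built for: 13,027 genes over 22 autosomes plus chrX, six tissues, five
#' species on the primate time tree, three male replicates and a single
#' female replicate, with female liver and testis absent. Expression evolves
#' by Brownian motion on a log scale (rate per My), human-branch shifts are
#' applied to contiguous blocks of genes, and a configurable fraction of
#' shifted blocks is "concerted" (same shift sign in every tissue).
#'
#' @param n_genes,n_chromosomes map size.
#' @param gene_length_mean,intergap_mean exponential means (bp) for gene
#'   lengths and intergenic gaps.
#' @param overlap_fraction fraction of adjacent gene pairs forced to overlap
#'   in transcript span.
#' @param strand_prob probability of the + strand.
#' @param tissues tissue names.
#' @param sexes named list: tissues available per sex (mimicking the missing
#'   female liver/testis).
#' @param n_replicates named integer vector per sex (1 allowed, mimicking
#'   single female samples).
#' @param tree_spec newick text for the five-species tree.
#' @param bm_rate Brownian trait variance per unit branch length (log
#'   expression units^2 / My).
#' @param root_mean,root_sd distribution of the per-gene/tissue root state
#'   (log expression).
#' @param shift_block_len genes per co-shifted block.
#' @param shift_prob probability a block receives a human-branch shift.
#' @param shift_sd magnitude scale of shifts (log units).
#' @param noise_sd replicate measurement noise (log units).
#' @param concerted_fraction fraction of shifted blocks whose shift sign is
#'   shared across all tissues.
#' @param silent_prob probability a gene is unexpressed (exact zero in all
#'   species) in a given tissue, exercising the zero-Z path.
#' @param sex_shift_prob,sex_shift_sd optional block-level female-specific
#'   human-branch shifts (default off) for sex-bias power studies.
#' @param seed integer seed; all generator outputs are byte-identical given
#'   the same config.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 13027, n_chromosomes = 23,
                       gene_length_mean = 25000, intergap_mean = 60000,
                       overlap_fraction = 0.05, strand_prob = 0.5,
                       tissues = c("brain", "cerebellum", "heart",
                                   "kidney", "liver", "testis"),
                       sexes = list(male = tissues,
                                    female = setdiff(tissues,
                                                     c("liver", "testis"))),
                       n_replicates = c(male = 3L, female = 1L),
                       tree_spec = NULL,
                       bm_rate = 0.05, root_mean = 1.5, root_sd = 1,
                       shift_block_len = 10, shift_prob = 0.2,
                       shift_sd = 1.0, noise_sd = 0.25,
                       concerted_fraction = 0.3, silent_prob = 0.05,
                       sex_shift_prob = 0, sex_shift_sd = 0,
                       seed = 1L) {
  if (is.null(tree_spec))
    tree_spec <- ape::write.tree(primate_tree())
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              gene_length_mean = gene_length_mean,
              intergap_mean = intergap_mean,
              overlap_fraction = overlap_fraction,
              strand_prob = strand_prob, tissues = tissues, sexes = sexes,
              n_replicates = n_replicates, tree_spec = tree_spec,
              bm_rate = bm_rate, root_mean = root_mean, root_sd = root_sd,
              shift_block_len = as.integer(shift_block_len),
              shift_prob = shift_prob, shift_sd = shift_sd,
              noise_sd = noise_sd, concerted_fraction = concerted_fraction,
              silent_prob = silent_prob, sex_shift_prob = sex_shift_prob,
              sex_shift_sd = sex_shift_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1, n_chromosomes >= 1, shift_block_len >= 1,
              all(n_replicates >= 1), length(tissues) >= 1)
    probs <- c(overlap_fraction, strand_prob, shift_prob,
               concerted_fraction, silent_prob, sex_shift_prob)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (any(c(bm_rate, shift_sd, noise_sd, root_sd, sex_shift_sd) < 0))
      stop("rates and standard deviations must be >= 0")
    if (gene_length_mean <= 0 || intergap_mean <= 0)
      stop("impossible geometry: gene_length_mean and intergap_mean must be positive")
    if (!all(names(sexes) %in% names(n_replicates)))
      stop("n_replicates must name every sex in `sexes`")
    if (!all(unlist(sexes) %in% tissues))
      stop("sexes lists a tissue not in `tissues`")
  })
  class(cfg) <- "sim_config"
  cfg
}

.sim_species <- c("human", "chimp", "gorilla", "orangutan", "macaque")

#' Generate a synthetic chromosome-ordered gene map
#'
#' Genes are laid left to right per chromosome with exponential lengths and
#' intergenic gaps; a configurable fraction of adjacent pairs is forced to
#' overlap in span. The last chromosome is named `"chrX"` (autosomes
#' `chr1..`), coordinates are 1-based inclusive and starts increase within a
#' chromosome. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return a [gene_map()] with an extra `block_id` attribute-free column
#'   left out (block structure lives in the truth object).
#' @export
generate_gene_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- if (config$n_chromosomes == 1) "chr1" else
    c(paste0("chr", seq_len(config$n_chromosomes - 1L)), "chrX")
  per <- rep(config$n_genes %/% config$n_chromosomes, config$n_chromosomes)
  extra <- config$n_genes %% config$n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  rows <- vector("list", length(chroms))
  gid <- 0L
  for (ci in seq_along(chroms)) {
    n <- per[ci]
    if (n == 0) next
    len <- pmax(200L, as.integer(round(stats::rexp(n, 1 / config$gene_length_mean))))
    gap <- pmax(1L, as.integer(round(stats::rexp(n, 1 / config$intergap_mean))))
    ov <- c(FALSE, stats::runif(n - 1) < config$overlap_fraction)
    start <- integer(n); end <- integer(n)
    start[1] <- gap[1]; end[1] <- start[1] + len[1] - 1L
    if (n > 1) for (k in 2:n) {
      if (ov[k] && len[k - 1] > 2L) {
        # start inside the previous gene body, strictly after its start
        off <- 1L + as.integer(floor(stats::runif(1) * (len[k - 1] - 2L)))
        start[k] <- start[k - 1] + off
      } else {
        start[k] <- max(end[seq_len(k - 1)]) + 1L + gap[k]
      }
      end[k] <- start[k] + len[k] - 1L
    }
    strand <- ifelse(stats::runif(n) < config$strand_prob, "+", "-")
    rows[[ci]] <- data.frame(gene = sprintf("g%05d", gid + seq_len(n)),
                             chrom = chroms[ci], start = start, end = end,
                             strand = strand, stringsAsFactors = FALSE)
    gid <- gid + n
  }
  gene_map(do.call(rbind, rows))
}

# Contiguous blocks of shift_block_len genes per chromosome (never spanning
# chromosomes); returns an integer block id per map row.
.assign_blocks <- function(map, block_len) {
  bid <- integer(nrow(map)); nxt <- 0L
  for (idx in split(seq_len(nrow(map)), map$chrom)) {
    b <- (seq_along(idx) - 1L) %/% block_len + 1L
    bid[idx] <- nxt + b
    nxt <- nxt + max(b)
  }
  bid
}

#' Simulate replicated multi-species expression with known truth
#'
#' Per gene and tissue, a latent log-expression trait evolves by Brownian
#' motion down the five-species tree from a Gaussian root state; a
#' block-shared human-branch shift is added on the human tip for shifted
#' blocks (sign shared across tissues in concerted blocks), and optional
#' female-specific block shifts model sex-biased change. Observed values are
#' `exp(latent + replicate noise)`, shared between sexes at the species
#' level; a `silent_prob` fraction of gene/tissue combinations is exactly
#' zero in all species. Missing sex/tissue combinations are absent columns,
#' not zeros.
#'
#' @param map a [generate_gene_map()] result (or any [gene_map()]).
#' @param config the same [sim_config()].
#' @return list with `dataset` (list `expr`, `samples`) and `truth` (class
#'   `sim_truth`: `ancestor`, `shift`, `sex_shift` gene x tissue matrices on
#'   the latent log scale, `block_id`, `blocks` table, `silent` matrix,
#'   `tree`).
#' @export
simulate_expression <- function(map, config) {
  stopifnot(inherits(config, "sim_config"))
  map <- .check_map(map)
  tree <- ape::read.tree(text = config$tree_spec)
  if (!setequal(tree$tip.label, .sim_species))
    stop("tree tips must be exactly: ", paste(.sim_species, collapse = ", "))
  set.seed(config$seed + 1L)
  G <- nrow(map); tis <- config$tissues; Tn <- length(tis)
  bid <- .assign_blocks(map, config$shift_block_len)
  B <- max(bid)

  # block-level shifts: per block, per tissue
  shifted <- stats::runif(B) < config$shift_prob
  concerted <- shifted & stats::runif(B) < config$concerted_fraction
  block_shift <- matrix(0, B, Tn, dimnames = list(NULL, tis))
  nb <- sum(shifted & !concerted)
  if (nb > 0)
    block_shift[shifted & !concerted, ] <-
      stats::rnorm(nb * Tn, 0, config$shift_sd)
  ncb <- sum(concerted)
  if (ncb > 0) {
    sgn <- sample(c(-1, 1), ncb, replace = TRUE)
    block_shift[concerted, ] <-
      sgn * abs(matrix(stats::rnorm(ncb * Tn, 0, config$shift_sd), ncb, Tn))
  }
  block_sex_shift <- matrix(0, B, Tn, dimnames = list(NULL, tis))
  sex_shifted <- stats::runif(B) < config$sex_shift_prob
  nsb <- sum(sex_shifted)
  if (nsb > 0)
    block_sex_shift[sex_shifted, ] <-
      stats::rnorm(nsb * Tn, 0, config$sex_shift_sd)

  shift <- block_shift[bid, , drop = FALSE]
  sex_shift <- block_sex_shift[bid, , drop = FALSE]
  rownames(shift) <- rownames(sex_shift) <- map$gene

  # Brownian motion on the tree, vectorized over gene x tissue
  info <- .tree_depths(tree)
  ntot <- ape::Ntip(tree) + tree$Nnode
  edge_order <- order(info$depth[tree$edge[, 2]])  # parents before children
  GT <- G * Tn
  node_val <- matrix(NA_real_, GT, ntot)
  node_val[, info$root] <- stats::rnorm(GT, config$root_mean, config$root_sd)
  blen <- tree$edge.length
  for (e in edge_order) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    node_val[, v] <- node_val[, p] +
      stats::rnorm(GT, 0, sqrt(config$bm_rate * blen[e]))
  }
  hc <- hc_ancestor(tree)
  ancestor <- matrix(node_val[, hc], G, Tn, dimnames = list(map$gene, tis))
  tip_idx <- stats::setNames(match(.sim_species, tree$tip.label), .sim_species)
  silent <- matrix(stats::runif(GT) < config$silent_prob, G, Tn,
                   dimnames = list(map$gene, tis))

  # observed replicate matrices
  sheets <- list(); cols <- list()
  for (sx in names(config$sexes)) {
    nrep <- config$n_replicates[[sx]]
    for (ts in config$sexes[[sx]]) {
      tcol <- match(ts, tis)
      gt_rows <- (tcol - 1L) * G + seq_len(G)
      for (sp in .sim_species) {
        latent <- node_val[gt_rows, tip_idx[sp]]
        if (sp == "human") {
          latent <- latent + shift[, tcol]
          if (sx == "female") latent <- latent + sex_shift[, tcol]
        }
        for (r in seq_len(nrep)) {
          val <- exp(latent + stats::rnorm(G, 0, config$noise_sd))
          val[silent[, tcol]] <- 0
          id <- paste(sp, ts, sx, r, sep = ".")
          cols[[id]] <- pmax(val, 0)
          sheets[[id]] <- data.frame(sample = id, species = sp, tissue = ts,
                                     sex = sx, replicate = r,
                                     stringsAsFactors = FALSE)
        }
      }
    }
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- map$gene
  samples <- do.call(rbind, sheets)
  rownames(samples) <- NULL
  blocks <- data.frame(block_id = seq_len(B),
                       chrom = tapply(map$chrom, bid, `[`, 1),
                       shifted = shifted, concerted = concerted,
                       sex_shifted = sex_shifted,
                       stringsAsFactors = FALSE)
  truth <- structure(list(ancestor = ancestor, shift = shift,
                          sex_shift = sex_shift,
                          block_id = stats::setNames(bid, map$gene),
                          blocks = blocks, silent = silent, tree = tree,
                          seed = config$seed),
                     class = "sim_truth")
  list(dataset = list(expr = expr, samples = samples), truth = truth)
}

#' Generate annotation tracks coupled to the simulated truth
#'
#' Emits BED-convention interval sets and per-gene scalar tracks whose
#' association with the true human-branch shifts is controlled by a single
#' signed `coupling` strength in `[-1, 1]`: LAD-like intervals
#' preferentially cover negatively shifted blocks, peak-like (and "gained")
#' intervals preferentially cover positively shifted genes, "depleted"
#' intervals negatively shifted genes, and the hmC-like (mC-like) scalar
#' track is positively (negatively) correlated with the mean true shift. At
#' `coupling = 0` every annotation is independent of the truth.
#'
#' @param map the [gene_map()] the truth was simulated on.
#' @param truth a `sim_truth`.
#' @param coupling signed strength in `[-1, 1]`.
#' @param seed RNG seed (default: truth seed + 2).
#' @return list: `lad`, `peaks`, `gained`, `depleted` (data.frames `chrom`,
#'   `start`, `end`, BED 0-based half-open) and `tracks` (data.frame `gene`,
#'   `hmc`, `mc` percentages).
#' @export
generate_annotations <- function(map, truth, coupling = 0.8,
                                 seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "sim_truth"), coupling >= -1, coupling <= 1)
  map <- .check_map(map)
  set.seed(seed)
  cpos <- max(0, coupling)
  bid <- truth$block_id[map$gene]
  gene_shift <- rowMeans(truth$shift)[map$gene]
  block_mean_shift <- tapply(gene_shift, bid, mean)
  block_rows <- split(seq_len(nrow(map)), bid)
  base_p <- 0.25
  span_of <- function(rows) c(min(map$start[rows]) - 1L, max(map$end[rows]))

  # LAD-like intervals over negatively shifted blocks
  p_block <- ifelse(block_mean_shift < 0, base_p + 0.6 * cpos,
                    base_p * (1 - cpos))
  lad_sel <- stats::runif(length(block_rows)) < p_block
  lad <- do.call(rbind, lapply(which(lad_sel), function(b) {
    sp <- span_of(block_rows[[b]])
    data.frame(chrom = map$chrom[block_rows[[b]][1]],
               start = sp[1], end = sp[2], stringsAsFactors = FALSE)
  }))
  if (is.null(lad)) lad <- .empty_bed()

  gene_peaks <- function(direction) {
    want <- if (direction > 0) gene_shift > 0 else gene_shift < 0
    p <- ifelse(want, base_p + 0.6 * cpos, base_p * (1 - cpos))
    sel <- which(stats::runif(nrow(map)) < p)
    if (!length(sel)) return(.empty_bed())
    mid <- (map$start[sel] + map$end[sel]) %/% 2L
    half <- pmax(100L, (map$end[sel] - map$start[sel]) %/% 4L)
    data.frame(chrom = map$chrom[sel], start = pmax(0L, mid - half - 1L),
               end = mid + half, stringsAsFactors = FALSE)
  }
  peaks <- gene_peaks(+1)
  gained <- gene_peaks(+1)
  depleted <- gene_peaks(-1)

  szn <- if (stats::sd(gene_shift) > 0)
    (gene_shift - mean(gene_shift)) / stats::sd(gene_shift) else
    gene_shift * 0
  tracks <- data.frame(
    gene = map$gene,
    hmc = 100 * stats::plogis(coupling * szn + stats::rnorm(nrow(map))),
    mc = 100 * stats::plogis(-coupling * szn + stats::rnorm(nrow(map))),
    stringsAsFactors = FALSE)
  list(lad = lad, peaks = peaks, gained = gained, depleted = depleted,
       tracks = tracks)
}

.empty_bed <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}
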