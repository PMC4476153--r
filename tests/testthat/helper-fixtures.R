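# Shared fixtures: all built in code at test time.

five_species_tree <- function() primate_tree()

# A small hand-laid map on two chromosomes (no overlaps).
toy_map <- function() {
  gene_map(data.frame(
    gene = c("a", "b", "c", "d", "e", "f"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(1000, 2500, 40000, 200000, 100, 5000),
    end = c(2000, 3000, 45000, 210000, 900, 9000),
    strand = c("+", "-", "+", "+", "-", "-")))
}

# Random map for oracle comparisons; overlaps arise naturally.
random_map <- function(n = 60, n_chrom = 3, seed = 1) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE))
  start <- unlist(lapply(split(seq_len(n), chrom), function(i)
    sort(sample.int(5e5, length(i)))))
  len <- sample(100:20000, n, replace = TRUE)
  gene_map(data.frame(gene = sprintf("g%03d", seq_len(n)), chrom = chrom,
                      start = start, end = start + len,
                      strand = sample(c("+", "-"), n, replace = TRUE)))
}

# Brute-force nearest downstream neighbor: exhaustive all-pairs scan.
oracle_downstream <- function(map, focal, max_gap, convention) {
  i <- which(map$gene == focal)
  cand <- which(map$chrom == map$chrom[i] & map$start > map$start[i])
  if (!length(cand)) return(NA_character_)
  cand <- cand[order(map$start[cand], map$end[cand], map$gene[cand])]
  j <- cand[1]
  gap <- max(map$start[j], map$start[i]) - min(map$end[j], map$end[i]) - 1
  d <- if (convention == "body_gap") max(gap, 0) else
    abs(map$start[j] - map$start[i])
  if (d > max_gap) NA_character_ else map$gene[j]
}

# Small multi-strata z_table built directly (bypasses the estimator).
toy_z_table <- function(zmat, sex = "male") {
  tissues <- colnames(zmat)
  rows <- do.call(rbind, lapply(tissues, function(ts)
    data.frame(gene = rownames(zmat), tissue = ts, sex = sex,
               E_c = 1, V_c = 0, E_a = 1, V_a = 1,
               Z_raw = zmat[, ts], Z_mod = zmat[, ts],
               sign = sign(zmat[, ts]), fold_change = 1,
               zero_flag = FALSE, degenerate = FALSE,
               single_replicate = FALSE, stringsAsFactors = FALSE)))
  class(rows) <- c("z_table", "data.frame")
  rows
}
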