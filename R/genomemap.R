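#' Build a chromosome-ordered gene map
#'
#' A gene map is a data.frame with columns `gene`, `chrom`, `start`, `end`
#' (1-based, inclusive) and `strand` (`"+"`/`"-"`), sorted by chromosome,
#' start, end and id. It is the spatial backbone for every neighborhood
#' statistic.
#'
#' @param df data.frame with those five columns.
#' @return the validated, sorted map (class `gene_map`).
#' @export
gene_map <- function(df) {
  need <- c("gene", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("gene map needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in map")
  if (any(df$start < 1)) stop("gene starts must be >= 1 (1-based coordinates)")
  if (any(df$end < df$start)) stop("gene end < start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$chrom, df$start, df$end, df$gene), ]
  rownames(df) <- NULL
  class(df) <- c("gene_map", "data.frame")
  df
}

.check_map <- function(map) {
  if (!inherits(map, "gene_map")) map <- gene_map(map)
  map
}

.map_row <- function(map, gene) {
  i <- match(gene, map$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  i
}

# Index of the nearest downstream gene (strictly larger start, same
# chromosome; ties on start broken by end then id through the map's sort
# order) for every gene; NA where none exists. "Downstream" is by published
# chromosome coordinate, not gene orientation.
.downstream_index <- function(map) {
  n <- nrow(map)
  nxt <- rep(NA_integer_, n)
  for (idx in split(seq_len(n), map$chrom)) {
    if (length(idx) < 2) next
    st <- map$start[idx]           # nondecreasing within the sorted map
    pos <- findInterval(st, st) + 1L   # first index with a strictly larger start
    ok <- pos <= length(idx)
    nxt[idx[ok]] <- idx[pos[ok]]
  }
  nxt
}

# Bases strictly between two gene bodies; negative means the spans overlap.
.body_gap <- function(map, i, j) {
  pmax(map$start[i], map$start[j]) - pmin(map$end[i], map$end[j]) - 1L
}

#' Nearest downstream neighbor of a focal gene
#'
#' The neighbor is the gene with the smallest start strictly greater than the
#' focal gene's start on the same chromosome (published-strand coordinates,
#' regardless of gene orientation). Returns `NULL` when no such gene exists
#' or the distance under the chosen convention exceeds `max_gap`.
#'
#' @param map a [gene_map()].
#' @param focal gene id.
#' @param max_gap maximum allowed distance in bp (default 100 kb, the
#'   estimated span of the chromatin "ripple" effect).
#' @param convention `"body_gap"` (bases strictly between gene bodies) or
#'   `"start_to_start"`.
#' @return `NULL` or a list (`focal`, `neighbor`, `gap_bp`,
#'   `start_to_start_bp`, `orientation`, `overlapping`).
#' @export
nearest_downstream <- function(map, focal, max_gap = 1e5,
                               convention = c("body_gap", "start_to_start")) {
  convention <- match.arg(convention)
  map <- .check_map(map)
  i <- .map_row(map, focal)
  nxt <- .downstream_index(map)
  j <- nxt[i]
  if (is.na(j)) return(NULL)
  .make_pair(map, i, j, max_gap, convention)
}

.make_pair <- function(map, i, j, max_gap, convention) {
  gap <- .body_gap(map, i, j)
  overlapping <- gap < 0
  sts <- abs(map$start[j] - map$start[i])
  d <- if (convention == "body_gap") max(gap, 0) else sts
  if (d > max_gap) return(NULL)
  left <- if (map$start[i] <= map$start[j]) i else j
  right <- if (left == i) j else i
  list(focal = map$gene[i], neighbor = map$gene[j],
       gap_bp = if (overlapping) NA_integer_ else gap,
       start_to_start_bp = sts,
       orientation = .orientation(map$strand[left], map$strand[right]),
       overlapping = overlapping)
}

.orientation <- function(left_strand, right_strand) {
  ifelse(left_strand == right_strand, "cooriented",
         ifelse(left_strand == "-", "divergent", "convergent"))
}

#' Classify the orientation of an adjacent gene pair
#'
#' With the focal gene being the left (lower-start) gene: `(-,+)` promoters
#' face away from each other -> `"divergent"`; `(+,-)` -> `"convergent"`;
#' equal strands -> `"cooriented"`.
#'
#' @param focal_strand,neighbor_strand strands of the left and right gene.
#' @return one of `"divergent"`, `"convergent"`, `"cooriented"`.
#' @export
classify_orientation <- function(focal_strand, neighbor_strand) {
  if (any(is.na(focal_strand)) || any(is.na(neighbor_strand)))
    stop("missing strand")
  stopifnot(all(c(focal_strand, neighbor_strand) %in% c("+", "-")))
  .orientation(focal_strand, neighbor_strand)
}

#' Nearest up- and downstream flanking pair
#'
#' Both flanks must lie within `max_gap` under the chosen convention,
#' otherwise `NULL` (chromosome-terminal genes therefore never qualify).
#'
#' @inheritParams nearest_downstream
#' @return `NULL` or list with elements `upstream` and `downstream`, each a
#'   pair as in [nearest_downstream()].
#' @export
flanking_pair <- function(map, focal, max_gap = 1e5,
                          convention = c("body_gap", "start_to_start")) {
  convention <- match.arg(convention)
  map <- .check_map(map)
  i <- .map_row(map, focal)
  nxt <- .downstream_index(map)
  j <- nxt[i]
  prv <- match(i, nxt)          # gene whose downstream neighbor is the focal
  if (is.na(j) || is.na(prv)) return(NULL)
  up <- .make_pair(map, i, prv, max_gap, convention)
  dn <- .make_pair(map, i, j, max_gap, convention)
  if (is.null(up) || is.null(dn)) return(NULL)
  list(upstream = up, downstream = dn)
}

#' All genes whose body lies within a radius of the focal body
#'
#' Distance is the minimum body-to-body gap (0 for overlapping genes); genes
#' at distance `<= radius` qualify, the focal gene is excluded, and
#' overlapping non-focal genes are included.
#'
#' @param map a [gene_map()].
#' @param focal gene id.
#' @param radius bp (> 0).
#' @return character vector of neighbor gene ids (possibly empty).
#' @export
neighbors_within <- function(map, focal, radius = 1e5) {
  stopifnot(radius > 0)
  map <- .check_map(map)
  i <- .map_row(map, focal)
  same <- which(map$chrom == map$chrom[i])
  same <- setdiff(same, i)
  if (!length(same)) return(character(0))
  d <- pmax(.body_gap(map, rep(i, length(same)), same), 0L)
  map$gene[same[d <= radius]]
}

#' Overlap flags for adjacent gene pairs
#'
#' Adjacency is map order within a chromosome; a pair overlaps iff the
#' 1-based inclusive spans intersect (touching spans, gap 0, do not overlap).
#'
#' @param map a [gene_map()].
#' @return data.frame with `gene1`, `gene2`, `overlapping`.
#' @export
detect_overlaps <- function(map) {
  map <- .check_map(map)
  out <- lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    if (length(idx) < 2) return(NULL)
    i <- idx[-length(idx)]; j <- idx[-1]
    data.frame(gene1 = map$gene[i], gene2 = map$gene[j],
               overlapping = .body_gap(map, i, j) < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# TRUE for each gene that overlaps its previous or next gene in map order.
.overlaps_adjacent <- function(map) {
  flag <- rep(FALSE, nrow(map))
  ov <- detect_overlaps(map)
  if (is.null(ov) || !nrow(ov)) return(flag)
  hit <- ov[ov$overlapping, ]
  flag[match(hit$gene1, map$gene)] <- TRUE
  flag[match(hit$gene2, map$gene)] <- TRUE
  flag
}

.map_granges <- function(map) {
  GenomicRanges::GRanges(map$chrom,
                         IRanges::IRanges(map$start, map$end),
                         strand = map$strand)
}

#' Which genes overlap a BED interval set
#'
#' TRUE iff at least one base of the gene body (1-based inclusive) intersects
#' at least one interval. Intervals follow the BED convention (0-based,
#' half-open) and are converted centrally: BED `[s, e)` covers 1-based bases
#' `s+1 .. e`.
#'
#' @param map a [gene_map()].
#' @param intervals data.frame with `chrom`, `start`, `end` in BED
#'   convention (e.g. from [read_bed()]).
#' @return logical vector along `map$gene`, named by gene id.
#' @export
gene_interval_overlap <- function(map, intervals) {
  map <- .check_map(map)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!nrow(intervals))
    return(stats::setNames(rep(FALSE, nrow(map)), map$gene))
  gr_genes <- .map_granges(map)
  gr_iv <- GenomicRanges::GRanges(intervals$chrom,
                                  IRanges::IRanges(intervals$start + 1L,
                                                   intervals$end))
  hit <- GenomicRanges::countOverlaps(gr_genes, gr_iv,
                                      ignore.strand = TRUE) > 0
  stats::setNames(hit, map$gene)
}

#' Genes intersecting a genomic window
#'
#' Returns the ids of genes whose body intersects
#' `[position - window, position + window]` on the given chromosome.
#'
#' @param map a [gene_map()].
#' @param chrom chromosome name (must exist in the map).
#' @param position center of the window (1-based bp).
#' @param window half-width in bp.
#' @return character vector of gene ids.
#' @export
window_query <- function(map, chrom, position, window) {
  map <- .check_map(map)
  if (!chrom %in% map$chrom) stop("unknown chromosome: ", chrom)
  lo <- position - window; hi <- position + window
  sel <- map$chrom == chrom & map$start <= hi & map$end >= lo
  map$gene[sel]
}

#' Table of nearest-downstream pairs for every focal gene
#'
#' Vectorized companion to [nearest_downstream()] used by the neighborhood
#' statistics: one row per focal gene that has a downstream neighbor within
#' `max_gap` under the convention.
#'
#' @inheritParams nearest_downstream
#' @return data.frame: `focal`, `neighbor`, `gap_bp`, `start_to_start_bp`,
#'   `orientation`, `overlapping`.
#' @export
downstream_pairs <- function(map, max_gap = 1e5,
                             convention = c("body_gap", "start_to_start")) {
  convention <- match.arg(convention)
  map <- .check_map(map)
  nxt <- .downstream_index(map)
  i <- which(!is.na(nxt)); j <- nxt[i]
  if (!length(i)) return(.empty_pairs())
  gap <- .body_gap(map, i, j)
  overlapping <- gap < 0
  sts <- abs(map$start[j] - map$start[i])
  d <- if (convention == "body_gap") pmax(gap, 0L) else sts
  keep <- d <= max_gap
  left_first <- map$start[i] <= map$start[j]
  ls <- ifelse(left_first, map$strand[i], map$strand[j])
  rs <- ifelse(left_first, map$strand[j], map$strand[i])
  out <- data.frame(focal = map$gene[i], neighbor = map$gene[j],
                    gap_bp = ifelse(overlapping, NA_integer_, gap),
                    start_to_start_bp = sts,
                    orientation = .orientation(ls, rs),
                    overlapping = overlapping,
                    stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  out
}

.empty_pairs <- function() {
  data.frame(focal = character(0), neighbor = character(0),
              gap_bp = integer(0), start_to_start_bp = integer(0),
              orientation = character(0), overlapping = logical(0),
              stringsAsFactors = FALSE)
}
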