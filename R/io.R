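#' Named analysis defaults
#'
#' One place for the pipeline's named constants: the 100 kb neighborhood
#' radius/max gap (the estimated chromatin "ripple" span), the 2-RPKM
#' expression floor, the Z > 1 tissue-specific-upregulation cutoff, the
#' 1.96-SD envelope, the final-0.10 chain retention, and the default
#' randomization counts.
#'
#' @param ... overrides for any field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(max_gap = 1e5, radius = 1e5, expression_floor = 2,
              tsu_threshold = 1, envelope_sd = 1.96,
              final_fraction = 0.10, n_rand_run = 10000,
              n_rand_cluster = 1000, n_rand_subset = 10000,
              n_rand_decay = 1000, distance_convention = "body_gap",
              retain_zeros = FALSE)
  override <- list(...)
  stopifnot(all(names(override) %in% names(cfg)))
  cfg[names(override)] <- override
  class(cfg) <- "run_config"
  cfg
}

.fmt_num <- function(x) {
  # full-precision decimal so written values survive a read round trip
  ifelse(x == round(x) & abs(x) < 1e15,
         sprintf("%.0f", x), sprintf("%.17g", x))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix with its sample sheet
#'
#' The matrix TSV has genes as rows (first column `gene`) and sample ids as
#' columns; the sheet TSV has columns `sample`, `species`, `tissue`, `sex`,
#' `replicate`. Readers validate rather than coerce: duplicate gene ids,
#' sample columns missing from the sheet, negative or non-finite values are
#' errors naming the offender.
#'
#' @param dataset list with `expr` matrix and `samples` sheet.
#' @param matrix_path,sheet_path file paths.
#' @return `write_expression` the paths, invisibly; `read_expression` a
#'   dataset list as produced by [simulate_expression()].
#' @export
write_expression <- function(dataset, matrix_path, sheet_path) {
  df <- data.frame(gene = rownames(dataset$expr),
                   as.data.frame(dataset$expr, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, matrix_path)
  .write_tsv(dataset$samples, sheet_path)
  invisible(c(matrix_path, sheet_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(matrix_path, sheet_path) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  if (anyDuplicated(mat$gene))
    stop("duplicate gene id: ", mat$gene[duplicated(mat$gene)][1])
  expr <- as.matrix(mat[, -1, drop = FALSE])
  rownames(expr) <- mat$gene
  unknown <- setdiff(colnames(expr), sheet$sample)
  if (length(unknown))
    stop("sample column not in sheet: ", paste(unknown, collapse = ", "))
  missing <- setdiff(sheet$sample, colnames(expr))
  if (length(missing))
    stop("sheet sample missing from matrix: ",
         paste(missing, collapse = ", "))
  if (!is.numeric(expr) || any(!is.finite(expr)))
    stop("expression matrix contains non-finite values")
  if (any(expr < 0)) {
    bad <- which(expr < 0, arr.ind = TRUE)[1, ]
    stop("negative expression for gene ", rownames(expr)[bad[1]])
  }
  expr <- expr[, sheet$sample, drop = FALSE]
  list(expr = expr, samples = sheet)
}

#' Write / read a gene map TSV
#'
#' Columns `gene`, `chrom`, `start`, `end`, `strand`; 1-based inclusive.
#'
#' @param map a [gene_map()].
#' @param path file path.
#' @export
write_gene_map <- function(map, path) .write_tsv(as.data.frame(map), path)

#' @rdname write_gene_map
#' @export
read_gene_map <- function(path)
  gene_map(utils::read.delim(path, stringsAsFactors = FALSE))

#' Read / write BED interval files (0-based, half-open)
#'
#' Only the first three BED columns are used. Malformed lines (fewer than 3
#' fields, non-numeric coordinates, `start >= end`) raise a parse error
#' naming the line number.
#'
#' @param path file path.
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return `read_bed`: data.frame `chrom`, `start`, `end` (BED convention).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", i, ": non-numeric coordinates")
    if (s >= e)
      stop("malformed BED line ", i, ": start must be < end")
    data.frame(chrom = f[1], start = s, end = e, stringsAsFactors = FALSE)
  })
  if (!length(out)) return(.empty_bed())
  do.call(rbind, out)
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  writeLines(paste(intervals$chrom, .fmt_num(intervals$start),
                   .fmt_num(intervals$end), sep = "\t"), path)
  invisible(path)
}

#' Write / read a per-gene scalar track TSV (`gene`, `value`)
#'
#' @param track named numeric vector (names are gene ids) or two-column
#'   data.frame.
#' @param path file path.
#' @export
write_scalar_track <- function(track, path) {
  if (!is.data.frame(track))
    track <- data.frame(gene = names(track), value = unname(track),
                        stringsAsFactors = FALSE)
  .write_tsv(track, path)
}

#' @rdname write_scalar_track
#' @export
read_scalar_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Write a Z table TSV
#'
#' @param z_table a `z_table` from [compute_z_table()].
#' @param path file path.
#' @export
write_z_table <- function(z_table, path) .write_tsv(as.data.frame(z_table), path)

#' @rdname write_z_table
#' @export
read_z_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("z_table", "data.frame")
  df
}

#' Write a full synthetic run to a directory, with a manifest
#'
#' Emits expression matrix, sample sheet, gene map, truth tables, BED
#' interval sets and scalar tracks, plus `manifest.txt` recording the seed
#' and every path written.
#'
#' @param sim the list returned by [simulate_expression()].
#' @param map the gene map used.
#' @param annotations optional [generate_annotations()] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, map, annotations = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- character(0)
  write_expression(sim$dataset, p("expression.tsv"), p("samples.tsv"))
  write_gene_map(map, p("gene_map.tsv"))
  paths <- c(paths, p("expression.tsv"), p("samples.tsv"), p("gene_map.tsv"))
  tr <- sim$truth
  anc <- data.frame(gene = rownames(tr$ancestor), tr$ancestor,
                    check.names = FALSE)
  .write_tsv(anc, p("truth_ancestor.tsv"))
  shf <- data.frame(gene = rownames(tr$shift), tr$shift, check.names = FALSE)
  .write_tsv(shf, p("truth_shift.tsv"))
  .write_tsv(data.frame(gene = names(tr$block_id), block_id = tr$block_id),
             p("truth_blocks.tsv"))
  paths <- c(paths, p("truth_ancestor.tsv"), p("truth_shift.tsv"),
             p("truth_blocks.tsv"))
  ape::write.tree(tr$tree, p("tree.nwk"))
  paths <- c(paths, p("tree.nwk"))
  if (!is.null(annotations)) {
    for (nm in c("lad", "peaks", "gained", "depleted")) {
      write_bed(annotations[[nm]], p(paste0(nm, ".bed")))
      paths <- c(paths, p(paste0(nm, ".bed")))
    }
    .write_tsv(annotations$tracks, p("tracks.tsv"))
    paths <- c(paths, p("tracks.tsv"))
  }
  manifest <- c(paste0("seed\t", tr$seed),
                paste0("written\t", basename(paths)))
  writeLines(manifest, p("manifest.txt"))
  invisible(c(paths, p("manifest.txt")))
}
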