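test_that("nearest_downstream follows the 100 kb body-gap rule", {
  map <- toy_map()
  pr <- nearest_downstream(map, "a", max_gap = 1e5)
  expect_equal(pr$neighbor, "b")
  expect_equal(pr$gap_bp, 499)          # 2500 - 2000 - 1
  expect_false(pr$overlapping)
  # left gene +, right gene - : promoters face each other -> convergent
  expect_equal(pr$orientation, "convergent")
  # next gene beyond the max gap -> none
  expect_null(nearest_downstream(map, "c", max_gap = 1e5))
  expect_false(is.null(nearest_downstream(map, "c", max_gap = 2e5)))
  expect_error(nearest_downstream(map, "nope"), "unknown gene")
})

test_that("nearest_downstream and flanking_pair match exhaustive scans", {
  for (seed in 1:3) {
    map <- random_map(50, 3, seed = seed)
    for (conv in c("body_gap", "start_to_start")) {
      pr <- downstream_pairs(map, max_gap = 8e4, convention = conv)
      got <- stats::setNames(pr$neighbor, pr$focal)
      for (g in map$gene) {
        want <- oracle_downstream(map, g, 8e4, conv)
        expect_identical(unname(got[g]),
                         if (is.na(want)) NA_character_ else want,
                         label = paste(seed, conv, g))
      }
    }
    # flanking pairs: both sides within the gap or nothing
    for (g in map$gene) {
      fp <- flanking_pair(map, g, max_gap = 8e4)
      if (!is.null(fp)) {
        expect_equal(fp$downstream$neighbor, oracle_downstream(map, g, 8e4, "body_gap"))
        expect_equal(fp$upstream$focal, g)
      }
    }
  }
})

test_that("neighbors_within uses <= radius on body distance and is symmetric", {
  map <- gene_map(data.frame(
    gene = c("x", "near", "far"), chrom = "chr1",
    start = c(5e5, 5e5 + 1e4 + 99999 + 1, 5e5 + 1e4 + 100001 + 1),
    end = c(5e5 + 1e4, 5e5 + 1e4 + 99999 + 500, 5e5 + 1e4 + 100001 + 500),
    strand = "+"))
  # gaps are exactly 99,999 and 100,001: only the first qualifies at 100 kb
  expect_identical(neighbors_within(map, "x", 1e5), "near")

  map2 <- random_map(40, 2, seed = 5)
  for (g1 in map2$gene) for (g2 in neighbors_within(map2, g1, 5e4))
    expect_true(g1 %in% neighbors_within(map2, g2, 5e4))
  # counts match a brute-force distance matrix
  for (g in map2$gene) {
    same <- map2[map2$chrom == map2$chrom[match(g, map2$gene)] &
                   map2$gene != g, ]
    i <- match(g, map2$gene)
    d <- pmax(pmax(map2$start[i], same$start) -
                pmin(map2$end[i], same$end) - 1, 0)
    expect_equal(length(neighbors_within(map2, g, 5e4)), sum(d <= 5e4))
  }
})

test_that("orientation classes follow strand geometry and partition pairs", {
  expect_equal(classify_orientation("-", "+"), "divergent")
  expect_equal(classify_orientation("+", "-"), "convergent")
  expect_equal(classify_orientation("+", "+"), "cooriented")
  expect_equal(classify_orientation("-", "-"), "cooriented")
  expect_error(classify_orientation(NA, "+"), "missing strand")

  pr <- downstream_pairs(random_map(80, 3, seed = 9), max_gap = Inf)
  expect_true(all(pr$orientation %in%
                    c("divergent", "convergent", "cooriented")))
  expect_equal(sum(table(pr$orientation)), nrow(pr))
})

test_that("overlap detection: touching genes do not overlap", {
  map <- gene_map(data.frame(gene = c("p", "q", "r"), chrom = "chr1",
                             start = c(1, 50, 151), end = c(100, 150, 200),
                             strand = "+"))
  ov <- detect_overlaps(map)
  expect_true(ov$overlapping[ov$gene1 == "p"])    # 50-100 shared
  expect_false(ov$overlapping[ov$gene1 == "q"])   # gap 0, touching
  # brute force on random maps
  map2 <- random_map(60, 2, seed = 3)
  ov2 <- detect_overlaps(map2)
  for (k in seq_len(nrow(ov2))) {
    i <- match(ov2$gene1[k], map2$gene); j <- match(ov2$gene2[k], map2$gene)
    inter <- min(map2$end[i], map2$end[j]) - max(map2$start[i], map2$start[j])
    expect_equal(ov2$overlapping[k], inter >= 0)
  }
})

test_that("gene/BED overlap honors the 0-based half-open convention", {
  map <- gene_map(data.frame(gene = "g1", chrom = "chr1", start = 1001,
                             end = 2000, strand = "+"))
  # BED 2000-3000 covers 1-based 2001..3000: no overlap with 1001..2000
  expect_false(unname(gene_interval_overlap(
    map, data.frame(chrom = "chr1", start = 2000, end = 3000))))
  expect_true(unname(gene_interval_overlap(
    map, data.frame(chrom = "chr1", start = 1999, end = 2100))))
  # brute-force per-bp check on a small random fixture
  set.seed(8)
  map2 <- gene_map(data.frame(gene = paste0("g", 1:15), chrom = "chr1",
                              start = s <- sort(sample.int(3000, 15)),
                              end = s + sample.int(300, 15), strand = "+"))
  iv <- data.frame(chrom = "chr1", start = st <- sort(sample.int(3200, 5)),
                   end = st + sample.int(200, 5))
  got <- gene_interval_overlap(map2, iv)
  covered <- unique(unlist(Map(function(s, e) (s + 1):e, iv$start, iv$end)))
  for (k in seq_len(nrow(map2)))
    expect_equal(unname(got[map2$gene[k]]),
                 any((map2$start[k]:map2$end[k]) %in% covered))
})

test_that("window_query returns genes intersecting the window", {
  map <- toy_map()
  expect_identical(window_query(map, "chr1", 5e6, 1e4), character(0))
  # gene straddling the window edge is included
  expect_true("c" %in% window_query(map, "chr1", 46000, 2000))
  expect_error(window_query(map, "chr9", 1, 1), "unknown chromosome")
  map2 <- random_map(50, 2, seed = 13)
  got <- window_query(map2, "chr1", 2.5e5, 5e4)
  want <- map2$gene[map2$chrom == "chr1" & map2$start <= 3e5 &
                      map2$end >= 2e5]
  expect_setequal(got, want)
})

test_that("gene_map validates and sorts; ties break by end then id", {
  expect_error(gene_map(data.frame(gene = c("a", "a"), chrom = "c",
                                   start = 1, end = 2, strand = "+")),
               "duplicate")
  expect_error(gene_map(data.frame(gene = "a", chrom = "c", start = 0,
                                   end = 2, strand = "+")), ">= 1")
  m <- gene_map(data.frame(gene = c("b", "a"), chrom = "c",
                           start = c(10, 10), end = c(30, 20),
                           strand = "+"))
  expect_identical(m$gene, c("a", "b"))
})
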