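test_that("spearman_cor: limits, rank oracle, degenerate flag", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 7, 8, 0.2, 6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(14)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  res <- spearman_cor(a, b)
  # direct rank-based computation and R's own estimate
  expect_equal(res$rho, cor(rank(a), rank(b)))
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  expect_equal(res$rho, unname(ct$estimate))
  expect_equal(res$p_value,
               suppressWarnings(cor.test(a, b, method = "spearman",
                                         exact = FALSE)$p.value),
               tolerance = 1e-6)
  expect_false(spearman_cor(rep(1, 10), rnorm(10))$defined)
  expect_false(spearman_cor(1:2, 2:1)$defined)
})

test_that("bin_means reproduces sorted-group means with SEM", {
  set.seed(3)
  f <- rnorm(1000); nb <- rnorm(1000)
  b <- bin_means(f, nb, bin_size = 500)
  expect_equal(nrow(b), 2)
  expect_false(any(b$partial))
  o <- order(f)
  expect_equal(b$neighbor_mean[1], mean(nb[o][1:500]))
  expect_equal(b$focal_mean[2], mean(f[o][501:1000]))
  expect_equal(b$neighbor_sem[1], sd(nb[o][1:500]) / sqrt(500))
  b2 <- bin_means(rnorm(1100), rnorm(1100), 500)
  expect_identical(b2$partial, c(FALSE, FALSE, TRUE))
  expect_equal(b2$n[3], 100)
  bc <- bin_means(1:4, rep(2, 4), 2)
  expect_equal(bc$neighbor_sem, c(0, 0))
})

test_that("run_edges counts switches and maximal runs", {
  s <- c(1, 1, 1, -1, 1, 1, 1)     # +++-+++ has two edges
  rs <- run_edges(s)
  expect_equal(rs$edge_count, 2)
  expect_equal(rs$clusters$size, c(3, 1, 3))
  all_plus <- run_edges(rep(1, 9))
  expect_equal(all_plus$edge_count, 0)
  expect_equal(all_plus$clusters$size, 9)
  # zeros are removed before runs are formed
  rz <- run_edges(c(1, 0, 1, -1, 0, -1))
  expect_equal(rz$edge_count, 1)
  expect_equal(rz$n_used, 4)
  # brute-force pairwise scan on a random sequence
  set.seed(10)
  s <- sample(c(-1, 1), 200, replace = TRUE)
  expect_equal(run_edges(s)$edge_count, sum(diff(s) != 0))
  # edges = clusters - chromosomes
  ch <- rep(c("c1", "c2"), each = 100)
  rs2 <- run_edges(s, ch)
  expect_equal(rs2$edge_count, nrow(rs2$clusters) - 2)
  # cluster sizes always sum to the non-zero gene count
  expect_equal(sum(rs2$clusters$size), 200)
})

test_that("run randomization preserves counts; clustered signs hit the floor", {
  set.seed(15)
  signs <- sample(c(-1, 1), 60, replace = TRUE)
  chrom <- rep(c("c1", "c2"), each = 30)
  # every randomization preserves per-chromosome +/- counts: the null mean
  # of a fully random sequence equals the theoretical expectation
  rt <- run_randomization_test(signs, chrom, n_rand = 300, seed = 2)
  expect_true(rt$envelope$lower <= rt$envelope$mean)
  expect_true(rt$envelope$mean <= rt$envelope$upper)
  # perfectly clustered signs: minimal edges, P = 1/(M+1)
  clustered <- rep(c(1, -1), each = 30)
  rtc <- run_randomization_test(clustered, rep("c1", 60), n_rand = 200,
                                seed = 3)
  expect_equal(rtc$empirical_p, 1 / 201)
})

test_that("run test empirical P matches exact enumeration on small sequences", {
  # exact null: enumerate all C(10,5) placements of +1 among 10 loci
  signs <- c(1, 1, 1, 1, 1, -1, -1, -1, -1, -1)
  obs <- run_edges(signs)$edge_count
  combos <- utils::combn(10, 5)
  exact_edges <- apply(combos, 2, function(pos) {
    v <- rep(-1, 10); v[pos] <- 1
    sum(diff(v) != 0)
  })
  p_exact <- mean(exact_edges <= obs)
  rt <- run_randomization_test(signs, n_rand = 4000, seed = 8)
  # (N+1)/(M+1) is consistent for the exact permutation P
  expect_lt(abs(rt$empirical_p - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
})

test_that("cluster spectrum: degenerate patterns and conservation", {
  alt <- rep(c(1, -1), 20)
  cs <- cluster_spectrum_test(alt, n_rand = 50, seed = 1)
  expect_equal(cs$observed[1], 40)           # all clusters are singletons
  expect_true(all(cs$observed[-1] == 0))
  set.seed(20)
  s <- sample(c(-1, 1, 0), 80, replace = TRUE)
  cs2 <- cluster_spectrum_test(s, n_rand = 30, seed = 2)
  expect_equal(sum(cs2$size * cs2$observed), sum(s != 0))
  expect_equal(sum(cs2$size * cs2$null_mean), sum(s != 0), tolerance = 1e-9)
})

test_that("empirical P formula is exact", {
  expect_equal(signif(empirical_p(0, 10000), 4), 9.999e-05)
  expect_equal(empirical_p(10000, 10000), 1)
  expect_equal(empirical_p(4, 9999), 5e-04)
  expect_error(empirical_p(5, 4), "0 <= N <= M")
  expect_error(empirical_p(-1, 4), "0 <= N <= M")
})

test_that("subset_mc: identity subset gives P = 1, planted subsets small P", {
  set.seed(30)
  pool <- data.frame(focal_z = rnorm(120), neighbor_z = rnorm(120))
  rho_all <- spearman_cor(pool$focal_z, pool$neighbor_z)$rho
  mc <- subset_mc(pool, rho_all, nrow(pool), n_draws = 50, seed = 1)
  expect_equal(mc$empirical_p, 1)
  # plant a concordant subset much stronger than the pool
  planted <- data.frame(focal_z = seq_len(30),
                        neighbor_z = seq_len(30) + rnorm(30, 0, 0.1))
  pool2 <- rbind(pool, planted)
  rho_sub <- spearman_cor(planted$focal_z, planted$neighbor_z)$rho
  mc2 <- subset_mc(pool2, rho_sub, 30, n_draws = 400, seed = 2)
  expect_lt(mc2$empirical_p, 0.02)
  expect_error(subset_mc(pool, 0.5, 1000), "larger than pool")
})

test_that("mann_whitney matches the pairwise-comparison count", {
  set.seed(40)
  for (i in 1:3) {
    a <- sample(1:20, 8, replace = TRUE)
    b <- sample(1:20, 11, replace = TRUE)
    mw <- mann_whitney(a, b)
    U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mw$U, U)
  }
  a <- c(1, 2, 3, 4, 5)
  same <- mann_whitney(a, a)
  expect_equal(same$U, length(a)^2 / 2)   # U at its null mean
  expect_gt(same$p_value, 0.9)
  apart <- mann_whitney(a + 100, a)
  expect_equal(apart$U, 25)
  expect_lt(apart$p_value, 0.01)
})

test_that("neighbor correlations detect planted block structure", {
  tr <- five_species_tree()
  cfg <- sim_config(n_genes = 400, n_chromosomes = 4, shift_prob = 0.4,
                    shift_sd = 3, seed = 18, tissues = "brain",
                    sexes = list(male = "brain"), n_replicates = c(male = 3L))
  gm <- generate_gene_map(cfg)
  sim <- simulate_expression(gm, cfg)
  zt <- compute_z_table(sim$dataset, tr)
  z <- neighborz:::.z_vector(zt, "brain", "male")
  for (mode in c("downstream", "flank_pair", "window")) {
    nc <- neighbor_correlation(z, gm, mode = mode)
    expect_true(nc$defined)
    expect_gt(nc$rho, 0)
    expect_lt(nc$p_value, 1e-4)
  }
  # window mode with every gene isolated: no pairs, undefined
  iso <- gene_map(data.frame(gene = c("u", "v"), chrom = "chr1",
                             start = c(1, 5e6), end = c(100, 5e6 + 100),
                             strand = "+"))
  ncw <- neighbor_correlation(stats::setNames(c(1, -1), c("u", "v")), iso,
                              mode = "window")
  expect_false(ncw$defined)
})

test_that("fold change gives the same qualitative neighbor signal as Z", {
  tr <- five_species_tree()
  cfg <- sim_config(n_genes = 300, n_chromosomes = 3, shift_prob = 0.4,
                    shift_sd = 3, seed = 19, tissues = "brain",
                    sexes = list(male = "brain"), n_replicates = c(male = 3L))
  gm <- generate_gene_map(cfg)
  sim <- simulate_expression(gm, cfg)
  zt <- compute_z_table(sim$dataset, tr)
  sub <- zt[zt$tissue == "brain" & zt$sex == "male", ]
  keep <- !sub$zero_flag & !sub$degenerate & !is.na(sub$fold_change)
  zv <- stats::setNames(sub$Z_mod[keep], sub$gene[keep])
  fc <- stats::setNames(sub$fold_change[keep], sub$gene[keep])
  nz <- neighbor_correlation(zv, gm)
  nf <- neighbor_correlation(fc, gm)
  expect_gt(nz$rho, 0)
  expect_gt(nf$rho, 0)
})

test_that("distance_decay flags empty grids and stays in the envelope on null data", {
  tr <- five_species_tree()
  cfg <- sim_config(n_genes = 300, n_chromosomes = 3, shift_prob = 0,
                    seed = 23, tissues = "brain",
                    sexes = list(male = "brain"), n_replicates = c(male = 3L))
  gm <- generate_gene_map(cfg)
  sim <- simulate_expression(gm, cfg)
  zt <- compute_z_table(sim$dataset, tr)
  z <- neighborz:::.z_vector(zt, "brain", "male")
  dd <- distance_decay(z, gm, min_gaps = c(1, 1e4, 1e5, 5e5, 1e6),
                       n_rand = 200, seed = 4)
  expect_true(all(dd$defined))
  outside <- dd$rho < dd$lower | dd$rho > dd$upper
  expect_lte(sum(outside), 1)
  # grid beyond the chromosome span: no pairs, flagged
  dd2 <- distance_decay(z, gm, min_gaps = c(1e9), n_rand = 10, seed = 1)
  expect_false(dd2$defined[1])
  expect_error(distance_decay(z, gm, min_gaps = c(5, 5)), "increasing")
})

test_that("bonferroni is a pure post-processing step", {
  p <- c(0.01, 0.2, 0.9)
  adj <- bonferroni(p)
  expect_equal(as.numeric(adj), pmin(1, 3 * p))
  expect_equal(attr(adj, "family_size"), 3)
  expect_equal(as.numeric(bonferroni(0.04, m = 10)), 0.4)
})
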