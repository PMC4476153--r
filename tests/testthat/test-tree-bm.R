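test_that("bm_covariance matches shared-path depths", {
  # two tips joined at the root: no shared path
  tr2 <- ape::read.tree(text = "(a:3,b:3)r;")
  C <- bm_covariance(tr2, c("a", "b"))
  expect_equal(unname(C), matrix(c(3, 0, 0, 3), 2))

  tr <- five_species_tree()
  C <- bm_covariance(tr, tr$tip.label)
  # diagonal is the total root-to-tip path length
  expect_equal(unname(diag(C)), rep(29, 5))
  # human/chimp covariance is the depth of their common ancestor
  expect_equal(C["human", "chimp"], 29 - 6.7)
  # independent oracle: C_ij = (d(root,i) + d(root,j) - d(i,j)) / 2 from
  # the full patristic distance matrix
  nodes <- c(tr$tip.label, "hc", "hcg")
  Cn <- bm_covariance(tr, nodes)
  D <- ape::dist.nodes(tr)
  ids <- vapply(nodes, function(v) neighborz:::.resolve_node(tr, v),
                integer(1))
  root <- ape::Ntip(tr) + 1L
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    expect_equal(Cn[i, j],
                 (D[root, ids[i]] + D[root, ids[j]] - D[ids[i], ids[j]]) / 2,
                 tolerance = 1e-10)
  }
  # and against ape's own tip covariance
  expect_equal(unname(C[tr$tip.label, tr$tip.label]),
               unname(ape::vcv(tr)[tr$tip.label, tr$tip.label]))
  expect_error(bm_covariance(tr, "no_such_node"), "unknown node")
})

test_that("fit_bm recovers degenerate and symmetric cases and the likelihood", {
  tr <- five_species_tree()
  x <- stats::setNames(rep(7, 5), tr$tip.label)
  f <- fit_bm(x, tr)
  expect_equal(f$root_mean, 7)
  expect_equal(f$rate, 0)

  tr2 <- ape::read.tree(text = "(a:2,b:2)r;")
  f2 <- fit_bm(c(a = 1, b = 5), tr2)
  expect_equal(f2$root_mean, 3)

  # log-likelihood equals a direct multivariate-normal density evaluation
  set.seed(11)
  x <- stats::setNames(rnorm(5, 4, 2), tr$tip.label)
  f <- fit_bm(x, tr, method = "ML")
  C <- bm_covariance(tr, names(x)) * f$rate
  L <- chol(C)
  q <- sum(backsolve(L, x - f$root_mean, transpose = TRUE)^2)
  ll <- -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + q)
  expect_equal(f$log_likelihood, ll, tolerance = 1e-8)

  # zero branch lengths -> singular covariance, explicit message
  tr0 <- ape::read.tree(text = "(a:0,b:0)r;")
  expect_error(fit_bm(c(a = 1, b = 2), tr0), "singular")
})

test_that("ancestral_posterior: degenerate, equivariance, and phytools cross-check", {
  tr <- five_species_tree()
  x <- stats::setNames(rep(3.3, 5), tr$tip.label)
  a <- ancestral_posterior(x, tr, "hc")
  expect_equal(a$E_a, 3.3)
  expect_equal(a$V_a, 0)

  set.seed(21)
  x <- stats::setNames(rnorm(5, 2, 1), tr$tip.label)
  f <- fit_bm(x, tr)
  a <- ancestral_posterior(x, tr, "hc", f)
  # scaling all tips by c scales E_a by c and V_a by c^2
  cs <- 3.7
  fs <- fit_bm(cs * x, tr)
  as <- ancestral_posterior(cs * x, tr, "hc", fs)
  expect_equal(as$E_a, cs * a$E_a, tolerance = 1e-10)
  expect_equal(as$V_a, cs^2 * a$V_a, tolerance = 1e-10)
  # adding a constant shifts E_a and leaves V_a unchanged
  ak <- ancestral_posterior(x + 5, tr, "hc", fit_bm(x + 5, tr))
  expect_equal(ak$E_a, a$E_a + 5, tolerance = 1e-10)
  expect_equal(ak$V_a, a$V_a, tolerance = 1e-10)
  # conditional mean agrees with phytools' ML ancestral states
  fa <- phytools::fastAnc(tr, x)
  hc_num <- as.character(hc_ancestor(tr))
  expect_equal(unname(a$E_a), unname(fa[hc_num]), tolerance = 1e-6)
  expect_error(ancestral_posterior(x, tr, "human", f), "internal")
})

test_that("ancestral_posterior matches a rejection-sampling oracle", {
  # 3-taxon tree, mu and rate fixed; ancestor states from joint BM
  # simulations retained by tip-matching
  tr3 <- ape::read.tree(text = "((a:1,b:1)ab:1,c:2)r;")
  target <- c(a = 0.5, b = -0.3, c = 1.0)
  fixed <- structure(list(root_mean = 0, rate = 1), class = "bm_fit")
  a <- ancestral_posterior(target, tr3, "ab", fixed,
                           mean_uncertainty = FALSE)
  set.seed(99)
  n_sim <- 2e5
  root <- rnorm(n_sim, 0, 0)                    # root fixed at mu = 0
  ab <- root + rnorm(n_sim, 0, 1)
  ta <- ab + rnorm(n_sim, 0, 1)
  tb <- ab + rnorm(n_sim, 0, 1)
  tc <- root + rnorm(n_sim, 0, sqrt(2))
  delta <- 0.3
  keep <- abs(ta - target["a"]) < delta & abs(tb - target["b"]) < delta &
    abs(tc - target["c"]) < delta
  kept <- ab[keep]
  expect_gt(length(kept), 200)
  mc_se <- sd(kept) / sqrt(length(kept))
  expect_lt(abs(mean(kept) - a$E_a), 3 * mc_se + 0.02)
  var_se <- var(kept) * sqrt(2 / (length(kept) - 1))
  # window smoothing adds ~delta^2/3-scale variance; allow for it
  expect_lt(abs(var(kept) - a$V_a), 3 * var_se + delta^2 / 3)
})

test_that("vectorized ancestral_table equals the per-gene path", {
  tr <- five_species_tree()
  set.seed(5)
  tm <- matrix(rnorm(40, 3, 1), 8, 5,
               dimnames = list(paste0("g", 1:8), tr$tip.label))
  tab <- ancestral_table(tm, tr, rate = "per_gene", method = "ML")
  for (i in c(1, 4, 8)) {
    f <- fit_bm(tm[i, ], tr, method = "ML")
    a <- ancestral_posterior(tm[i, ], tr, "hc", f)
    expect_equal(tab$E_a[i], a$E_a, tolerance = 1e-10)
    expect_equal(tab$V_a[i], a$V_a, tolerance = 1e-10)
    expect_equal(tab$rate[i], f$rate, tolerance = 1e-10)
  }
  # pooled rate is the REML average of per-gene quadratic forms
  tabp <- ancestral_table(tm, tr, rate = "pooled")
  tabr <- ancestral_table(tm, tr, rate = "per_gene", method = "REML")
  expect_equal(tabp$rate, rep(mean(tabr$rate), 8), tolerance = 1e-10)
})

test_that("MCMC ancestral estimates agree with the analytic posterior", {
  tr <- five_species_tree()
  x <- stats::setNames(rep(4.2, 5), tr$tip.label)
  m <- mcmc_ancestral(x, tr, "hc", n_iter = 1000, seed = 3)
  expect_equal(m$E_a, 4.2, tolerance = 1e-4)

  set.seed(31)
  d <- replicate(8, {
    x <- stats::setNames(rnorm(5, 3, 1.5), tr$tip.label)
    a <- ancestral_posterior(x, tr, "hc", fit_bm(x, tr, "REML"))
    m <- mcmc_ancestral(x, tr, "hc", n_iter = 2e4, seed = sample.int(1e6, 1))
    abs(m$E_a - a$E_a) / sqrt(a$V_a)
  })
  expect_lt(mean(d), 0.05)

  x <- stats::setNames(c(1, 2, 3, 4, 5), tr$tip.label)
  m1 <- mcmc_ancestral(x, tr, "hc", n_iter = 2000, seed = 7)
  m2 <- mcmc_ancestral(x, tr, "hc", n_iter = 2000, seed = 7)
  expect_identical(m1$E_a, m2$E_a)
  expect_identical(m1$V_a, m2$V_a)
  expect_equal(m1$n_samples, 200)  # final 10% of the chain
  expect_error(mcmc_ancestral(x, tr, "hc", n_iter = 50), "at least 100")
})
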