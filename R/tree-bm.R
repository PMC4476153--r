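#' Default five-primate time tree
#'
#' Rooted ultrametric tree over human, chimp, gorilla, orangutan and macaque
#' with branch lengths in millions of years (approximate consensus divergence
#' times: human-chimp 6.7 My, +gorilla 9.0, +orangutan 15.4, +macaque 29.0).
#' The human-chimp ancestor node is labelled `"hc"`.
#'
#' @return An [ape::phylo] tree with node labels.
#' @export
#' @examples
#' tr <- primate_tree()
#' hc_ancestor(tr)
primate_tree <- function() {
  txt <- "((((human:6.7,chimp:6.7)hc:2.3,gorilla:9.0)hcg:6.4,orangutan:15.4)hcgo:13.6,macaque:29.0)root;"
  ape::read.tree(text = txt)
}

#' Node number of the human-chimp ancestor
#'
#' @param tree a rooted `phylo` tree containing tips `"human"` and `"chimp"`.
#' @return Integer node number of their most recent common ancestor.
#' @export
hc_ancestor <- function(tree) {
  stopifnot(all(c("human", "chimp") %in% tree$tip.label))
  ape::getMRCA(tree, c("human", "chimp"))
}

# Resolve a node given as tip label, node label, or number.
.resolve_node <- function(tree, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > ape::Ntip(tree) + tree$Nnode)
      stop("node number out of range: ", node)
    return(node)
  }
  i <- match(node, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(node, tree$node.label)
    if (!is.na(j)) return(ape::Ntip(tree) + j)
  }
  k <- suppressWarnings(as.integer(node))   # a node number passed as text
  if (!is.na(k) && k >= 1L && k <= ape::Ntip(tree) + tree$Nnode) return(k)
  stop("unknown node name: ", node)
}

# Root-to-node depths and parent lookup for all nodes.
.tree_depths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n)
  blen <- numeric(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  root <- ape::Ntip(tree) + 1L
  depth <- numeric(n)
  # accumulate depths by walking each node up to the root (trees are small)
  for (v in seq_len(n)) {
    d <- 0
    u <- v
    while (u != root) {
      d <- d + blen[u]
      u <- parent[u]
    }
    depth[v] <- d
  }
  list(parent = parent, depth = depth, root = root)
}

# Ancestor chain (self first, root last).
.ancestor_chain <- function(info, v) {
  chain <- v
  while (v != info$root) {
    v <- info$parent[v]
    chain <- c(chain, v)
  }
  chain
}

#' Unit-rate Brownian-motion covariance structure on a tree
#'
#' Under Brownian motion with rate `sigma^2`, the covariance between the trait
#' values at two nodes equals `sigma^2` times the length of their shared
#' root-to-node path (the depth of their most recent common ancestor). This
#' returns the unit-rate matrix (`sigma^2` factored out) for any mix of tips
#' and named internal nodes.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param nodes character vector of tip labels / node labels (or node
#'   numbers). Defaults to all tips.
#' @return Symmetric positive semidefinite matrix with `nodes` as dimnames.
#' @export
bm_covariance <- function(tree, nodes = tree$tip.label) {
  info <- .tree_depths(tree)
  ids <- vapply(nodes, function(v) .resolve_node(tree, v), integer(1))
  chains <- lapply(ids, .ancestor_chain, info = info)
  k <- length(ids)
  C <- matrix(0, k, k, dimnames = list(nodes, nodes))
  for (i in seq_len(k)) {
    for (j in i:k) {
      common <- intersect(chains[[i]], chains[[j]])
      C[i, j] <- C[j, i] <- max(info$depth[common])
    }
  }
  C
}

#' Fit a Brownian-motion model to tip values
#'
#' Estimates the root state `mu` by generalized least squares and the rate
#' `sigma^2` by maximum likelihood (or REML) for a single continuous trait on
#' a tree.
#'
#' @param x named numeric vector of tip values (names must match tip labels).
#' @param tree rooted `phylo` with branch lengths.
#' @param method `"ML"` (rate = quadratic form / n) or `"REML"` (/ (n-1)).
#' @return An object of class `bm_fit`: list with `root_mean`, `rate`,
#'   `log_likelihood` (Gaussian log density at the fitted parameters),
#'   `method`, `n`.
#' @export
#' @examples
#' tr <- primate_tree()
#' x <- c(human = 5, chimp = 4.5, gorilla = 6, orangutan = 3, macaque = 7)
#' fit_bm(x, tr)
fit_bm <- function(x, tree, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 2, all(is.finite(x)))
  if (is.null(names(x)) || !all(names(x) %in% tree$tip.label))
    stop("tip values must be named by tip labels present in the tree")
  C <- bm_covariance(tree, names(x))
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance (zero branch lengths?): ",
         conditionMessage(e)))
  one <- rep(1, length(x))
  mu <- drop(crossprod(one, Cinv %*% x) / crossprod(one, Cinv %*% one))
  r <- x - mu
  q <- drop(crossprod(r, Cinv %*% r))
  n <- length(x)
  rate <- if (method == "ML") q / n else q / (n - 1)
  ll <- if (rate > 0) {
    -0.5 * (n * log(2 * pi * rate) + determinant(C)$modulus[1] + q / rate)
  } else Inf
  structure(list(root_mean = mu, rate = rate, log_likelihood = ll,
                 method = method, n = n, tips = names(x)),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("Brownian-motion fit (", x$method, "), ", x$n, " tips\n",
      "  root mean: ", format(x$root_mean), "\n",
      "  rate:      ", format(x$rate), "\n", sep = "")
  invisible(x)
}

#' Closed-form posterior of an ancestral state
#'
#' Conditional mean `E_a` and variance `V_a` of the trait value at an internal
#' node given the tip values, under the fitted Gaussian Brownian-motion model:
#' `E_a = mu + c' C^-1 (x - mu)`, with `c` the unit-rate covariances between
#' the node and the tips. By default `V_a` is the full prediction variance,
#' i.e. the rate-scaled Schur complement plus the contribution of the
#' uncertainty in the GLS root mean (`mean_uncertainty = FALSE` drops that
#' term and conditions on `mu` as known).
#'
#' @param x named tip values.
#' @param tree rooted `phylo`.
#' @param node internal node (label or number).
#' @param fit a [fit_bm()] result for the same tips (supply a hand-built one
#'   to fix the rate).
#' @param mean_uncertainty include the GLS-mean term in `V_a` (default TRUE).
#' @return Object of class `ancestral_estimate`: list with `E_a`, `V_a`,
#'   `method = "analytic"`.
#' @export
ancestral_posterior <- function(x, tree, node, fit = fit_bm(x, tree),
                                mean_uncertainty = TRUE) {
  id <- .resolve_node(tree, node)
  if (id <= ape::Ntip(tree)) stop("node must be internal, got a tip")
  g <- .anc_geometry(tree, names(x), id)
  mu <- fit$root_mean
  Ea <- mu + drop(crossprod(g$w, x - mu))
  s <- g$caa - drop(crossprod(g$cvec, g$w))
  if (mean_uncertainty) s <- s + (1 - sum(g$w))^2 / g$q11
  Va <- fit$rate * s
  structure(list(E_a = Ea, V_a = max(0, Va), method = "analytic",
                 n_samples = NA_integer_),
            class = "ancestral_estimate")
}

#' @export
print.ancestral_estimate <- function(x, ...) {
  cat("Ancestral estimate (", x$method, "): E_a = ", format(x$E_a),
      ", V_a = ", format(x$V_a), "\n", sep = "")
  invisible(x)
}

# Shared geometry for ancestral conditioning: tip covariance inverse,
# node-tip covariance vector, node depth, and derived weights.
.anc_geometry <- function(tree, tips, node_id) {
  Cfull <- bm_covariance(tree, c(tips, node_id))
  k <- length(tips)
  Ct <- Cfull[seq_len(k), seq_len(k), drop = FALSE]
  cvec <- Cfull[seq_len(k), k + 1L]
  caa <- Cfull[k + 1L, k + 1L]
  Cinv <- solve(Ct)
  one <- rep(1, k)
  list(Ct = Ct, Cinv = Cinv, cvec = cvec, caa = caa,
       w = drop(Cinv %*% cvec),
       a = drop(Cinv %*% one) / drop(crossprod(one, Cinv %*% one)),
       q11 = drop(crossprod(one, Cinv %*% one)))
}

#' Ancestral estimates for a matrix of genes at once
#'
#' Vectorized equivalent of [fit_bm()] + [ancestral_posterior()] for many
#' genes sharing one tree: rows are genes, columns are species tip values.
#' `rate = "pooled"` shares a single REML rate across genes (each gene keeps
#' its own GLS mean); with only a handful of tips the per-gene rate has very
#' few degrees of freedom, and pooling is the calibrated choice when genes
#' can be assumed to share a rate.
#'
#' @param tipmat numeric matrix, genes x species; colnames are tip labels.
#' @param tree rooted `phylo`.
#' @param node internal node (default: human-chimp ancestor).
#' @param rate `"per_gene"` or `"pooled"`.
#' @param method `"ML"` or `"REML"` for the per-gene rate.
#' @param mean_uncertainty as in [ancestral_posterior()].
#' @return data.frame with one row per gene: `E_a`, `V_a`, `rate`,
#'   `root_mean`.
#' @export
ancestral_table <- function(tipmat, tree, node = hc_ancestor(tree),
                            rate = c("per_gene", "pooled"),
                            method = c("ML", "REML"),
                            mean_uncertainty = TRUE) {
  rate <- match.arg(rate)
  method <- match.arg(method)
  tipmat <- as.matrix(tipmat)
  stopifnot(!is.null(colnames(tipmat)),
            all(colnames(tipmat) %in% tree$tip.label))
  id <- .resolve_node(tree, node)
  g <- .anc_geometry(tree, colnames(tipmat), id)
  n <- ncol(tipmat)
  mu <- drop(tipmat %*% g$a)
  R <- tipmat - outer(mu, rep(1, n))
  q <- rowSums((R %*% g$Cinv) * R)
  sig2 <- switch(method, ML = q / n, REML = q / (n - 1))
  if (rate == "pooled") sig2 <- rep(sum(q) / (nrow(tipmat) * (n - 1)), nrow(tipmat))
  Ea <- mu + drop(R %*% g$w)
  s <- g$caa - drop(crossprod(g$cvec, g$w))
  if (mean_uncertainty) s <- s + (1 - sum(g$w))^2 / g$q11
  data.frame(gene = rownames(tipmat) %||% seq_len(nrow(tipmat)),
             E_a = Ea, V_a = pmax(0, sig2 * s), rate = sig2, root_mean = mu,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MCMC estimate of an ancestral state
#'
#' Samples the joint posterior of (root mean, rate, node state) under
#' Brownian motion with improper reference priors (flat on the mean, flat on
#' the log rate — the standard scale-parameter choice; a flat prior on the
#' rate itself leaves the five-tip rate posterior without a finite mean and
#' the node-state estimate without a finite Monte Carlo variance), using
#' a random-walk Metropolis update on log sigma^2 and exact conditional
#' (Gibbs) draws of the root mean and the node state at every iteration
#' (both conditionals are Gaussian in closed form, so mixing for the node
#' state is limited only by the rate's random walk). `E_a` and
#' `V_a` are the mean and variance of the node-state samples in the final
#' `final_fraction` of the chain (default 0.10: only the last tenth of the
#' chain is treated as converged, the retention rule used with long
#' trait-MCMC runs).
#'
#' @param x named tip values.
#' @param tree rooted `phylo`.
#' @param node internal node.
#' @param n_iter chain length (>= 100).
#' @param seed integer seed for reproducibility (optional).
#' @param proposal_scale RW sd for log sigma^2 (default 1).
#' @param final_fraction fraction of the chain, taken from the end, used for
#'   the estimates.
#' @return `ancestral_estimate` with `method = "mcmc"`, `n_samples`, the
#'   acceptance rate, and a `converged` flag (split-half mean difference of
#'   the retained samples < 0.1 posterior SD; logged, not enforced).
#' @export
mcmc_ancestral <- function(x, tree, node, n_iter = 10000, seed = NULL,
                           proposal_scale = NULL, final_fraction = 0.10) {
  if (n_iter < 100) stop("chain length must be at least 100")
  stopifnot(final_fraction > 0, final_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  id <- .resolve_node(tree, node)
  if (id <= ape::Ntip(tree)) stop("node must be internal, got a tip")
  g <- .anc_geometry(tree, names(x), id)
  n <- length(x)
  qxx <- drop(crossprod(x, g$Cinv %*% x))
  qx1 <- drop(crossprod(rep(1, n), g$Cinv %*% x))
  q11 <- g$q11
  wx <- drop(crossprod(g$cvec, g$Cinv %*% x))
  s1 <- sum(g$w)
  s0 <- max(g$caa - drop(crossprod(g$cvec, g$w)), 0)

  init <- fit_bm(x, tree, method = "REML")
  mu_hat <- qx1 / q11
  mu <- init$root_mean
  sig2 <- max(init$rate, 1e-10 * (1 + abs(mu)))
  lsig <- log(sig2)
  if (is.null(proposal_scale)) proposal_scale <- 1

  # tips-only log posterior of log sigma^2 given mu (flat prior on lsig)
  logpost <- function(mu, lsig) {
    q <- qxx - 2 * mu * qx1 + mu^2 * q11
    -0.5 * (n * lsig + q * exp(-lsig))
  }
  keep_from <- floor(n_iter * (1 - final_fraction)) + 1L
  xa <- numeric(n_iter - keep_from + 1L)
  acc <- 0L
  for (i in seq_len(n_iter)) {
    # exact Gaussian conditional for the root mean
    mu <- mu_hat + sqrt(exp(lsig) / q11) * stats::rnorm(1)
    prop_ls <- lsig + proposal_scale * stats::rnorm(1)
    if (log(stats::runif(1)) < logpost(mu, prop_ls) - logpost(mu, lsig)) {
      lsig <- prop_ls; acc <- acc + 1L
    }
    # exact Gaussian conditional for the node state
    cm <- mu * (1 - s1) + wx
    draw <- cm + sqrt(exp(lsig) * s0) * stats::rnorm(1)
    if (i >= keep_from) xa[i - keep_from + 1L] <- draw
  }
  m <- length(xa)
  h1 <- mean(xa[seq_len(m %/% 2)]); h2 <- mean(xa[(m %/% 2 + 1L):m])
  psd <- stats::sd(xa)
  converged <- is.finite(psd) && (psd == 0 || abs(h1 - h2) < 0.1 * psd)
  structure(list(E_a = mean(xa), V_a = stats::var(xa) * (m - 1) / m,
                 method = "mcmc", n_samples = m,
                 acceptance = acc / n_iter, converged = converged),
            class = "ancestral_estimate")
}
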