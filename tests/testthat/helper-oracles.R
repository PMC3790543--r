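# Independent oracles used across the suite. These deliberately use
# brute-force algebra (dense inverses, explicit path walks, exhaustive grids)
# so they share no code with the implementation they check.

# covariance by explicit pairwise MRCA path walk: entry (i, j) is the summed
# length of edges common to the root->i and root->j paths
oracle_vcv <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  edge_of <- integer(max(tree$edge))
  edge_of[child] <- seq_along(child)
  path_edges <- function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root) {
      e <- edge_of[node]
      out <- c(out, e)
      node <- parent[e]
    }
    out
  }
  paths <- lapply(seq_len(ntip), path_edges)
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(i)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- V[j, i] <- sum(tree$edge.length[shared])
    }
  }
  V
}

# dense-inverse GLS: beta = (X' V^-1 X)^-1 X' V^-1 y
oracle_gls <- function(V, y, X) {
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# profiled MVN log-likelihood at a given lambda, by dense algebra
oracle_loglik <- function(V, x, lam) {
  W <- V * lam
  diag(W) <- diag(V)
  n <- length(x)
  Wi <- solve(W)
  one <- rep(1, n)
  mu <- sum(Wi %*% x) / sum(Wi)
  r <- x - mu
  s2 <- drop(t(r) %*% Wi %*% r) / n
  -0.5 * (n * log(2 * pi * s2) + as.numeric(determinant(W)$modulus) + n)
}

# exhaustive grid search of the same likelihood (ties toward lower lambda)
oracle_grid_lambda <- function(tree, x, step = 0.001) {
  V <- phylo_vcv(tree)
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(l) oracle_loglik(V, x, l), numeric(1))
  grid[which.max(ll)]
}

# non-ultrametric random tree for stress tests
random_rtree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}
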