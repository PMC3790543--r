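#' Sum of sister-clade differences of a binary trait
#'
#' The building block of the Fritz-Purvis D statistic. Nodal values are
#' computed tip-to-root by unweighted averaging of the two daughter values at
#' each internal node (branch lengths are ignored at this step); the statistic
#' is the sum over internal nodes of the absolute difference between the two
#' daughter values.
#'
#' @param tree a fully bifurcating `phylo` object (see [resolve_polytomies]).
#' @param x a 0/1 vector, named by tip label or in tip order.
#' @return the observed sum of sister-clade differences.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' sum_sister_differences(tr, c(A = 1, B = 1, C = 0, D = 0)) # 1: root only
#' sum_sister_differences(tr, c(A = 1, B = 0, C = 1, D = 0)) # 2
#' @export
sum_sister_differences <- function(tree, x) {
  x <- .check_binary(tree, x, require_both = FALSE)
  D <- .sister_diff_operator(tree)
  sum(abs(D %*% x))
}

# Linear operator of the sister-difference recursion. Because daughter
# averaging is linear, the value at any internal node is a fixed weighted sum
# of tip values; row k of the returned matrix maps tip values to
# (daughter1 - daughter2) at internal node k, so the D-statistic numerator for
# trait vector x is sum(abs(op %*% x)) and whole null distributions are a
# single matrix product.
.sister_diff_operator <- function(tree) {
  if (!ape::is.binary(tree))
    stop("the D statistic requires a binary tree; use resolve_polytomies()",
         call. = FALSE)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  W <- matrix(0, ntip + nnode, ntip) # node weight vectors over tips
  W[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  D <- matrix(0, nnode, ntip)
  parent <- tr$edge[, 1L]
  child <- tr$edge[, 2L]
  daughters <- split(child, parent)
  # postorder guarantees every daughter is visited before its parent
  for (p in unique(parent)) {
    ch <- daughters[[as.character(p)]]
    W[p, ] <- (W[ch[1L], ] + W[ch[2L], ]) / 2
    D[p - ntip, ] <- W[ch[1L], ] - W[ch[2L], ]
  }
  colnames(D) <- tr$tip.label
  D[, tree$tip.label, drop = FALSE]
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures phylogenetic dispersion of a binary trait by scaling the observed
#' sum of sister-clade differences ([sum_sister_differences]) between two
#' simulated expectations: D is approximately 1 when the trait is randomly
#' shuffled over the tips and approximately 0 when it arises by thresholding
#' Brownian motion on the tree. Values below 0 indicate extreme clumping.
#' Because D measures dispersion rather than concentration, results also carry
#' `one_minus_d` = 1 - D, which is on the same scale as Pagel's lambda
#' (larger = more signal) and is the quantity used for signal labelling.
#'
#' Both nulls condition on the observed prevalence: the permutation null
#' shuffles tip states, and the Brownian null simulates continuous Brownian
#' motion on the tree and marks the top k values as 1, where k is the observed
#' number of 1s (rank thresholding).
#'
#' @param tree a `phylo` object; must be binary unless `resolve = TRUE`.
#' @param x a 0/1 vector with both states present, named by tip label or in
#'   tip order.
#' @param n_perm number of replicates per null (at least 100).
#' @param seed integer seed recorded in the result; the same seed and inputs
#'   give an identical result.
#' @param resolve resolve polytomies to zero-length bifurcations first.
#' @return an object of class `"D_fit"`: a list with `d`, `one_minus_d`,
#'   `sum_d_obs`, mean null sums `mean_random`/`mean_brownian`, Monte-Carlo
#'   p-values `p_random` (fraction of permutation-null sums <= observed) and
#'   `p_brownian` (fraction of Brownian-null sums >= observed), `n_perm`,
#'   `seed`, and `n`.
#' @examples
#' tr <- simulate_tree(64, seed = 1)
#' x <- simulate_binary_threshold(tr, lambda = 1, prevalence = 0.5, seed = 2)
#' fit_D(tr, x, n_perm = 200, seed = 3)
#' @export
fit_D <- function(tree, x, n_perm = 1000, seed = NULL, resolve = FALSE) {
  validate_phylogeny(tree)
  if (resolve) tree <- resolve_polytomies(tree)
  x <- .check_binary(tree, x, require_both = TRUE)
  if (n_perm < 100)
    stop("n_perm must be at least 100", call. = FALSE)
  op <- .sister_diff_operator(tree)
  obs <- sum(abs(op %*% x))
  k <- sum(x)
  n <- length(x)

  .with_seed(seed, {
    perm <- replicate(n_perm, sample(x))              # n x n_perm
    sum_random <- colSums(abs(op %*% perm))
    V <- phylo_vcv(tree)
    L <- t(.psd_chol(V))
    z <- matrix(stats::rnorm(n * n_perm), n, n_perm)
    sims <- L %*% z
    bin <- apply(sims, 2L, function(v) {
      b <- numeric(n)
      b[order(v, decreasing = TRUE)[seq_len(k)]] <- 1
      b
    })
    sum_brownian <- colSums(abs(op %*% bin))
  })

  denom <- mean(sum_random) - mean(sum_brownian)
  if (abs(denom) < 1e-9)
    stop("degenerate nulls: permutation and Brownian expectations coincide",
         call. = FALSE)
  d <- (obs - mean(sum_brownian)) / denom
  out <- list(
    d = d,
    one_minus_d = 1 - d,
    sum_d_obs = obs,
    mean_random = mean(sum_random),
    mean_brownian = mean(sum_brownian),
    p_random = (1 + sum(sum_random <= obs)) / (n_perm + 1),
    p_brownian = (1 + sum(sum_brownian >= obs)) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = seed,
    n = n
  )
  class(out) <- "D_fit"
  out
}

#' @export
print.D_fit <- function(x, ...) {
  cat("Fritz-Purvis D\n")
  cat(sprintf("  D = %.4f   1 - D = %.4f   (n = %d, n_perm = %d)\n",
              x$d, x$one_minus_d, x$n, x$n_perm))
  cat(sprintf("  sum of sister differences: observed %.3f, random null %.3f, Brownian null %.3f\n",
              x$sum_d_obs, x$mean_random, x$mean_brownian))
  cat(sprintf("  P(random dispersion) = %.3g   P(Brownian clumping) = %.3g\n",
              x$p_random, x$p_brownian))
  invisible(x)
}

.check_binary <- function(tree, x, require_both = TRUE) {
  x <- .align_values(tree, x, "x")
  if (!all(x %in% c(0, 1)))
    stop("x must contain only 0/1 values", call. = FALSE)
  if (require_both && length(unique(x)) < 2L)
    stop("both states (0 and 1) must be present", call. = FALSE)
  x
}

# Cholesky-like factor tolerating zero eigenvalues (zero-length branches)
.psd_chol <- function(V) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(V, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(ev)))
}
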