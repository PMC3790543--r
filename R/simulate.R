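#' Simulate a pure-birth (Yule) tree scaled to unit depth
#'
#' Exponential waiting times between speciation events (via [ape::rphylo]
#' with zero extinction), then all branch lengths rescaled so the
#' root-to-tip depth is 1. Unit depth makes `lambda` and the Brownian rate
#' comparable across tree sizes: with `sigma2` = 1 every tip has unit
#' marginal variance.
#'
#' @param n_tips number of tips (at least 2).
#' @param seed integer seed; the same seed gives an identical tree.
#' @return an ultrametric binary `phylo` object with tips `t1..tn` and
#'   root-to-tip depth 1.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2)
    stop("n_tips must be at least 2", call. = FALSE)
  n_tips <- as.integer(n_tips)
  tree <- .with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate a continuous trait with lambda-scaled Brownian covariance
#'
#' One draw from the multivariate normal with mean `mu` and covariance
#' `sigma2 * V(lambda)`, where `V` is the tree's phylogenetic covariance and
#' `V(lambda)` scales its off-diagonals by `lambda` ([lambda_transform]).
#' `lambda` = 1 is Brownian motion; `lambda` = 0 gives independent tips with
#' variance `sigma2 *` root-to-tip depth.
#'
#' @param tree a `phylo` object.
#' @param lambda phylogenetic signal of the generating process, in `[0, 1]`.
#' @param sigma2 Brownian rate (trait-units squared per unit branch length).
#' @param mu ancestral mean (trait units).
#' @param seed integer seed.
#' @return named numeric vector of tip values in `tree$tip.label` order.
#' @export
simulate_continuous <- function(tree, lambda, sigma2 = 1, mu = 0, seed = NULL) {
  validate_phylogeny(tree)
  if (sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  V <- lambda_transform(phylo_vcv(tree), lambda)
  n <- nrow(V)
  if (sigma2 == 0)
    return(stats::setNames(rep(mu, n), tree$tip.label))
  U <- .psd_chol(sigma2 * V)
  z <- .with_seed(seed, stats::rnorm(n))
  stats::setNames(mu + drop(crossprod(U, z)), tree$tip.label)
}

#' Simulate a binary trait by thresholding Brownian motion
#'
#' Simulates a continuous trait ([simulate_continuous]) and marks the top
#' `floor(prevalence * n)` values as 1 (rank thresholding), so the number of
#' 1s is fixed exactly by `prevalence`.
#'
#' @param tree a `phylo` object.
#' @param lambda generating signal in `[0, 1]`.
#' @param prevalence fraction of tips in state 1; `prevalence * n` must be
#'   at least 1 and below `n`.
#' @param seed integer seed.
#' @return named 0/1 vector in tip order.
#' @export
simulate_binary_threshold <- function(tree, lambda, prevalence = 0.5, seed = NULL) {
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  k <- floor(prevalence * n)
  if (prevalence <= 0 || prevalence >= 1 || k < 1 || k >= n)
    stop("prevalence must leave at least one tip in each state", call. = FALSE)
  cont <- simulate_continuous(tree, lambda, sigma2 = 1, mu = 0, seed = seed)
  out <- stats::setNames(numeric(n), tree$tip.label)
  out[order(cont, decreasing = TRUE)[seq_len(k)]] <- 1
  out
}

#' Simulate an SEF/SRF pair with controlled cross-correlation
#'
#' Draws two independent vectors `u ~ MVN(0, V(lambda_sef))` and
#' `w ~ MVN(0, V(lambda_srf))` (unit marginal variance on a unit-depth tree)
#' and sets `sef = u`, `srf = rho * u + sqrt(1 - rho^2) * w`. The realized
#' Pearson correlation converges to `rho` as the number of tips grows. When
#' `lambda_sef != lambda_srf` and `rho != 0` the mixture slightly perturbs
#' the marginal signal of `srf`; see the package vignette.
#'
#' @param tree a `phylo` object (unit depth recommended; see [simulate_tree]).
#' @param lambda_sef,lambda_srf generating signal of each function, `[0, 1]`.
#' @param rho target cross-species correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return a list with named numeric vectors `sef` and `srf`.
#' @export
simulate_sef_srf <- function(tree, lambda_sef, lambda_srf, rho = 0, seed = NULL) {
  if (!is.numeric(rho) || abs(rho) > 1)
    stop("rho must lie in [-1, 1]", call. = FALSE)
  .with_seed(seed, {
    u <- simulate_continuous(tree, lambda_sef)
    w <- simulate_continuous(tree, lambda_srf)
  })
  list(sef = u, srf = stats::setNames(rho * u + sqrt(1 - rho^2) * w, names(u)))
}

#' Scenario archetypes: generate a full synthetic dataset
#'
#' Packages a simulated tree and trait table for one of the four scenario
#' quadrants. Archetypes use generating lambda 0.05 for "no signal" and 0.95
#' for "strong signal": quadrant A = neither SEF nor SRF patterned,
#' B = SEF only, C = SRF only, D = both. `rho` sets the SEF-SRF
#' cross-correlation (the maximum-concern configuration is quadrant D with
#' strongly negative `rho`).
#'
#' @param quadrant `"A"`, `"B"`, `"C"` or `"D"`.
#' @param n_tips number of species.
#' @param rho target SEF-SRF correlation; default 0 except nothing is implied
#'   by the quadrant itself.
#' @param seed integer seed.
#' @param lambda_low,lambda_high generating signal used for the low/high
#'   signal axes of the quadrant.
#' @return a list of class `"sef_scenario"` with `tree` (`phylo`), `data`
#'   (data.frame with `species`, `sef`, `srf`), and `spec` (the generating
#'   parameters).
#' @export
generate_scenario <- function(quadrant = c("A", "B", "C", "D"), n_tips = 128,
                              rho = 0, seed = NULL,
                              lambda_low = 0.05, lambda_high = 0.95) {
  quadrant <- match.arg(quadrant)
  lam <- switch(quadrant,
    A = c(lambda_low, lambda_low),
    B = c(lambda_high, lambda_low),
    C = c(lambda_low, lambda_high),
    D = c(lambda_high, lambda_high))
  tree <- simulate_tree(n_tips, seed = .stage_seed(seed, "simulate"))
  pair <- simulate_sef_srf(tree, lam[1L], lam[2L], rho = rho,
                           seed = .stage_seed(seed, "correlation"))
  out <- list(
    tree = tree,
    data = data.frame(species = tree$tip.label, sef = unname(pair$sef),
                      srf = unname(pair$srf)),
    spec = list(quadrant = quadrant, n_tips = as.integer(n_tips),
                lambda_sef = lam[1L], lambda_srf = lam[2L], rho = rho,
                seed = seed)
  )
  class(out) <- "sef_scenario"
  out
}

#' @export
print.sef_scenario <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic scenario: quadrant %s (lambda SEF = %.2f, SRF = %.2f, rho = %.2f, n = %d)\n",
              s$quadrant, s$lambda_sef, s$lambda_srf, s$rho, s$n_tips))
  invisible(x)
}

#' Write a scenario to disk as a fixture bundle
#'
#' Writes `tree.nwk` (Newick), `traits.csv` and `spec.json` into `dir`.
#' Output is byte-identical for identical seeds and parameters.
#'
#' @param scenario a `"sef_scenario"` object from [generate_scenario].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "sef_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(scenario$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(scenario$data, file.path(dir, "traits.csv"), row.names = FALSE)
  jsonlite::write_json(scenario$spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
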