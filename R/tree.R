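#' Read a phylogeny from a Newick string or file
#'
#' Parses a rooted phylogeny with branch lengths. Trees are represented as
#' [ape::phylo] objects throughout the package. Polytomies are preserved;
#' validation enforces unique tip labels, at least two tips, branch lengths
#' on every edge, and non-negative branch lengths.
#'
#' @param source a Newick string (must contain "(") or a path to a Newick file.
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(source) {
  text <- source
  if (length(text) != 1L || !is.character(text))
    stop("`source` must be a single Newick string or file path", call. = FALSE)
  if (!grepl("(", text, fixed = TRUE)) {
    if (!file.exists(text))
      stop("file not found: ", text, call. = FALSE)
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  .check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failure: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree))
    stop("Newick parse failure: string could not be read as a tree", call. = FALSE)
  validate_phylogeny(tree)
  tree
}

# cheap structural pre-check so malformed input errors name a character position
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick format error: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick format error: ", depth, " unclosed '(' at end of input (character ",
         nchar(text), ")", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick format error: missing terminating ';' at character ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Validate a phylogeny for use in sefrisk
#'
#' @param tree a `phylo` object.
#' @param require_binary require a fully bifurcating tree.
#' @return the tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree, require_binary = FALSE) {
  if (!inherits(tree, "phylo"))
    stop("not a 'phylo' object", call. = FALSE)
  tree$tip.label <- trimws(tree$tip.label)
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; they are required", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and non-missing", call. = FALSE)
  if (sum(tree$edge.length) <= 0)
    stop("tree has zero total branch length", call. = FALSE)
  if (require_binary && !ape::is.binary(tree))
    stop("tree must be fully bifurcating; resolve polytomies first ",
         "(see `resolve_polytomies()`)", call. = FALSE)
  invisible(tree)
}

#' Resolve polytomies to zero-length bifurcations
#'
#' Multifurcations are replaced by arbitrary bifurcations joined by
#' zero-length branches (via [ape::multi2di]). Required before computing the
#' D statistic, which is defined on binary trees.
#'
#' @param tree a `phylo` object.
#' @return a binary `phylo` object.
#' @export
resolve_polytomies <- function(tree) {
  validate_phylogeny(tree)
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the summed branch length shared by tips i and j on the
#' path from the root; the diagonal holds root-to-tip distances. Units are
#' the tree's branch-length units.
#'
#' @param tree a `phylo` object.
#' @return a symmetric positive semidefinite matrix with tip labels as
#'   dimnames, in `tree$tip.label` order.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda` = 1 returns the matrix untouched; `lambda` = 0 removes
#' all phylogenetic covariance (a star phylogeny with the original tip
#' depths).
#'
#' @param V a phylogenetic covariance matrix (see [phylo_vcv]).
#' @param lambda scaling factor, constrained to `[0, lambda_max]`.
#' @param lambda_max upper bound for `lambda`. The default 1 matches the
#'   usual interpretation (0 = no signal, 1 = Brownian motion); on
#'   non-ultrametric trees slightly larger values can keep the matrix
#'   positive semidefinite, so the bound is configurable.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda, lambda_max = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > lambda_max)
    stop("lambda must be a single value in [0, ", lambda_max, "]", call. = FALSE)
  d <- diag(V)
  W <- V * lambda
  diag(W) <- d
  W
}

#' Faith's phylogenetic diversity of a species subset
#'
#' Sum of branch lengths of the minimal subtree connecting the subset to the
#' root (root-inclusive, so a single species contributes its root-to-tip
#' distance).
#'
#' @param tree a `phylo` object.
#' @param subset character vector of tip labels (default: all tips).
#' @return total branch length (tree units).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' pd_total(tr, c("A", "B")) # 3: both tip edges plus their stem
#' pd_total(tr)              # 5: the whole tree
#' @export
pd_total <- function(tree, subset = tree$tip.label) {
  validate_phylogeny(tree)
  if (length(subset) == 0L)
    stop("subset must contain at least one species", call. = FALSE)
  subset <- unique(trimws(subset))
  unknown <- setdiff(subset, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  tipno <- match(subset, tree$tip.label)
  # walk each tip to the root, marking edges; sum marked edge lengths once
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  edge_of_child <- integer(max(tree$edge))
  edge_of_child[child] <- seq_along(child)
  root <- ape::Ntip(tree) + 1L
  used <- logical(nrow(tree$edge))
  for (tip in tipno) {
    node <- tip
    while (node != root) {
      e <- edge_of_child[node]
      if (used[e]) break # path above already marked
      used[e] <- TRUE
      node <- parent[e]
    }
  }
  sum(tree$edge.length[used])
}

# warn when lambda's standard interpretation is shaky (non-ultrametric tree)
.warn_if_not_ultrametric <- function(tree, tol = 0.01) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (max(depths) > 0 && (max(depths) - min(depths)) / max(depths) > tol)
    warning("tree is not ultrametric (tip depths differ by >1%); ",
            "Pagel's lambda assumes ultrametricity for its standard interpretation",
            call. = FALSE)
  invisible(NULL)
}
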