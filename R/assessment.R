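#' Full phylogenetic risk assessment of an ecosystem function
#'
#' The package's central fitting function. Given a phylogeny for the local
#' species pool and a species table carrying one SEF column and one SRF (or
#' SRF-proxy) column, it:
#'
#' 1. estimates phylogenetic signal in the SEF and the SRF — maximum-
#'    likelihood Pagel's lambda ([fit_lambda]) for continuous variables, the
#'    Fritz-Purvis D statistic reported as 1 - D ([fit_D]) for binary ones —
#'    and labels each ([label_signal]);
#' 2. classifies the system into the four-scenario quadrant matrix
#'    ([classify_quadrant]);
#' 3. assesses the SEF-SRF correlation both phylogenetically and
#'    nonphylogenetically ([assess_correlation]), including a quadratic-term
#'    screen;
#' 4. assigns an ordinal risk of function loss ([assess_risk]); and
#' 5. simulates the driver filter ([apply_filter]), summarising the SEF
#'    distribution before and after and the retained phylogenetic diversity.
#'
#' Optionally, when `traits` names functional effect-trait columns, the SEF is
#' modelled from them by PGLS with single-step backward elimination at
#' `alpha` ([sef_trait_model]).
#'
#' @param tree a `phylo` object, or a Newick string/path ([read_newick]).
#' @param data a data.frame with a `species` column (or row names) matching
#'   the tip labels, plus the columns named by `sef`, `srf` and `traits`.
#' @param sef name of the SEF column.
#' @param srf name of the SRF (or proxy) column.
#' @param srf_transform optional proxy transform applied to the SRF column
#'   before analysis: `"none"`, `"negate"`, `"log"` or `"neglog"` (e.g.
#'   negated log body mass as a hunting-tolerance proxy). See [apply_proxy]
#'   for product proxies.
#' @param traits optional character vector of effect-trait columns for the
#'   trait model.
#' @param quantile driver-filter quantile (default 0.5, an equal split).
#' @param n_perm permutation/simulation replicates for the D statistic.
#' @param seed root seed; stage seeds are derived from it and recorded.
#' @param cutpoints signal/correlation cutpoints, see [default_cutpoints].
#' @param alpha significance level for trait elimination.
#' @param prune drop tree tips (and table rows) outside the intersection of
#'   tree and table instead of erroring on mismatch.
#' @param polytomies `"error"` (default) or `"resolve"`: how [fit_D] should
#'   treat multifurcations.
#' @return an object of class `"risk_assessment"`: list with `sef_signal`,
#'   `srf_signal` (fit objects), `sef_label`, `srf_label`, `quadrant`,
#'   `correlation`, `risk`, `filter`, `trait_model` (or NULL), `n`, `seed`,
#'   `settings`.
#' @examples
#' sc <- generate_scenario("D", n_tips = 64, rho = -0.9, seed = 42)
#' ra <- risk_assessment(sc$tree, sc$data, sef = "sef", srf = "srf", seed = 1)
#' ra
#' @export
risk_assessment <- function(tree, data, sef, srf, srf_transform = "none",
                            traits = NULL, quantile = 0.5, n_perm = 1000,
                            seed = NULL, cutpoints = default_cutpoints(),
                            alpha = 0.05, prune = FALSE,
                            polytomies = c("error", "resolve")) {
  polytomies <- match.arg(polytomies)
  if (is.character(tree)) tree <- read_newick(tree)
  validate_phylogeny(tree)
  data <- as.data.frame(data)
  for (col in c(sef, srf, traits)) {
    if (!col %in% names(data))
      stop("column not found in table: ", col, call. = FALSE)
  }

  # reconcile tree tips and table species
  sp <- if ("species" %in% names(data)) trimws(as.character(data$species))
        else trimws(rownames(data))
  if (anyDuplicated(sp))
    stop("duplicate species in table: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "), call. = FALSE)
  only_tree <- setdiff(tree$tip.label, sp)
  only_table <- setdiff(sp, tree$tip.label)
  if (length(only_tree) || length(only_table)) {
    if (!prune)
      stop("tree/table mismatch (use prune = TRUE to intersect). ",
           "Tips without data: ", paste(only_tree, collapse = ", "),
           "; rows without tips: ", paste(only_table, collapse = ", "),
           call. = FALSE)
    common <- intersect(tree$tip.label, sp)
    if (length(common) < 5L)
      stop("fewer than 5 species shared between tree and table", call. = FALSE)
    tree <- ape::keep.tip(tree, common)
  }
  data <- .align_data(tree, data)

  sef_v <- stats::setNames(data[[sef]], rownames(data))
  srf_v <- stats::setNames(data[[srf]], rownames(data))
  if (!identical(srf_transform, "none"))
    srf_v <- apply_proxy(srf_v, srf_transform)

  seeds <- list(signal_sef = .stage_seed(seed, "signal_sef"),
                signal_srf = .stage_seed(seed, "signal_srf"))

  fit_signal <- function(v, stage_seed) {
    if (all(v %in% c(0, 1))) {
      fit <- fit_D(tree, v, n_perm = n_perm, seed = stage_seed,
                   resolve = polytomies == "resolve")
      list(fit = fit,
           label = label_signal(min(1, max(0, fit$one_minus_d)),
                                "one_minus_d", cutpoints))
    } else {
      fit <- fit_lambda(tree, v)
      list(fit = fit, label = label_signal(fit$lambda, "lambda", cutpoints))
    }
  }
  sef_sig <- fit_signal(sef_v, seeds$signal_sef)
  srf_sig <- fit_signal(srf_v, seeds$signal_srf)

  quadrant <- classify_quadrant(sef_sig$label, srf_sig$label)
  correlation <- assess_correlation(tree, sef_v, srf_v)
  risk <- assess_risk(quadrant, correlation, cutpoints)
  filter <- apply_filter(sef_v, srf_v, quantile = quantile, tree = tree)
  attr(filter, "sef_values") <- sef_v

  trait_model <- NULL
  if (!is.null(traits))
    trait_model <- sef_trait_model(tree, data, sef = sef, traits = traits,
                                   alpha = alpha)

  out <- list(
    sef_signal = sef_sig$fit, srf_signal = srf_sig$fit,
    sef_label = sef_sig$label, srf_label = srf_sig$label,
    quadrant = quadrant,
    correlation = correlation,
    risk = risk,
    filter = filter,
    trait_model = trait_model,
    n = ape::Ntip(tree),
    seed = seed,
    settings = list(sef = sef, srf = srf, srf_transform = srf_transform,
                    quantile = quantile, n_perm = n_perm, alpha = alpha,
                    prune = prune, polytomies = polytomies,
                    cutpoints = cutpoints, stage_seeds = seeds)
  )
  class(out) <- "risk_assessment"
  out
}

#' @export
print.risk_assessment <- function(x, ...) {
  fmt_label <- function(lab) {
    stat <- if (lab$kind == "lambda") "lambda" else "1 - D"
    sprintf("%s (%s = %.2f)", tools::toTitleCase(as.character(lab$level)),
            stat, lab$value)
  }
  cat("Ecosystem-function risk assessment (", x$n, " species)\n", sep = "")
  cat("  SEF signal:", fmt_label(x$sef_label), "\n")
  cat("  SRF signal:", fmt_label(x$srf_label), "\n")
  cat("  Scenario quadrant:", x$quadrant, "\n")
  cat(sprintf("  Correlation: phylogenetic r2 = %.3f, nonphylogenetic r2 = %.3f, sign %+d\n",
              x$correlation$phylo_r2, x$correlation$nonphylo_r2,
              x$correlation$sign))
  print(x$risk)
  invisible(x)
}

#' @export
summary.risk_assessment <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$filter)
  if (!is.null(object$trait_model)) {
    cat("\nTrait model for the SEF:\n")
    print(object$trait_model)
  }
  invisible(object)
}

#' Model an SEF from functional effect traits by PGLS
#'
#' Fits the SEF on all named traits by PGLS with estimated lambda, then
#' performs a single-step backward elimination: traits whose coefficients are
#' nonsignificant at `alpha` in the full model are dropped together and the
#' model refitted (no iterative search). Both fits are returned.
#'
#' @param tree a `phylo` object.
#' @param data species x column data.frame (see [pgls]).
#' @param sef name of the SEF column.
#' @param traits character vector of effect-trait columns.
#' @param alpha elimination threshold on the full-model p-values.
#' @return an object of class `"trait_model"`: list with `full`, `reduced`
#'   (`pgls_fit` objects; `reduced` may equal `full`), `dropped` (character),
#'   `alpha`.
#' @export
sef_trait_model <- function(tree, data, sef, traits, alpha = 0.05) {
  data <- .align_data(tree, data)
  y <- stats::setNames(data[[sef]], rownames(data))
  X <- as.matrix(data[, traits, drop = FALSE])
  full <- fit_pgls(tree, y, X, lambda = "estimate")
  pv <- full$p_values[traits]
  drop_these <- names(pv)[pv > alpha]
  reduced <- full
  if (length(drop_these) && length(drop_these) < length(traits)) {
    keep <- setdiff(traits, drop_these)
    reduced <- fit_pgls(tree, y, X[, keep, drop = FALSE], lambda = "estimate")
  }
  out <- list(full = full, reduced = reduced, dropped = drop_these,
              alpha = alpha)
  class(out) <- "trait_model"
  out
}

#' @export
print.trait_model <- function(x, ...) {
  if (length(x$dropped))
    cat("Traits dropped at alpha =", x$alpha, ":",
        paste(x$dropped, collapse = ", "), "\n")
  print(x$reduced)
  invisible(x)
}
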