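#' Default cutpoints for signal labels and correlation strength
#'
#' Signal labels for Pagel's lambda use four bands (none < 0.15 <= weak <
#' 0.30 <= moderate < 0.60 <= strong); labels for 1 - D use three (none <
#' 0.20 <= moderate < 0.60 <= strong). Correlation strength on r-squared is
#' negligible below 0.01, weak below 0.30, strong at or above 0.30. All
#' cutpoints can be overridden by passing a modified copy of this list.
#'
#' @return a named list of cutpoint vectors.
#' @export
default_cutpoints <- function() {
  list(
    lambda = c(weak = 0.15, moderate = 0.30, strong = 0.60),
    one_minus_d = c(moderate = 0.20, strong = 0.60),
    correlation = c(weak = 0.01, strong = 0.30)
  )
}

#' Label the strength of phylogenetic signal
#'
#' Maps a signal statistic to an ordinal label. For `kind = "lambda"` the
#' bands are none/weak/moderate/strong; for `kind = "one_minus_d"` (1 - D,
#' already on the same 0-1 scale as lambda) they are none/moderate/strong.
#'
#' @param value signal statistic in `[0, 1]`.
#' @param kind `"lambda"` or `"one_minus_d"`.
#' @param cutpoints see [default_cutpoints].
#' @return an object of class `"signal_label"`: list with `level` (factor
#'   ordered none < weak < moderate < strong), `kind`, `value`.
#' @examples
#' label_signal(0.32, "lambda")      # moderate
#' label_signal(0.13, "one_minus_d") # none
#' @export
label_signal <- function(value, kind = c("lambda", "one_minus_d"),
                         cutpoints = default_cutpoints()) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    stop("signal value must be a single number in [0, 1]", call. = FALSE)
  cuts <- cutpoints[[kind]]
  levels_all <- c("none", "weak", "moderate", "strong")
  i <- findInterval(value, cuts)
  lev <- if (i == 0L) "none" else names(cuts)[i]
  out <- list(level = factor(lev, levels = levels_all, ordered = TRUE),
              kind = kind, value = value)
  class(out) <- "signal_label"
  out
}

#' @export
print.signal_label <- function(x, ...) {
  stat <- if (x$kind == "lambda") "lambda" else "1 - D"
  cat(sprintf("%s signal (%s = %.2f)\n",
              tools::toTitleCase(as.character(x$level)), stat, x$value))
  invisible(x)
}

# dichotomize a label for the quadrant matrix: moderate counts as patterned
.is_high_signal <- function(label) {
  as.character(label$level) %in% c("moderate", "strong")
}

#' Classify a system into the four-scenario quadrant matrix
#'
#' Quadrants are defined by presence of phylogenetic signal in the SEF and
#' the SRF: A = neither patterned, B = SEF only, C = SRF only, D = both.
#' Labels none/weak count as unpatterned; moderate/strong as patterned.
#'
#' @param sef_label,srf_label `"signal_label"` objects (see [label_signal]).
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
classify_quadrant <- function(sef_label, srf_label) {
  stopifnot(inherits(sef_label, "signal_label"), inherits(srf_label, "signal_label"))
  sef_high <- .is_high_signal(sef_label)
  srf_high <- .is_high_signal(srf_label)
  if (!sef_high && !srf_high) "A"
  else if (sef_high && !srf_high) "B"
  else if (!sef_high && srf_high) "C"
  else "D"
}

#' Dual (phylogenetic and nonphylogenetic) SEF-SRF correlation
#'
#' Regresses the SEF on the SRF twice: by PGLS with jointly estimated lambda
#' (phylogenetic arm) and by OLS (nonphylogenetic arm). The slope sign comes
#' from the OLS arm; a negative sign means the most important species are the
#' least tolerant. A quadratic term is screened in the OLS arm to check that
#' the linear summary is not hiding curvature.
#'
#' @param tree a `phylo` object.
#' @param sef,srf aligned numeric vectors (named by tip or in tip order).
#' @return an object of class `"correlation_assessment"`: list with
#'   `phylo_r2`, `nonphylo_r2`, `sign` (-1/0/+1), `slope_ols`, `quadratic_p`,
#'   `lambda_used`, `sign_consistent` (slope signs agree between arms).
#' @export
assess_correlation <- function(tree, sef, srf) {
  validate_phylogeny(tree)
  sef <- .align_values(tree, sef, "sef")
  srf <- .align_values(tree, srf, "srf")
  if (length(sef) < 5L)
    stop("at least 5 species are required", call. = FALSE)
  if (stats::sd(sef) == 0 || stats::sd(srf) == 0)
    stop("sef and srf must be non-constant", call. = FALSE)
  pfit <- fit_pgls(tree, sef, cbind(srf = srf), lambda = "estimate")
  ofit <- fit_ols(sef, cbind(srf = srf))
  slope <- unname(ofit$coefficients["srf"])
  out <- list(
    phylo_r2 = pfit$r2,
    nonphylo_r2 = ofit$r2,
    sign = sign(slope),
    slope_ols = slope,
    # a binary SRF makes the squared term collinear with the linear one
    quadratic_p = tryCatch(quadratic_check(tree, sef, srf, phylogenetic = FALSE),
                           error = function(e) NA_real_),
    lambda_used = pfit$lambda,
    sign_consistent = sign(slope) == sign(unname(pfit$coefficients["srf"]))
  )
  class(out) <- "correlation_assessment"
  out
}

#' @export
print.correlation_assessment <- function(x, ...) {
  cat(sprintf("SEF-SRF correlation: phylogenetic r2 = %.3f (lambda = %.2f), nonphylogenetic r2 = %.3f\n",
              x$phylo_r2, x$lambda_used, x$nonphylo_r2))
  cat(sprintf("  OLS slope sign: %+d   quadratic-term P = %.3g%s\n",
              x$sign, x$quadratic_p,
              if (!x$sign_consistent) "   [warning: slope signs disagree between arms]" else ""))
  invisible(x)
}

#' Ordinal risk of function loss
#'
#' Combines the quadrant with the dual correlation into an ordinal risk of
#' losing the specified function under the specified driver. The rule, with
#' strength = max of the two r-squared values and default cutpoints 0.01 /
#' 0.30:
#'
#' * strength below 0.01: `very_low` (no SEF-SRF association; the filter
#'   takes an effectively random SEF sample).
#' * negative correlation, strength in \[0.01, 0.30): `low`.
#' * negative correlation, strength at or above 0.30: `high`; if the system is
#'   additionally in quadrant D the `maximum_concern` flag is set (function
#'   loss plus loss of the clades that carried it, with no independent
#'   backup).
#' * non-negative correlation at or above 0.01: `very_low`, with a note that
#'   the function is concentrated in tolerant species; the framework's risk
#'   logic is developed for the negative case.
#'
#' @param quadrant `"A"`..`"D"` from [classify_quadrant].
#' @param correlation a `"correlation_assessment"` (or a list with
#'   `phylo_r2`, `nonphylo_r2`, `sign`).
#' @param cutpoints see [default_cutpoints].
#' @return an object of class `"risk_level"`: list with `risk` (ordered
#'   factor very_low < low < high < maximum), `maximum_concern` (flag),
#'   `strength`, `note`.
#' @export
assess_risk <- function(quadrant, correlation, cutpoints = default_cutpoints()) {
  stopifnot(quadrant %in% c("A", "B", "C", "D"))
  strength <- max(correlation$phylo_r2, correlation$nonphylo_r2)
  cuts <- cutpoints$correlation
  note <- NULL
  maximum_concern <- FALSE
  if (strength < cuts[["weak"]]) {
    risk <- "very_low"
  } else if (correlation$sign >= 0) {
    risk <- "very_low"
    note <- paste("SEF and SRF are positively associated: the function is",
                  "concentrated in species tolerant of this driver. Risk of",
                  "loss is assessed as very low for this driver; other",
                  "drivers may differ.")
  } else if (strength < cuts[["strong"]]) {
    risk <- "low"
  } else {
    risk <- "high"
    if (quadrant == "D") {
      maximum_concern <- TRUE
      note <- paste("Strong negative SEF-SRF correlation with both functions",
                    "phylogenetically patterned: loss of function would be",
                    "accompanied by loss of the clades providing it, leaving",
                    "no independent backup (maximum concern).")
    }
  }
  out <- list(
    risk = factor(risk, levels = c("very_low", "low", "high", "maximum"),
                  ordered = TRUE),
    maximum_concern = maximum_concern,
    strength = strength,
    note = note
  )
  class(out) <- "risk_level"
  out
}

#' @export
print.risk_level <- function(x, ...) {
  cat(sprintf("Risk of function loss: %s%s (max r2 = %.3f)\n",
              gsub("_", " ", as.character(x$risk)),
              if (x$maximum_concern) " [maximum concern]" else "", x$strength))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Simulate a driver filter on the species pool
#'
#' Removes the species least able to persist: survivors are the species whose
#' SRF ranks in the top `ceiling(n * (1 - quantile))`, with all species tied
#' at the cut-off value retained (the tie count is reported). Summaries of
#' the SEF distribution before and after the filter, and the fraction of the
#' tree's evolutionary history (root-inclusive Faith PD, [pd_total]) retained
#' by the survivors, quantify the ecosystem-level consequence.
#'
#' @param sef,srf aligned named numeric vectors.
#' @param quantile fraction of the pool removed from below, in `[0, 1)`;
#'   0.5 reproduces an equal split into more- and less-tolerant halves.
#' @param tree a `phylo` object covering the species.
#' @return an object of class `"filter_result"`: list with `survivors`
#'   (character), `sef_before`/`sef_after` (mean, sd, min, max, n),
#'   `pd_retained_fraction`, `quantile_used`, `srf_threshold`, `n_ties`.
#' @examples
#' tr <- simulate_tree(8, seed = 1)
#' sef <- stats::setNames(8:1, tr$tip.label)
#' srf <- stats::setNames(1:8, tr$tip.label)
#' apply_filter(sef, srf, quantile = 0.5, tree = tr)
#' @export
apply_filter <- function(sef, srf, quantile = 0.5, tree = NULL) {
  if (!is.numeric(quantile) || length(quantile) != 1L || quantile < 0 ||
      quantile >= 1)
    stop("quantile must lie in [0, 1)", call. = FALSE)
  if (length(sef) != length(srf))
    stop("sef and srf must have the same length", call. = FALSE)
  if (!is.null(names(sef)) && !is.null(names(srf)) &&
      !identical(names(sef), names(srf)))
    srf <- srf[names(sef)]
  n <- length(sef)
  k <- ceiling(n * (1 - quantile))
  threshold <- sort(srf, decreasing = TRUE)[k]
  alive <- srf >= threshold
  if (!any(alive)) stop("filter removed every species", call. = FALSE)
  n_ties <- sum(srf == threshold)
  summ <- function(v) c(mean = mean(v), sd = stats::sd(v), min = min(v),
                        max = max(v), n = length(v))
  pdf_frac <- NA_real_
  if (!is.null(tree)) {
    nm <- names(sef)
    if (is.null(nm)) {
      validate_phylogeny(tree)
      nm <- tree$tip.label
      if (length(nm) != n)
        stop("unnamed sef/srf cannot be matched to the tree", call. = FALSE)
    }
    pdf_frac <- pd_total(tree, nm[alive]) / pd_total(tree)
  }
  out <- list(
    survivors = if (is.null(names(sef))) which(alive) else names(sef)[alive],
    sef_before = summ(sef),
    sef_after = summ(sef[alive]),
    pd_retained_fraction = pdf_frac,
    quantile_used = quantile,
    srf_threshold = unname(threshold),
    n_ties = n_ties
  )
  class(out) <- "filter_result"
  out
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("Driver filter at SRF quantile %.2f: %d of %d species persist\n",
              x$quantile_used, x$sef_after[["n"]], x$sef_before[["n"]]))
  cat(sprintf("  SEF before: mean %.3f (sd %.3f, range %.3f..%.3f)\n",
              x$sef_before[["mean"]], x$sef_before[["sd"]],
              x$sef_before[["min"]], x$sef_before[["max"]]))
  cat(sprintf("  SEF after : mean %.3f (sd %.3f, range %.3f..%.3f)\n",
              x$sef_after[["mean"]], x$sef_after[["sd"]],
              x$sef_after[["min"]], x$sef_after[["max"]]))
  if (!is.na(x$pd_retained_fraction))
    cat(sprintf("  phylogenetic diversity retained: %.1f%%\n",
                100 * x$pd_retained_fraction))
  invisible(x)
}
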