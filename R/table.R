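#' Load a species trait table from CSV
#'
#' Reads a CSV with a header and a species identifier column, validates it
#' (unique species, numeric role columns), and applies an optional SRF-proxy
#' transform. Role columns are checked to exist; the transformed SRF is added
#' as a new column `<srf>_proxy` with its provenance recorded in the
#' `"proxy"` attribute.
#'
#' @param path CSV file path.
#' @param sef,srf names of the SEF and SRF columns (optional; validated when
#'   given).
#' @param srf_transform proxy transform for the SRF column: `"none"`,
#'   `"negate"`, `"log"`, `"neglog"`, or `"product:colA,colB"` (product of
#'   the named columns).
#' @param species_col name of the species identifier column.
#' @return a data.frame with a `species` column, checked and transformed.
#' @export
load_table <- function(path, sef = NULL, srf = NULL, srf_transform = "none",
                       species_col = "species") {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!species_col %in% names(tab))
    stop("species column '", species_col, "' missing from ", path, call. = FALSE)
  tab$species <- trimws(as.character(tab[[species_col]]))
  if (!identical(species_col, "species")) tab[[species_col]] <- NULL
  dup <- unique(tab$species[duplicated(tab$species)])
  if (length(dup))
    stop("duplicate species row(s): ", paste(dup, collapse = ", "), call. = FALSE)
  for (col in c(sef, srf)) {
    if (!col %in% names(tab))
      stop("role column not found: ", col, call. = FALSE)
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "', row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyNA(v))
      stop("missing value in column '", col, "', row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    tab[[col]] <- v
  }
  if (!identical(srf_transform, "none")) {
    if (is.null(srf)) stop("srf_transform given without an srf column", call. = FALSE)
    if (startsWith(srf_transform, "product:")) {
      cols <- strsplit(sub("^product:", "", srf_transform), ",")[[1]]
      tab[[paste0(srf, "_proxy")]] <- apply_proxy(tab, srf_transform, cols = cols)
    } else {
      tab[[paste0(srf, "_proxy")]] <- apply_proxy(tab[[srf]], srf_transform)
    }
    attr(tab, "proxy") <- list(column = srf, transform = srf_transform)
  }
  tab
}

#' SRF-proxy transforms
#'
#' Converts a measurable stand-in into an SRF on the "high = tolerant"
#' convention. `"negate"` flips sign; `"log"` takes natural logs;
#' `"neglog"` is `-log(x)` (e.g. negated log body mass as a hunting-tolerance
#' proxy: smaller species tolerate hunting better); `"product:colA,colB"`
#' multiplies the named columns of a data.frame (e.g. log seed mass times a
#' seed shape measure as a seed-bank persistence proxy).
#'
#' @param x numeric vector, or a data.frame for the product transform.
#' @param transform one of `"none"`, `"negate"`, `"log"`, `"neglog"`,
#'   `"product:..."`.
#' @param cols columns for the product transform (parsed from `transform`
#'   when omitted).
#' @return transformed numeric vector with a `"proxy"` attribute recording
#'   the transform.
#' @export
apply_proxy <- function(x, transform, cols = NULL) {
  if (startsWith(transform, "product:") || identical(transform, "product")) {
    if (is.null(cols))
      cols <- strsplit(sub("^product:", "", transform), ",")[[1]]
    cols <- trimws(cols)
    if (!is.data.frame(x))
      stop("product transform needs the full table", call. = FALSE)
    missing <- setdiff(cols, names(x))
    if (length(missing))
      stop("product transform: column(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    out <- Reduce(`*`, lapply(cols, function(cl) as.numeric(x[[cl]])))
  } else {
    out <- switch(transform,
      none = x,
      negate = -x,
      log = {
        if (any(x <= 0)) stop("log transform needs positive values", call. = FALSE)
        log(x)
      },
      neglog = {
        if (any(x <= 0)) stop("neglog transform needs positive values", call. = FALSE)
        -log(x)
      },
      stop("unknown srf transform: ", transform, call. = FALSE))
    if (!is.null(names(x))) names(out) <- names(x)
  }
  attr(out, "proxy") <- transform
  out
}

#' Serialize a risk assessment to report files
#'
#' Writes `report.json` (all statistics, labels, seeds and cutpoints),
#' `summary.txt` (the printed summary), and `sef_histogram.csv` (shared bin
#' edges with before/after counts, mirroring "SEF before filter" / "SEF after
#' filter" panels) into `dir`.
#'
#' @param assessment a `"risk_assessment"` object.
#' @param dir output directory (created if needed).
#' @param bins number of histogram bins.
#' @return invisibly, the paths written.
#' @export
write_report <- function(assessment, dir, bins = 12) {
  stopifnot(inherits(assessment, "risk_assessment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "summary.txt")
  hist_path <- file.path(dir, "sef_histogram.csv")

  jsonlite::write_json(as_report_list(assessment), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  writeLines(utils::capture.output(summary(assessment)), txt_path)
  write_sef_histogram(assessment, hist_path, bins = bins)
  invisible(c(json = json_path, summary = txt_path, histogram = hist_path))
}

#' Histogram data for the before/after SEF panels
#'
#' @param assessment a `"risk_assessment"` object (its filter component
#'   carries only summaries, so the underlying SEF values are recovered from
#'   the filter's survivor set and summary bounds via the stored vectors).
#' @param path output CSV path.
#' @param bins number of bins spanning the pre-filter SEF range.
#' @return invisibly, the data.frame written (`bin_lower`, `bin_upper`,
#'   `count_before`, `count_after`).
#' @export
write_sef_histogram <- function(assessment, path, bins = 12) {
  f <- assessment$filter
  sef <- attr(f, "sef_values")
  survivors <- f$survivors
  if (is.null(sef))
    stop("assessment does not carry SEF values", call. = FALSE)
  breaks <- seq(f$sef_before[["min"]], f$sef_before[["max"]],
                length.out = bins + 1L)
  before <- graphics::hist(sef, breaks = breaks, plot = FALSE)$counts
  after <- graphics::hist(sef[names(sef) %in% survivors], breaks = breaks,
                          plot = FALSE)$counts
  out <- data.frame(bin_lower = breaks[-length(breaks)],
                    bin_upper = breaks[-1L],
                    count_before = before, count_after = after)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

# flatten an assessment into plain lists for JSON
as_report_list <- function(x) {
  lab <- function(l) list(level = as.character(l$level), kind = l$kind,
                          value = l$value)
  sig <- function(s) {
    if (inherits(s, "lambda_fit"))
      list(statistic = "lambda", lambda = s$lambda, sigma2 = s$sigma2,
           mu = s$mu, loglik = s$loglik, p_vs_zero = s$p_vs_zero,
           p_vs_one = s$p_vs_one, n = s$n,
           unidentifiable = isTRUE(s$unidentifiable))
    else
      list(statistic = "D", d = s$d, one_minus_d = s$one_minus_d,
           sum_d_obs = s$sum_d_obs, p_random = s$p_random,
           p_brownian = s$p_brownian, n_perm = s$n_perm, seed = s$seed,
           n = s$n)
  }
  tm <- NULL
  if (!is.null(x$trait_model)) {
    r <- x$trait_model$reduced
    tm <- list(predictors = r$predictor_names, r2 = r$r2, lambda = r$lambda,
               coefficients = as.list(r$coefficients),
               p_values = as.list(r$p_values),
               dropped = x$trait_model$dropped, alpha = x$trait_model$alpha)
  }
  list(
    n_species = x$n,
    sef_signal = sig(x$sef_signal),
    srf_signal = sig(x$srf_signal),
    sef_label = lab(x$sef_label),
    srf_label = lab(x$srf_label),
    quadrant = x$quadrant,
    correlation = list(phylo_r2 = x$correlation$phylo_r2,
                       nonphylo_r2 = x$correlation$nonphylo_r2,
                       sign = x$correlation$sign,
                       slope_ols = x$correlation$slope_ols,
                       quadratic_p = x$correlation$quadratic_p,
                       lambda_used = x$correlation$lambda_used),
    risk = list(level = as.character(x$risk$risk),
                maximum_concern = x$risk$maximum_concern,
                strength = x$risk$strength, note = x$risk$note),
    filter = list(survivors = x$filter$survivors,
                  sef_before = as.list(x$filter$sef_before),
                  sef_after = as.list(x$filter$sef_after),
                  pd_retained_fraction = x$filter$pd_retained_fraction,
                  quantile_used = x$filter$quantile_used,
                  n_ties = x$filter$n_ties),
    seed = x$seed,
    settings = x$settings
  )
}
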