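#' Phylogenetic generalized least squares regression
#'
#' Fits a linear model whose residual covariance is proportional to the
#' lambda-scaled phylogenetic covariance matrix `V(lambda)`: coefficients are
#' `(X' V(lambda)^-1 X)^-1 X' V(lambda)^-1 y`. `lambda` can be fixed (0 gives
#' ordinary least squares on an ultrametric tree) or estimated by maximum
#' likelihood jointly with the coefficients. `r2` is computed on the
#' whitened scale (data premultiplied by `V(lambda)^-1/2`) against the
#' whitened intercept-only model, so it reduces to the usual R-squared at
#' `lambda` = 0; it is unadjusted.
#'
#' @param formula model formula; variables are looked up in `data`.
#' @param data a data.frame whose rows are species. Row names, or a `species`
#'   column, must match the tree's tip labels.
#' @param tree a `phylo` object.
#' @param lambda either a fixed value in `[0, 1]` or `"estimate"` (the
#'   default) for joint ML estimation.
#' @return an object of class `"pgls_fit"` with components `coefficients`,
#'   `std_errors`, `t_stats`, `p_values`, `lambda`, `lambda_mode`, `r2`,
#'   `loglik`, `sigma2`, `n`, `df_residual`, `fitted`, `residuals` (response
#'   scale), `predictor_names`, `formula`.
#' @examples
#' tr <- simulate_tree(32, seed = 1)
#' d <- data.frame(x = simulate_continuous(tr, 1, seed = 2))
#' d$y <- 2 * d$x + 1
#' pgls(y ~ x, d, tr, lambda = "estimate")
#' @export
pgls <- function(formula, data, tree, lambda = "estimate") {
  validate_phylogeny(tree)
  data <- .align_data(tree, data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  keep <- stats::complete.cases(cbind(y, X))
  if (!all(keep)) {
    message("dropping ", sum(!keep), " species with missing values")
    tree <- ape::keep.tip(tree, tree$tip.label[keep])
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
  }
  fit <- fit_pgls(tree, y, X, lambda = lambda, .has_intercept_col = TRUE)
  fit$formula <- formula
  fit
}

#' Phylogenetic GLS with explicit response and design matrix
#'
#' Matrix-interface workhorse behind [pgls]. An intercept column is prepended
#' unless `X` already carries one.
#'
#' @param tree a `phylo` object.
#' @param y numeric response vector aligned to `tree$tip.label` (or named).
#' @param X numeric predictor matrix (or vector) aligned likewise.
#' @param lambda fixed value in `[0, 1]` or `"estimate"`.
#' @param .has_intercept_col internal: `X` already contains the intercept.
#' @return a `"pgls_fit"` object; see [pgls].
#' @export
fit_pgls <- function(tree, y, X, lambda = "estimate", .has_intercept_col = FALSE) {
  validate_phylogeny(tree)
  y <- .align_values(tree, y, "y")
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (nrow(X) != n)
    stop("X has ", nrow(X), " rows but the tree has ", n, " tips", call. = FALSE)
  if (!.has_intercept_col || !any(apply(X, 2L, function(c) all(c == 1)))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  p <- ncol(X)
  if (n < p + 2L)
    stop("need at least p + 2 observations (n = ", n, ", p = ", p, ")", call. = FALSE)
  if (qr(X)$rank < p)
    stop("design matrix is rank deficient (collinear predictors)", call. = FALSE)

  V <- phylo_vcv(tree)
  prep <- .gls_prepare(V, y, X)

  estimate <- identical(lambda, "estimate")
  if (estimate) {
    ml <- .lambda_mle(prep)
    lam <- ml$lambda
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
      stop("lambda must be \"estimate\" or a single value in [0, 1]", call. = FALSE)
    lam <- lambda
  }
  ev <- .gls_eval(prep, lam)
  if (!is.finite(ev$loglik))
    stop("V(lambda) is not positive definite at lambda = ", lam, call. = FALSE)
  if (ev$rank < p)
    stop("whitened design matrix is rank deficient", call. = FALSE)

  beta <- ev$beta
  df_res <- n - p
  sigma2_unbiased <- ev$rss / df_res
  XtX_inv <- chol2inv(qr.R(qr(ev$Xw)))
  se <- sqrt(sigma2_unbiased * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df_res)

  # null (whitened intercept-only) model at the same lambda for r2
  ev0 <- .gls_eval(.gls_prepare(V, y, matrix(1, n, 1)), lam)
  tss <- ev0$rss
  r2 <- if (tss > 0) max(0, min(1, 1 - ev$rss / tss)) else NA_real_

  fitted <- drop(X %*% beta)
  out <- list(
    coefficients = stats::setNames(beta, colnames(X)),
    std_errors = stats::setNames(se, colnames(X)),
    t_stats = stats::setNames(tval, colnames(X)),
    p_values = stats::setNames(pval, colnames(X)),
    lambda = lam,
    lambda_mode = if (estimate) "estimated" else "fixed",
    r2 = r2,
    loglik = ev$loglik,
    sigma2 = ev$sigma2,
    n = n,
    df_residual = df_res,
    fitted = stats::setNames(fitted, tree$tip.label),
    residuals = stats::setNames(y - fitted, tree$tip.label),
    predictor_names = setdiff(colnames(X), "(Intercept)")
  )
  class(out) <- "pgls_fit"
  out
}

#' Ordinary least squares with the same output contract as [fit_pgls]
#'
#' The nonphylogenetic arm of the dual-correlation assessment: identical to
#' [fit_pgls] with an identity residual covariance (`lambda` = 0 on a star
#' phylogeny).
#'
#' @param y numeric response vector.
#' @param X numeric predictor matrix or vector.
#' @return a `"pgls_fit"` object with `lambda = 0`, `lambda_mode = "ols"`.
#' @export
fit_ols <- function(y, X) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  star <- ape::stree(n, type = "star")
  star$tip.label <- if (!is.null(names(y))) names(y) else paste0("s", seq_len(n))
  names(y) <- star$tip.label
  star$edge.length <- rep(1, nrow(star$edge))
  fit <- fit_pgls(star, y, X, lambda = 0)
  fit$lambda_mode <- "ols"
  fit
}

#' Test for curvature in the SEF-SRF relationship
#'
#' Regresses `y` on `x` and centred `x^2` and returns the p-value of the
#' squared term, either phylogenetically (PGLS with estimated lambda) or
#' nonphylogenetically (OLS). A nonsignificant result supports treating the
#' relationship as linear.
#'
#' @param tree a `phylo` object (ignored when `phylogenetic = FALSE`).
#' @param y response vector.
#' @param x predictor vector.
#' @param phylogenetic use PGLS (`TRUE`) or OLS (`FALSE`).
#' @return the squared-term p-value.
#' @export
quadratic_check <- function(tree, y, x, phylogenetic = FALSE) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("y and x must be non-constant", call. = FALSE)
  xc <- x - mean(x)
  X <- cbind(x = xc, x2 = xc^2)
  fit <- if (phylogenetic) fit_pgls(tree, y, X, lambda = "estimate")
         else fit_ols(y, X)
  unname(fit$p_values["x2"])
}

#' @export
print.pgls_fit <- function(x, ...) {
  kind <- switch(x$lambda_mode, ols = "Ordinary least squares",
                 "Phylogenetic GLS")
  cat(kind, "\n")
  if (x$lambda_mode != "ols")
    cat(sprintf("  lambda = %.4f (%s)\n", x$lambda, x$lambda_mode))
  cat(sprintf("  n = %d   r2 = %.4f   logLik = %.3f\n", x$n, x$r2, x$loglik))
  tab <- data.frame(Estimate = x$coefficients, `Std. Error` = x$std_errors,
                    `t value` = x$t_stats, `Pr(>|t|)` = signif(x$p_values, 3),
                    check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
summary.pgls_fit <- function(object, ...) object

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted

#' @export
logLik.pgls_fit <- function(object, ...) {
  df <- length(object$coefficients) + 1L + (object$lambda_mode == "estimated")
  structure(object$loglik, df = df, nobs = object$n, class = "logLik")
}

#' @export
predict.pgls_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- as.matrix(newdata[, object$predictor_names, drop = FALSE])
  drop(cbind(1, X) %*% object$coefficients)
}

# align a species x column data.frame to tip order via row names or a
# `species` column
.align_data <- function(tree, data) {
  data <- as.data.frame(data)
  if ("species" %in% names(data)) {
    rownames(data) <- trimws(as.character(data$species))
    data$species <- NULL
  }
  rn <- trimws(rownames(data))
  if (is.null(rownames(data)) || all(rn == as.character(seq_len(nrow(data))))) {
    if (nrow(data) != ape::Ntip(tree))
      stop("data rows cannot be matched to tree tips: provide row names or ",
           "a `species` column", call. = FALSE)
    rownames(data) <- tree$tip.label
    return(data)
  }
  rownames(data) <- rn
  missing <- setdiff(tree$tip.label, rn)
  if (length(missing))
    stop("no data rows for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  data[tree$tip.label, , drop = FALSE]
}
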