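#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the Brownian-motion model with lambda-scaled covariance to a
#' continuous variable: values are multivariate normal with mean `mu 1` and
#' covariance `sigma2 * V(lambda)`, where `V(lambda)` multiplies the
#' off-diagonal entries of the tree's covariance matrix by `lambda`
#' ([lambda_transform]). `mu` and `sigma2` are concentrated out analytically
#' by GLS at each `lambda`; `lambda` is profiled over `[0, 1]` with restarts
#' from 0, 0.25, 0.5, 0.75 and 1 (ties broken toward the lower value).
#'
#' `lambda` = 0 means tip values are phylogenetically random; `lambda` = 1 is
#' pure Brownian motion on the tree. Likelihood-ratio tests against both
#' boundaries use the chi-squared reference with 1 degree of freedom; because
#' each null pins `lambda` to a boundary of the parameter space this reference
#' is anti-conservative there, which matches common reporting practice.
#'
#' @param tree a `phylo` object with at least 4 tips.
#' @param x named numeric vector of trait values; names must match
#'   `tree$tip.label` (unnamed vectors are taken to be in tip order).
#' @return an object of class `"lambda_fit"`: a list with `lambda`,
#'   `sigma2` (Brownian rate, trait-units squared per branch-length unit),
#'   `mu` (ancestral mean), `loglik`, `loglik0`, `loglik1`, `p_vs_zero`,
#'   `p_vs_one`, `n`, and `unidentifiable` (TRUE on a star phylogeny, where
#'   the likelihood is flat in `lambda` and 0 is returned by convention).
#' @examples
#' tr <- simulate_tree(64, seed = 1)
#' x <- simulate_continuous(tr, lambda = 1, seed = 2)
#' fit_lambda(tr, x)
#' @export
fit_lambda <- function(tree, x) {
  validate_phylogeny(tree)
  x <- .align_values(tree, x, "x")
  n <- length(x)
  if (n < 4L)
    stop("at least 4 tips are required to estimate lambda", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("trait is constant; lambda is not estimable", call. = FALSE)
  .warn_if_not_ultrametric(tree)
  V <- phylo_vcv(tree)
  X <- matrix(1, n, 1)
  prep <- .gls_prepare(V, x, X)

  offmax <- max(abs(V[upper.tri(V)]))
  if (offmax <= 1e-12 * max(diag(V))) {
    # star phylogeny: V(lambda) does not depend on lambda
    e0 <- .gls_eval(prep, 0)
    out <- list(lambda = 0, sigma2 = e0$sigma2, mu = unname(e0$beta[1L]),
                loglik = e0$loglik, loglik0 = e0$loglik, loglik1 = e0$loglik,
                p_vs_zero = 1, p_vs_one = 1, n = n, unidentifiable = TRUE)
    class(out) <- "lambda_fit"
    return(out)
  }

  ml <- .lambda_mle(prep)
  eh <- .gls_eval(prep, ml$lambda)
  e0 <- .gls_eval(prep, 0)
  e1 <- .gls_eval(prep, 1)
  out <- list(
    lambda = ml$lambda,
    sigma2 = eh$sigma2,
    mu = unname(eh$beta[1L]),
    loglik = ml$loglik,
    loglik0 = e0$loglik,
    loglik1 = e1$loglik,
    p_vs_zero = stats::pchisq(2 * pmax(ml$loglik - e0$loglik, 0), df = 1,
                              lower.tail = FALSE),
    p_vs_one = stats::pchisq(2 * pmax(ml$loglik - e1$loglik, 0), df = 1,
                             lower.tail = FALSE),
    n = n,
    unidentifiable = FALSE
  )
  class(out) <- "lambda_fit"
  out
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda (ML)\n")
  cat(sprintf("  lambda = %.4f   sigma2 = %.4g   mu = %.4g   n = %d\n",
              x$lambda, x$sigma2, x$mu, x$n))
  cat(sprintf("  logLik = %.3f   P(lambda = 0) = %.3g   P(lambda = 1) = %.3g\n",
              x$loglik, x$p_vs_zero, x$p_vs_one))
  if (isTRUE(x$unidentifiable))
    cat("  note: star phylogeny; lambda is unidentifiable (0 by convention)\n")
  invisible(x)
}

#' @export
logLik.lambda_fit <- function(object, ...) {
  structure(object$loglik, df = 3, nobs = object$n, class = "logLik")
}

# align a (possibly named) value vector to tree tip order
.align_values <- function(tree, x, what = "values") {
  tips <- tree$tip.label
  if (!is.null(names(x))) {
    names(x) <- trimws(names(x))
    missing <- setdiff(tips, names(x))
    if (length(missing))
      stop(what, " has no value for tip(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    x <- x[tips]
  } else if (length(x) != length(tips)) {
    stop(what, " has length ", length(x), " but the tree has ",
         length(tips), " tips", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x))
    stop(what, " must be numeric with no missing values", call. = FALSE)
  stats::setNames(as.numeric(x), tips)
}
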