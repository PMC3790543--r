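# Internal GLS machinery shared by fit_lambda() and pgls().
#
# The profiled quantities at a given lambda are computed on whitened data:
# with W = lambda_transform(V, lambda), beta-hat = (X' W^-1 X)^-1 X' W^-1 y,
# sigma2_ML = RSS_W / n, and
# logLik = -(n log(2 pi sigma2) + log|W| + n) / 2.
#
# On ultrametric trees V(lambda) = lambda V + (1 - lambda) depth I, so a single
# symmetric eigendecomposition of V diagonalizes V(lambda) for every lambda:
# rotate y and X once, then each lambda evaluation is O(n p^2). Non-ultrametric
# trees fall back to a Cholesky factorization per lambda.

.gls_prepare <- function(V, y, X) {
  n <- nrow(V)
  d <- diag(V)
  ultra <- (max(d) - min(d)) <= 1e-8 * max(max(d), 1)
  if (ultra) {
    e <- eigen(V, symmetric = TRUE)
    list(type = "spectral", n = n, depth = mean(d),
         ev = e$values, yr = crossprod(e$vectors, y),
         Xr = crossprod(e$vectors, X))
  } else {
    list(type = "chol", n = n, V = V, y = y, X = X)
  }
}

# weighted LS on whitened data; returns profiled ML loglik and fit pieces
.gls_eval <- function(prep, lambda) {
  n <- prep$n
  if (prep$type == "spectral") {
    w <- lambda * prep$ev + (1 - lambda) * prep$depth
    if (any(w <= 0)) return(list(loglik = -Inf))
    sw <- sqrt(w)
    yw <- prep$yr / sw
    Xw <- prep$Xr / sw
    logdet <- sum(log(w))
  } else {
    W <- lambda_transform(prep$V, lambda, lambda_max = Inf)
    C <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(C)) return(list(loglik = -Inf))
    yw <- backsolve(C, prep$y, transpose = TRUE)
    Xw <- backsolve(C, prep$X, transpose = TRUE)
    logdet <- 2 * sum(log(diag(C)))
  }
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.xmin
  list(loglik = -0.5 * (n * log(2 * pi * sigma2) + logdet + n),
       beta = fit$coefficients, rss = rss, sigma2 = sigma2,
       Xw = Xw, yw = yw, rank = fit$rank)
}

# profile-ML estimate of lambda on [0, 1] with multiple restarts;
# ties broken toward lower lambda
.lambda_mle <- function(prep, starts = c(0, 0.25, 0.5, 0.75, 1), tol = 1e-9) {
  nll <- function(l) -.gls_eval(prep, l)$loglik
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value - tol ||
        (abs(op$value - best$value) <= tol && op$par < best$par))
      best <- op
  }
  if (is.null(best))
    stop("lambda optimization failed at every restart", call. = FALSE)
  # compare against the boundaries; ties go to the lower lambda
  cand_l <- c(0, best$par, 1)
  cand_v <- c(nll(0), best$value, nll(1))
  keep <- which(cand_v <= min(cand_v) + tol)
  pick <- keep[which.min(cand_l[keep])]
  list(lambda = cand_l[pick], loglik = -cand_v[pick])
}
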