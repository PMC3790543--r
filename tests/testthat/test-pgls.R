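test_that("PGLS at lambda = 0 on an ultrametric tree equals OLS", {
  set.seed(51)
  tr <- simulate_tree(24)
  x <- simulate_continuous(tr, 0.8)
  y <- 1.5 * x + rnorm(24, sd = 0.5)
  names(y) <- names(x)
  fit0 <- fit_pgls(tr, y, cbind(x = x), lambda = 0)
  ols <- stats::lm(y ~ x)
  expect_equal(unname(fit0$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit0$r2, summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("a noiseless linear response is recovered exactly at any lambda", {
  tr <- simulate_tree(20, seed = 52)
  x <- simulate_continuous(tr, 0.5, seed = 53)
  y <- 2 * x + 1
  for (lam in c(0, 0.4, 1)) {
    fit <- fit_pgls(tr, y, cbind(x = x), lambda = lam)
    expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-8)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
  }
  # fitting a variable on itself gives r2 = 1 exactly
  self <- fit_pgls(tr, x, cbind(x = x), lambda = "estimate")
  expect_equal(self$r2, 1, tolerance = 1e-12)
})

test_that("coefficients match the dense-inverse GLS oracle", {
  set.seed(54)
  for (i in 1:10) {
    tr <- simulate_tree(16)
    X <- cbind(a = rnorm(16), b = rnorm(16))
    y <- simulate_continuous(tr, 0.9) + 0.5 * X[, "a"]
    lam <- runif(1)
    fit <- fit_pgls(tr, y, X, lambda = lam)
    V <- lambda_transform(phylo_vcv(tr), lam)
    expect_equal(unname(fit$coefficients),
                 unname(oracle_gls(V, y, cbind(1, X))), tolerance = 1e-8)
  }
})

test_that("PGLS on a star phylogeny is OLS for any lambda", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1,F:1,G:1,H:1);")
  set.seed(55)
  x <- rnorm(8)
  y <- 0.7 * x + rnorm(8, sd = 0.3)
  names(x) <- names(y) <- star$tip.label
  ols <- stats::lm(y ~ x)
  for (lam in c(0.3, 1)) {
    fit <- fit_pgls(star, y, cbind(x = x), lambda = lam)
    expect_lt(max(abs(fit$coefficients - coef(ols))), 1e-8)
  }
})

test_that("estimated lambda attains the best likelihood on a 21-point grid", {
  tr <- simulate_tree(40, seed = 56)
  x <- simulate_continuous(tr, 0.7, seed = 57)
  y <- x + simulate_continuous(tr, 0.7, seed = 58)
  fit <- fit_pgls(tr, y, cbind(x = x), lambda = "estimate")
  grid_ll <- vapply(seq(0, 1, length.out = 21), function(l)
    fit_pgls(tr, y, cbind(x = x), lambda = l)$loglik, numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
})

test_that("fit_ols handles exact and orthogonal relationships", {
  set.seed(59)
  x <- rnorm(30)
  fit <- fit_ols(x, cbind(x = x))
  expect_equal(unname(fit$coefficients["x"]), 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # construct a response orthogonal to x
  y <- stats::residuals(stats::lm(rnorm(30) ~ x))
  fit2 <- fit_ols(y, cbind(x = x))
  expect_lt(abs(fit2$coefficients["x"]), 1e-10)
})

test_that("r2 does not improve when the predictor is replaced by a permuted copy", {
  set.seed(60)
  diffs <- replicate(200, {
    x <- rnorm(30)
    y <- 0.8 * x + rnorm(30)
    fit_ols(y, cbind(x = x))$r2 - fit_ols(y, cbind(x = sample(x)))$r2
  })
  expect_gt(mean(diffs), 0)
})

test_that("quadratic_check flags curvature and stays null-calibrated", {
  set.seed(61)
  x <- rnorm(50)
  y <- (x - mean(x))^2 + rnorm(50, sd = 0.1)
  expect_lt(quadratic_check(NULL, y, x, phylogenetic = FALSE), 0.01)

  pvals <- replicate(200, {
    x <- rnorm(40)
    quadratic_check(NULL, x + rnorm(40, sd = 0.2), x, phylogenetic = FALSE)
  })
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.60)
  expect_lt(mean(pvals < 0.05), 0.12)

  expect_error(quadratic_check(NULL, rep(1, 10), rnorm(10)), "non-constant")
})

test_that("PGLS rejects rank-deficient designs and tiny samples", {
  tr <- simulate_tree(10, seed = 62)
  x <- simulate_continuous(tr, 0.5, seed = 63)
  expect_error(fit_pgls(tr, x, cbind(a = x, b = 2 * x)), "rank deficient")
  tr4 <- simulate_tree(4, seed = 64)
  y4 <- simulate_continuous(tr4, 0.5, seed = 65)
  expect_error(fit_pgls(tr4, y4, cbind(a = rnorm(4), b = rnorm(4))), "p \\+ 2")
})

test_that("PGLS with fixed lambda matches nlme::gls with corPagel", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(32, seed = 66)
  x <- simulate_continuous(tr, 0.8, seed = 67)
  y <- 0.6 * x + simulate_continuous(tr, 0.8, seed = 68)
  d <- data.frame(y = y, x = x, row.names = tr$tip.label)
  fit <- pgls(y ~ x, d, tr, lambda = 0.7)
  # rows of d are in tip order; corPagel's ordering note is expected
  gfit <- suppressWarnings(
    nlme::gls(y ~ x, data = d,
              correlation = ape::corPagel(0.7, tr, fixed = TRUE)))
  expect_equal(unname(fit$coefficients), unname(coef(gfit)), tolerance = 1e-6)
})
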