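test_that("label_signal maps the documented reference values", {
  expect_equal(as.character(label_signal(0.32, "lambda")$level), "moderate")
  expect_equal(as.character(label_signal(0.70, "lambda")$level), "strong")
  expect_equal(as.character(label_signal(0.22, "lambda")$level), "weak")
  expect_equal(as.character(label_signal(1.00, "lambda")$level), "strong")
  expect_equal(as.character(label_signal(0.39, "lambda")$level), "moderate")
  expect_equal(as.character(label_signal(0.13, "one_minus_d")$level), "none")
  expect_equal(as.character(label_signal(0.25, "one_minus_d")$level), "moderate")
  expect_error(label_signal(1.2, "lambda"), "\\[0, 1\\]")
  expect_error(label_signal(-0.1, "one_minus_d"), "\\[0, 1\\]")
})

test_that("classify_quadrant implements the four-scenario matrix", {
  lab <- function(v, k = "lambda") label_signal(v, k)
  expect_equal(classify_quadrant(lab(0.05), lab(0.10)), "A")
  expect_equal(classify_quadrant(lab(0.22), lab(0.13, "one_minus_d")), "A")
  expect_equal(classify_quadrant(lab(0.95), lab(0.05)), "B")
  expect_equal(classify_quadrant(lab(0.05), lab(0.95)), "C")
  expect_equal(classify_quadrant(lab(0.95), lab(0.95)), "D")
  # moderate counts as patterned
  expect_equal(classify_quadrant(lab(0.32), lab(0.05)), "B")
})

test_that("assess_risk follows the sign- and strength-based rule", {
  corr <- function(p, np, s) list(phylo_r2 = p, nonphylo_r2 = np, sign = s)
  # strong negative correlation in quadrant D: high risk, maximum concern
  r <- assess_risk("D", corr(0.42, 0.57, -1))
  expect_equal(as.character(r$risk), "high")
  expect_true(r$maximum_concern)
  # strong negative correlation outside quadrant D: high, no flag
  r2 <- assess_risk("B", corr(0.05, 0.45, -1))
  expect_equal(as.character(r2$risk), "high")
  expect_false(r2$maximum_concern)
  # negligible correlation: very low regardless of quadrant
  expect_equal(as.character(assess_risk("B", corr(5e-4, 5e-4, -1))$risk),
               "very_low")
  # weak negative correlation: low
  expect_equal(as.character(assess_risk("C", corr(5e-4, 0.018, -1))$risk),
               "low")
  expect_equal(as.character(assess_risk("D", corr(5e-4, 0.027, -1))$risk),
               "low")
  # positive association: function concentrated in tolerant species
  rp <- assess_risk("D", corr(0.30, 0.45, +1))
  expect_equal(as.character(rp$risk), "very_low")
  expect_match(rp$note, "tolerant")
})

test_that("assess_correlation recovers perfect and null relationships", {
  tr <- simulate_tree(24, seed = 81)
  sef <- simulate_continuous(tr, 0.5, seed = 82)
  ca <- assess_correlation(tr, sef, -sef)
  expect_equal(ca$phylo_r2, 1, tolerance = 1e-8)
  expect_equal(ca$nonphylo_r2, 1, tolerance = 1e-8)
  expect_equal(ca$sign, -1)
  expect_error(assess_correlation(tr, sef, rep(1, 24)), "non-constant")

  # null: mean OLS r2 is about 1/(n-1)
  set.seed(83)
  tr30 <- simulate_tree(30)
  sef30 <- simulate_continuous(tr30, 0.3)
  r2s <- replicate(200, fit_ols(sef30, cbind(x = sample(unname(sef30))))$r2)
  expect_gt(mean(r2s), 0.015)
  expect_lt(mean(r2s), 0.055)
})

test_that("assess_correlation tracks a target cross-correlation", {
  set.seed(84)
  r2s <- replicate(50, {
    tr <- simulate_tree(100)
    pair <- simulate_sef_srf(tr, 0.5, 0.5, rho = -0.75)
    fit_ols(pair$sef, cbind(srf = pair$srf))$r2
  })
  expect_gt(mean(r2s), 0.45)
  expect_lt(mean(r2s), 0.65)
})

test_that("apply_filter implements the quantile split with tie retention", {
  tr <- simulate_tree(8, seed = 85)
  sef <- stats::setNames(c(8, 7, 6, 5, 4, 3, 2, 1), tr$tip.label)
  srf <- stats::setNames(1:8, tr$tip.label)
  f <- apply_filter(sef, srf, quantile = 0.5, tree = tr)
  expect_setequal(unname(sef[f$survivors]), c(4, 3, 2, 1))
  expect_equal(f$sef_before[["mean"]], 4.5)
  expect_equal(f$sef_after[["mean"]], 2.5)
  expect_equal(f$sef_after[["n"]], 4)
  expect_lte(f$pd_retained_fraction, 1)

  # quantile 0 keeps everything
  f0 <- apply_filter(sef, srf, quantile = 0, tree = tr)
  expect_equal(f0$sef_after, f0$sef_before)
  expect_equal(f0$pd_retained_fraction, 1)

  # ties at the threshold all survive
  srf_tied <- stats::setNames(c(1, 2, 3, 4, 4, 4, 7, 8), tr$tip.label)
  ft <- apply_filter(sef, srf_tied, quantile = 0.5)
  expect_equal(ft$sef_after[["n"]], 5)
  expect_equal(ft$n_ties, 3)

  # survivor count without ties is ceiling(n * (1 - q))
  set.seed(86)
  for (q in c(0.2, 0.3, 0.5, 0.8)) {
    n <- sample(10:40, 1)
    s <- stats::setNames(sample(seq_len(n)), paste0("s", 1:n))
    f <- apply_filter(s, s, quantile = q)
    expect_equal(f$sef_after[["n"]], ceiling(n * (1 - q)))
    expect_gte(f$sef_after[["min"]], f$sef_before[["min"]])
    expect_lte(f$sef_after[["max"]], f$sef_before[["max"]])
  }
  expect_error(apply_filter(sef, srf, quantile = 1), "quantile")
})

test_that("risk_assessment integrates the stages end to end", {
  sc <- generate_scenario("D", n_tips = 64, rho = -0.9, seed = 7)
  ra <- risk_assessment(sc$tree, sc$data, sef = "sef", srf = "srf",
                        n_perm = 200, seed = 1)
  expect_s3_class(ra, "risk_assessment")
  expect_equal(ra$quadrant, "D")
  expect_equal(as.character(ra$risk$risk), "high")
  expect_true(ra$risk$maximum_concern)
  expect_lt(ra$filter$sef_after[["mean"]], ra$filter$sef_before[["mean"]])

  scA <- generate_scenario("A", n_tips = 64, rho = 0, seed = 8)
  raA <- risk_assessment(scA$tree, scA$data, sef = "sef", srf = "srf",
                         n_perm = 200, seed = 1)
  expect_equal(raA$quadrant, "A")
  expect_equal(as.character(raA$risk$risk), "very_low")

  expect_error(risk_assessment(sc$tree, sc$data, sef = "sef", srf = "nope"),
               "column not found")
})

test_that("risk_assessment uses 1 - D labelling for a binary SRF", {
  tr <- simulate_tree(64, seed = 91)
  d <- data.frame(species = tr$tip.label,
                  sef = unname(simulate_continuous(tr, 0.9, seed = 92)),
                  srf = unname(simulate_binary_threshold(tr, 0.9, 0.5, seed = 93)))
  ra <- risk_assessment(tr, d, sef = "sef", srf = "srf", n_perm = 200, seed = 2)
  expect_s3_class(ra$srf_signal, "D_fit")
  expect_equal(ra$srf_label$kind, "one_minus_d")
})

test_that("tree/table mismatch errors unless pruning is requested", {
  sc <- generate_scenario("B", n_tips = 16, seed = 12)
  extra <- rbind(sc$data, data.frame(species = "ghost", sef = 1, srf = 1))
  expect_error(risk_assessment(sc$tree, extra, sef = "sef", srf = "srf"),
               "mismatch")
  ra <- risk_assessment(sc$tree, extra, sef = "sef", srf = "srf",
                        prune = TRUE, seed = 3)
  expect_equal(ra$n, 16)
})
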