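test_that("trapezoid AUC equals brute-force pair counting on random data", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    score <- round(rnorm(n, 0, 50), sample(0:1, 1))   # force some ties
    repeat {
      lab <- runif(n) < 0.4
      if (any(lab) && !all(lab)) break
    }
    dirn <- sample(c("lower", "higher"), 1)
    pts <- roc_curve(score, lab, dirn)
    expect_equal(roc_auc(pts), oracle_auc_pairs(score, lab, dirn),
                 tolerance = 1e-12)
  }
})

test_that("curve points match exhaustive threshold enumeration", {
  score <- c(-90, -80, -70, -40, -10, 0, 30)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  pts <- roc_curve(score, lab, "lower")
  for (i in seq_len(nrow(pts))) {
    t <- pts$threshold[i]
    called <- score <= t
    expect_equal(pts$sensitivity[i], sum(called & lab) / sum(lab))
    expect_equal(pts$specificity[i], sum(!called & !lab) / sum(!lab))
  }
  # perfect separation: a (sens = 1, spec = 1) point exists
  expect_true(any(pts$sensitivity == 1 & pts$specificity == 1))
  expect_equal(roc_auc(pts), 1)
})

test_that("hand-counted pair orderings give the exact AUC fraction", {
  full <- roc_analysis(c(-90, -80, -70, -40, -10, 0, 30),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(full$auc, 1)
  # negative at -85 outranks two of the three positives: 10/12 ordered
  swapped <- roc_analysis(c(-90, -80, -70, -85, -10, 0, 30),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(swapped$auc, 10 / 12)
  # a negative between the two best positives flips exactly one pair
  near <- roc_analysis(c(-90, -80, -70, -75, -10, 0, 30),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(near$auc, 11 / 12)
})

test_that("degenerate scores and labels behave: ties, chance, one class", {
  # all scores identical: AUC is exactly 1/2
  pts <- roc_curve(rep(3, 8), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                                FALSE, FALSE))
  expect_equal(roc_auc(pts), 0.5)
  # random labels at large n: AUC near 1/2
  set.seed(18)
  score <- rnorm(400)
  lab <- sample(c(TRUE, FALSE), 400, replace = TRUE)
  expect_lt(abs(roc_auc(roc_curve(score, lab)) - 0.5), 0.1)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "non-responder")
})

test_that("direction flip complements the AUC when scores are tie-free", {
  set.seed(19)
  score <- rnorm(12)
  lab <- c(rep(TRUE, 5), rep(FALSE, 7))
  a <- roc_auc(roc_curve(score, lab, "lower"))
  b <- roc_auc(roc_curve(score, lab, "higher"))
  expect_equal(a + b, 1, tolerance = 1e-12)
})

test_that("permutation p-value matches full enumeration at small n", {
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    score <- rnorm(n, 0, 40)
    repeat {
      lab <- runif(n) < 0.4
      if (any(lab) && !all(lab)) break
    }
    pv <- roc_pvalue(score, lab, "lower")
    expect_equal(pv$method, "exact")
    expect_equal(pv$p_value, oracle_perm_pvalue(score, lab, "lower"),
                 tolerance = 1e-12)
  }
  # perfect separation: two-sided exact p is 2 / choose(n, n_pos)
  score <- c(-9, -8, -7, 1, 2, 3, 4)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  pv <- roc_pvalue(score, lab, "lower")
  expect_equal(pv$p_value, 2 / choose(7, 3))
})

test_that("Monte-Carlo p-value branch is seeded and near the exact value", {
  set.seed(21)
  score <- rnorm(9)
  lab <- c(rep(TRUE, 4), rep(FALSE, 5))
  exact <- roc_pvalue(score, lab)$p_value
  mc1 <- roc_pvalue(score, lab, max_enumerate = 1, n_mc = 4000, seed = 7)
  mc2 <- roc_pvalue(score, lab, max_enumerate = 1, n_mc = 4000, seed = 7)
  expect_equal(mc1$method, "monte-carlo")
  expect_identical(mc1$p_value, mc2$p_value)
  expect_lt(abs(mc1$p_value - exact), 0.05)
})

test_that("Youden cutoff lands between the straddling scores", {
  r <- roc_analysis(c(-90, -80, -70, -40, -10, 0, 30),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(r$optimal$cutoff, -55)       # midpoint of -70 and -40
  expect_equal(r$optimal$youden, 1)
  expect_gt(r$optimal$cutoff, -70)
  expect_lt(r$optimal$cutoff, -40)
})

test_that("Youden cutoff is invariant to strictly monotone score transforms", {
  set.seed(22)
  score <- rnorm(10, 0, 30)
  lab <- c(rep(TRUE, 4), rep(FALSE, 6))
  base <- optimal_cutoff(roc_curve(score, lab, "lower"))
  # monotone transform preserves order, hence the chosen datum threshold
  tr <- function(x) x^3 / 100 + 5 * x
  after <- optimal_cutoff(roc_curve(tr(score), lab, "lower"))
  expect_equal(after$threshold, tr(base$threshold), tolerance = 1e-9)
  expect_equal(after$sensitivity, base$sensitivity)
  expect_equal(after$specificity, base$specificity)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (rep in 1:5) {
    score <- round(rnorm(15, 0, 20), 1)
    lab <- c(rep(TRUE, 6), rep(FALSE, 9))
    ours <- roc_auc(roc_curve(score, lab, "lower"))
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(response = lab, predictor = score,
                                     direction = ">"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
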