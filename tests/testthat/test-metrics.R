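# Independent oracles used throughout: O(n^2) pair counting for AUROC,
# the step-curve definition for average precision, an exhaustive candidate
# scan for Youden, and frozen reference values (computed externally with
# statsmodels' cohens_kappa) for the kappa variance.

auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

test_that("confusion metrics match hand-counted tables", {
  m <- confusion_at_threshold(c(5, 5, 1, 1), c(1, 1, 0, 0), 3)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$f1, 1.0)
  m2 <- confusion_at_threshold(c(5, 1, 5, 1), c(1, 1, 0, 0), 3)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.5)
  # f1 is the harmonic mean of precision and sensitivity
  expect_equal(m2$f1, 2 * m2$precision * m2$sensitivity /
                 (m2$precision + m2$sensitivity))
})

test_that("undefined precision is NaN with a warning, never silent zero", {
  expect_warning(
    m <- confusion_at_threshold(c(1, 2, 3), c(0, 0, 0), 5),
    "precision undefined")
  expect_true(is.nan(m$precision))
  expect_true(is.nan(m$f1))
})

test_that("auroc handles separation, ties, and the pair-count example", {
  expect_equal(auroc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(2, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  # positives {1,4}, negatives {3,2}: 2 wins of 4 pairs
  expect_equal(auroc(c(1, 4, 3, 2), c(1, 1, 0, 0)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("auroc equals the O(n^2) pair-counting oracle on random data", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    scores <- sample(seq(0, 9, 0.2), n, replace = TRUE)  # ties likely
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels))
    # complement and monotone-transform invariance
    expect_equal(auroc(scores, labels) + auroc(-scores, labels), 1)
    expect_equal(auroc(exp(scores), labels), auroc(scores, labels))
  }
})

test_that("auprc follows the average-precision convention", {
  expect_equal(auprc(c(9, 8, 1), c(1, 1, 0)), 1.0)
  expect_equal(auprc(c(2, 1), c(0, 1)), 0.5)   # one pos ranked below one neg
  expect_equal(auprc(rep(3, 10), c(rep(1, 3), rep(0, 7))), 0.3)  # ties: pi
  expect_error(auprc(c(1, 2), c(0, 0)), "no positive")
  # oracle: sum of precision-at-rank over positives (tie-free case)
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    scores <- sample(seq_len(100), n)   # distinct
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    ord <- order(-scores)
    lab_sorted <- labels[ord]
    ap <- sum((cumsum(lab_sorted) / seq_along(lab_sorted))[lab_sorted == 1]) /
      sum(labels)
    expect_equal(auprc(scores, labels), ap)
  }
})

test_that("youden threshold maximizes J over midpoint candidates", {
  yt <- youden_threshold(c(5, 5, 1, 1), c(1, 1, 0, 0))
  expect_equal(yt$bcp, 3.0)
  expect_equal(yt$youden_j, 1.0)
  # exhaustive-scan oracle on random gridded data
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 9, 0.2), n, replace = TRUE)
    labels <- rbinom(n, 1, plogis(scores - 4))
    if (length(unique(labels)) < 2 || length(unique(scores)) < 2) next
    v <- sort(unique(scores))
    cand <- (head(v, -1) + tail(v, -1)) / 2
    j <- sapply(cand, function(t) {
      mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1
    })
    yt <- youden_threshold(scores, labels)
    expect_equal(yt$youden_j, max(j))
    expect_equal(yt$bcp, cand[which.max(j)])  # first max = lower threshold
  }
})

test_that("youden J is near zero when labels are independent of scores", {
  set.seed(10)
  scores <- sample(seq(0, 9, 0.2), 20000, replace = TRUE)
  labels <- rbinom(20000, 1, 0.3)
  expect_lt(youden_threshold(scores, labels)$youden_j, 0.05)
})

test_that("cohens_kappa matches hand computation and the frozen FCE oracle", {
  # cells: both+ 45, a+only 15, b+only 25, both- 15
  a <- rep(c(1, 1, 0, 0), c(45, 15, 25, 15))
  b <- rep(c(1, 0, 1, 0), c(45, 15, 25, 15))
  k <- cohens_kappa(a, b)
  expect_equal(k$po, 0.6)
  expect_equal(k$pe, 0.54)
  expect_equal(k$kappa, 0.06 / 0.46, tolerance = 1e-12)
  # frozen from statsmodels cohens_kappa (Fleiss-Cohen-Everitt variance)
  expect_equal(k$se, 0.0986615, tolerance = 1e-6)
  expect_equal(k$ci_low, -0.0629418, tolerance = 1e-5)
  expect_equal(k$ci_high, 0.3238114, tolerance = 1e-5)
  # second frozen table: (both+ 130, a+only 22, b+only 35, both- 310)
  a2 <- rep(c(1, 1, 0, 0), c(130, 22, 35, 310))
  b2 <- rep(c(1, 0, 1, 0), c(130, 22, 35, 310))
  k2 <- cohens_kappa(a2, b2)
  expect_equal(k2$kappa, 0.7362020, tolerance = 1e-6)
  expect_equal(k2$se, 0.0326562, tolerance = 1e-6)
})

test_that("kappa degenerate and invariance properties hold", {
  both <- c(1, 0, 1, 1, 0)
  expect_equal(cohens_kappa(both, both)$kappa, 1)
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5))$kappa, 1)  # pe = 1, agree
  # constant raters in opposite directions: pe = 0, po = 0, kappa = 0
  expect_equal(cohens_kappa(rep(1, 5), rep(0, 5))$kappa, 0)
  expect_error(cohens_kappa(c(1, 0), c(1, 0, 1)), "equal")
  expect_error(cohens_kappa(c(1, 2), c(1, 0)), "binary")
  set.seed(11)
  a <- rbinom(200, 1, 0.4); b <- rbinom(200, 1, 0.6)
  expect_equal(cohens_kappa(a, b)$kappa, cohens_kappa(b, a)$kappa)
  # independence null at large n
  a <- rbinom(50000, 1, 0.25); b <- rbinom(50000, 1, 0.12)
  expect_lt(abs(cohens_kappa(a, b)$kappa), 0.02)
})
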