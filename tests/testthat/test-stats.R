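# ROC/AUC, DeLong comparison, correlation, ANOVA, Fisher, OLS

test_that("AUC handles separability, pure ties, and the 5/6 toy set", {
  r <- roc(c(10, 11, 12, 1, 2), c(1, 1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  r <- roc(rep(3, 20), rep(c(0, 1), 10))
  expect_equal(r$auc, 0.5)

  # positives {1,2,3} vs negatives {0,1.5}: 5 of 6 pairs won
  r <- roc(c(1, 2, 3, 0, 1.5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 5 / 6)

  expect_error(roc(1:5, rep(1, 5)), "both classes")
})

test_that("rank-based AUC equals explicit pair counting exactly", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(6:25, 1)
    scores <- sample(round(rnorm(n), 1)) # rounding forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_identical(roc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(15)
  scores <- rnorm(40)
  labels <- rep(c(TRUE, FALSE), 20)
  a0 <- roc(scores, labels)$auc
  expect_equal(roc(exp(scores), labels)$auc, a0)
  expect_equal(roc(scores^3 + 2 * scores, labels)$auc, a0)
  # flipping the score direction complements the AUC exactly
  expect_equal(roc(-scores, labels)$auc, 1 - a0)
})

test_that("ROC confidence interval brackets the AUC and SE shrinks with n", {
  set.seed(16)
  ses <- vapply(c(20, 80, 320), function(n) {
    scores <- c(rnorm(n, 1.5), rnorm(n, 0))
    labels <- rep(c(TRUE, FALSE), each = n)
    r <- roc(scores, labels)
    expect_gte(r$auc, r$ci95[1])
    expect_lte(r$auc, r$ci95[2])
    r$se
  }, 1)
  expect_true(all(diff(ses) < 0))
})

test_that("cut point maximizes Youden; the specificity-1 variant is reported", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  r <- roc(scores, labels)
  j <- r$sensitivity + r$specificity - 1
  curve <- tidy(r)
  expect_equal(max(curve$sensitivity + curve$specificity - 1), j)
  expect_equal(r$specificity, 1) # tie broken toward higher specificity here
  expect_equal(r$sensitivity_spec1, 0.75)
})

test_that("identical scores compare as equal curves (z = 0, p = 1)", {
  set.seed(17)
  s <- rnorm(30)
  lab <- rep(c(TRUE, FALSE), 15)
  cmp <- compare_auc(s, s, lab)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_auc(s, s[-1], lab), "equal-length")
})

test_that("DeLong comparison separates a perfect from a random marker", {
  set.seed(18)
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    lab <- rep(c(TRUE, FALSE), each = 30)
    perfect <- ifelse(lab, 1, 0) + rnorm(60, sd = 0.01)
    random <- rnorm(60)
    cmp <- compare_auc(perfect, random, lab)
    hits <- hits + (cmp$p < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("pearson matches closed-form values", {
  expect_equal(pearson(1:10, 1:10)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(19)
  x <- rnorm(20, 0)
  y <- rnorm(25, 0.8)
  res <- anova_bonferroni(c(x, y), rep(c("a", "b"), c(20, 25)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$pairwise$p_raw, res$pairwise$p_adj) # one pair: no penalty
})

test_that("ANOVA on equal-mean groups rarely rejects; Bonferroni inflates p", {
  set.seed(20)
  ps <- vapply(1:20, function(i) {
    v <- rnorm(60)
    anova_bonferroni(v, rep(letters[1:3], 20))$p
  }, 1)
  expect_gt(mean(ps > 0.01), 0.8)

  set.seed(21)
  v <- c(rnorm(20), rnorm(20, 3), rnorm(20, -1), rnorm(20))
  res <- anova_bonferroni(v, rep(letters[1:4], each = 20))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adj <= 1))
  expect_error(anova_bonferroni(1:5, c("a", "a", "a", "a", "b")), ">= 2")
})

test_that("a strongly shifted group shows up in all its post-hoc pairs", {
  set.seed(22)
  fails <- 0L
  for (i in 1:25) {
    v <- c(rnorm(20), rnorm(20), rnorm(20), rnorm(20, 3)) # one +3 SD group
    res <- anova_bonferroni(v, rep(c("a", "b", "c", "d"), each = 20))
    pw <- res$pairwise
    d_pairs <- pw[pw$group1 == "d" | pw$group2 == "d", ]
    if (!all(d_pairs$p_adj < 0.001)) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-9)
  set.seed(23)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab), tolerance = 1e-7)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  # 2 x k tables go through exact enumeration too
  p <- fisher_exact(matrix(c(8, 1, 1, 1, 8, 1), nrow = 2, byrow = TRUE))
  expect_true(p > 0 && p < 1)
})

test_that("OLS matches the closed-form normal equations", {
  x <- c(1, 2, 4, 5, 7)
  y <- c(2.1, 2.9, 5.2, 6.1, 8.3)
  fit <- linreg(x, y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(fit$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - fit$slope * mean(x), tolerance = 1e-12)

  # lm warns about the exact fit; the r2 = 1 value is the point
  suppressWarnings(expect_equal(linreg(1:10, 3 + 2 * (1:10))$r2, 1))
  set.seed(24)
  null_fit <- linreg(rnorm(1000), rnorm(1000))
  expect_lt(null_fit$r2, 0.01)
  expect_error(linreg(rep(2, 5), rnorm(5)), "constant")
})

test_that("correlation tables Bonferroni-correct over the whole family", {
  set.seed(25)
  d <- tibble::tibble(
    a = rnorm(50), b = rnorm(50),
    x = rnorm(50), y = rnorm(50), z = rnorm(50)
  )
  ct <- correlation_table(d, c("a", "b"), c("x", "y", "z"))
  expect_equal(nrow(ct), 6)
  expect_true(all(ct$p_adj >= ct$p_raw))
  expect_true(all(ct$p_adj <= 1))
  expect_equal(ct$p_adj, pmin(1, ct$p_raw * 6))
})
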