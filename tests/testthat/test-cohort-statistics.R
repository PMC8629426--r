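test_that("rank-sum test matches exact enumeration on small samples", {
  # identical samples carry no separation
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # fully separated 3 vs 3: the two extreme assignments out of C(6,3)
  out <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, 6)
  expect_equal(out$p, 0.1)
  expect_equal(out$method, "exact-enumeration")
  # independent enumeration oracle, with ties present
  x <- c(1, 2, 2, 5); y <- c(2, 3, 6, 7)
  r <- rank(c(x, y))
  ew <- 4 * 9 / 2
  wobs <- sum(r[1:4])
  combs <- combn(8, 4)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  p_oracle <- mean(abs(ws - ew) >= abs(wobs - ew) - 1e-9)
  expect_equal(wilcoxon_rank_sum(x, y)$p, p_oracle)
})

test_that("normal approximation agrees with reference implementations", {
  set.seed(19)
  x <- rnorm(30, 0.6); y <- rnorm(30)
  ours <- wilcoxon_rank_sum(x, y)
  expect_equal(ours$method, "normal-approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  # permutation oracle within Monte-Carlo error
  pooled <- c(x, y)
  ew <- 30 * 61 / 2
  wobs <- sum(rank(pooled)[1:30])
  set.seed(20)
  perm <- replicate(20000, {
    ix <- sample(60, 30)
    sum(rank(pooled)[ix])
  })
  p_perm <- mean(abs(perm - ew) >= abs(wobs - ew) - 1e-9)
  se <- sqrt(p_perm * (1 - p_perm) / 20000)
  expect_lt(abs(ours$p - p_perm), 4 * se + 1e-3)
})

test_that("exact and approximate branches agree near the crossover", {
  set.seed(33)
  for (i in 1:10) {
    x <- sample(1:8, 6, replace = TRUE)
    y <- sample(2:9, 6, replace = TRUE)
    p_ex <- wilcoxon_rank_sum(x, y)$p
    p_ap <- wilcoxon_rank_sum(x, y, exact_max = 0)$p
    expect_lt(abs(p_ex - p_ap), 0.05)
  }
})

test_that("spearman is a rank correlation with tie handling", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, -x^3), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # invariance under strictly increasing transforms
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman(a, b), spearman(exp(a), b^3 + 5 * b))
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("ROC scan equals brute-force confusion counts at every cut", {
  scores <- c(0.2, 0.5, 0.5, 0.9, 1.4, 0.1, 0.3, 0.8, 1.1, 0.05)
  labels <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE,
              FALSE)
  r <- roc_with_youden(scores, labels)
  npos <- sum(labels); nneg <- sum(!labels)
  for (i in seq_along(r$thresholds)) {
    pred <- scores >= r$thresholds[i]
    expect_equal(r$sensitivity[i], sum(pred & labels) / npos)
    expect_equal(r$specificity[i], sum(!pred & !labels) / nneg)
  }
  # AUC equals the normalized Mann-Whitney statistic and pROC agrees
  rr <- rank(scores)
  u <- sum(rr[labels]) - npos * (npos + 1) / 2
  expect_equal(r$auc, u / (npos * nneg))
  skip_if_not_installed("pROC")
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("Youden threshold maximizes J with smallest-threshold ties", {
  # perfect separation
  r <- roc_with_youden(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$youden_j, 1)
  expect_equal(r$at_youden$accuracy, 1)
  # uninformative scores: J = 0 (all-positive cut leaves NPV undefined,
  # which is signaled rather than silently zeroed)
  expect_warning(
    r0 <- roc_with_youden(rep(1, 6),
                          c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),
    "undefined")
  expect_equal(r0$youden_j, 0)
  # tie in J resolved toward the smallest threshold
  r2 <- roc_with_youden(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  j <- r2$sensitivity + r2$specificity - 1
  expect_equal(r2$youden_threshold,
               min(r2$thresholds[j >= max(j) - 1e-12]))
  expect_error(roc_with_youden(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("confusion metrics are the standard ratios", {
  m <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, ppv = 1,
                            npv = 1, accuracy = 1))
  m2 <- confusion_metrics(8, 6, 20, 2)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 20 / 26, tolerance = 1e-10)
  expect_equal(m2$ppv, 8 / 14, tolerance = 1e-10)
  expect_equal(m2$npv, 20 / 22, tolerance = 1e-10)
  expect_equal(m2$accuracy, 28 / 36, tolerance = 1e-10)
  # ratio property: invariant under scaling all counts
  m3 <- confusion_metrics(24, 18, 60, 6)
  expect_equal(unlist(m2), unlist(m3))
  expect_warning(m4 <- confusion_metrics(0, 0, 5, 5), "PPV undefined")
  expect_true(is.na(m4$ppv))
})
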