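test_that("confusion counts match a brute-force loop and swap symmetrically", {
  set.seed(701)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    pred <- sample(c("abnormal", "normal"), n, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    cm <- confusion(pred, truth)
    # brute-force oracle
    tp <- fp <- fn <- tn <- 0L
    for (k in seq_len(n)) {
      if (pred[k] == "abnormal" && truth[k]) tp <- tp + 1L
      if (pred[k] == "abnormal" && !truth[k]) fp <- fp + 1L
      if (pred[k] == "normal" && truth[k]) fn <- fn + 1L
      if (pred[k] == "normal" && !truth[k]) tn <- tn + 1L
    }
    expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]),
                 c(TP = tp, FP = fp, FN = fn, TN = tn))
    expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, n)

    # inverting the predictions swaps TP with FN and TN with FP
    inv <- confusion(ifelse(pred == "abnormal", "normal", "abnormal"), truth)
    expect_equal(c(inv$TP, inv$TN), c(cm$FN, cm$FP))
  }
  expect_error(confusion("abnormal", c(TRUE, FALSE)),
               class = "hs_evaluation_error")
})

test_that("metric formulas reproduce the reference worked examples", {
  m1 <- metrics(list(TP = 11, FN = 1, FP = 1, TN = 99))
  expect_equal(round(m1$accuracy, 2), 98.21)
  expect_equal(round(m1$sensitivity, 2), 91.67)
  expect_equal(round(m1$specificity, 2), 99.00)

  m2 <- metrics(list(TP = 10, FN = 2, FP = 1, TN = 99))
  expect_equal(round(m2$sensitivity, 2), 83.33)
  expect_equal(round(m2$accuracy, 2), 97.32)

  all_correct <- metrics(list(TP = 7, FN = 0, FP = 0, TN = 30))
  expect_equal(c(all_correct$accuracy, all_correct$sensitivity,
                 all_correct$specificity), c(100, 100, 100))

  # zero denominators flag, never silently zero
  m3 <- metrics(list(TP = 0, FN = 0, FP = 2, TN = 8))
  expect_true(is.na(m3$sensitivity))
  expect_true(m3$undefined[["sensitivity"]])
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(702)
  for (i in 1:30) {
    cm <- list(TP = sample(1:20, 1), FP = sample(1:20, 1),
               FN = sample(1:20, 1), TN = sample(1:20, 1))
    m <- metrics(cm)
    prev <- (cm$TP + cm$FN) / (cm$TP + cm$FP + cm$FN + cm$TN)
    expect_equal(m$accuracy, m$sensitivity * prev + m$specificity * (1 - prev),
                 tolerance = 1e-10)
  }
})

test_that("stratified splits preserve stratum proportions deterministically", {
  labels <- rep(c("target", "non-target"), c(40, 408))
  s1 <- stratified_split(labels, seed = 9)
  expect_identical(s1, stratified_split(labels, seed = 9))
  expect_equal(sum(s1 == "test"), 112L)
  expect_equal(sum(s1 == "train"), 336L)
  expect_equal(sum(s1 == "test" & labels == "target"), 10L)
  expect_equal(sum(s1 == "test" & labels == "non-target"), 102L)
  expect_true(all(s1 %in% c("train", "test")))

  # hand-level unit split keeps repetitions together
  unit <- rep(seq_len(112), each = 4)
  s2 <- stratified_split(labels, seed = 9, unit = unit)
  tab <- table(unit, s2)
  expect_true(all(rowSums(tab > 0) == 1L))

  expect_warning(stratified_split(c("a", "b", "b", "b")),
                 class = "hs_split_warning")
})

test_that("group summaries report mean, SD and normal-approximation CI", {
  gs <- group_summary(c(1, 2, 3), rep("g", 3))
  expect_equal(gs$mean, 2)
  expect_equal(gs$sd, 1)
  expect_equal(gs$ci_lower, 2 - 1.96 / sqrt(3))

  const <- group_summary(rep(5, 10), rep("g", 10))
  expect_equal(const$sd, 0)
  expect_equal(const$ci_lower, const$ci_upper)

  set.seed(703)
  big <- group_summary(rnorm(20000, 5.49, 3.59), rep("g", 20000))
  expect_equal(big$mean, 5.49, tolerance = 3 * 3.59 / sqrt(20000))

  expect_error(group_summary(1, "g"), class = "hs_summary_error")
})

test_that("the independent t-test matches the closed-form Welch statistic", {
  a <- c(19.8, 21.4, 18.9, 22.1, 20.3)
  b <- c(5.1, 6.4, 4.9, 7.2)
  res <- independent_t_test(a, b)
  # closed-form arithmetic oracle
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(res$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  expect_true(res$significant)

  same <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flat <- independent_t_test(rep(2, 5), rep(2, 6))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 1)

  set.seed(704)
  w <- independent_t_test(rnorm(200, 1.58, 1.00), rnorm(200, 6.50, 1.83))
  expect_true(w$significant)
})

test_that("subgroup analysis separates targeted injuries only", {
  set.seed(705)
  n <- 120
  sub <- rep(c("non-injury", "untargeted", "targeted"), each = n)
  feats <- data.frame(web3 = c(rnorm(n, 1.58, 1), rnorm(n, 1.58, 1),
                               rnorm(n, 6.50, 1.83)))
  res <- subgroup_analysis(feats, sub, feature_names = "web3")
  expect_equal(nrow(res), 3L)
  pick <- function(a, b) res[(res$group_a == a & res$group_b == b) |
                             (res$group_a == b & res$group_b == a), ]
  expect_false(pick("non-injury", "untargeted")$significant)
  expect_true(pick("non-injury", "targeted")$significant)
  expect_true(pick("untargeted", "targeted")$significant)

  empty <- subgroup_analysis(feats, sub, feature_names = character(0))
  expect_equal(nrow(empty), 0L)
  expect_error(subgroup_analysis(feats, rep("a", nrow(feats))),
               class = "hs_analysis_error")
})
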