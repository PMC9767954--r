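test_that("ROC curves match exhaustive threshold enumeration, ties included", {
  scores <- c(1, 2, 2, 3, 4, 5)
  pos <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  curve <- roc_curve(scores, pos)

  # brute-force oracle: classify score > t for every candidate cutoff
  cand <- curve$threshold
  oracle_tpr <- vapply(cand, function(t) mean(scores[pos] > t), numeric(1))
  oracle_fpr <- vapply(cand, function(t) mean(scores[!pos] > t), numeric(1))
  expect_equal(curve$tpr, oracle_tpr)
  expect_equal(curve$fpr, oracle_fpr)

  # endpoints present, both rates nondecreasing
  expect_equal(curve$tpr[1L], 0)
  expect_equal(curve$fpr[1L], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_true(all(diff(curve$tpr) >= 0) && all(diff(curve$fpr) >= 0))

  expect_error(roc_curve(1:5, rep(TRUE, 5)), class = "hs_calibration_error")
})

test_that("perfectly separated scores reach the (0, 1) ROC corner with AUC 1", {
  curve <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_equal(auc(curve), 1)
})

test_that("trapezoidal AUC equals the all-pairs concordance oracle", {
  set.seed(401)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    # integer scores force ties
    scores <- sample(1:6, n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(pos)) < 2) next
    expect_equal(auc(scores, pos), auc_bruteforce(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(402)
  scores <- rnorm(60)
  pos <- rep(c(TRUE, FALSE), 30)
  a <- auc(scores, pos)
  expect_equal(auc(exp(scores), pos), a, tolerance = 1e-12)
  expect_equal(auc(scores^3 + 5 * scores, pos), a, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(403)
  scores <- c(rnorm(80), rnorm(80, 1.2))
  pos <- rep(c(FALSE, TRUE), each = 80)
  expect_equal(auc(scores, pos),
               as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("label-independent scores give near-diagonal ROC", {
  set.seed(404)
  scores <- rnorm(4000)
  pos <- rep(c(TRUE, FALSE), 2000)
  expect_equal(auc(scores, pos), 0.5, tolerance = 0.03)
})

test_that("AUC filter keeps features at 0.8 and back-fills to the minimum count", {
  tab <- data.frame(feature = c("a", "b", "c", "d"), number = 1:4,
                    auc = c(0.95, 0.85, 0.80, 0.68))
  sel <- select_features(tab)
  expect_equal(sel$selected, c("a", "b", "c"))
  expect_equal(sel$rule_applied, "auc-filter")

  # only one survivor: back-fill by descending AUC
  tab2 <- data.frame(feature = c("a", "b", "c"), number = 1:3,
                     auc = c(0.9, 0.65, 0.66))
  sel2 <- select_features(tab2)
  expect_equal(sel2$selected, c("a", "c"))
  expect_equal(sel2$rule_applied, "minimum-two-fallback")

  # AUC tie in the back-fill breaks by ascending feature number
  tab3 <- data.frame(feature = c("a", "b", "c"), number = 1:3,
                     auc = c(0.9, 0.66, 0.66))
  expect_equal(select_features(tab3)$selected, c("a", "b"))

  expect_error(select_features(data.frame(feature = character(0),
                                          auc = numeric(0))),
               class = "hs_calibration_error")
})

test_that("Youden threshold sits midway between classes on separable data", {
  spec <- choose_threshold(roc_curve(c(1, 2), c(FALSE, TRUE)))
  expect_equal(spec$threshold, 1.5)
  expect_equal(spec$achieved_tpr, 1)
  expect_equal(spec$achieved_fpr, 0)

  # equal-variance binormal: the optimum is near the midpoint of the means
  set.seed(405)
  scores <- c(rnorm(20000, 0), rnorm(20000, 2))
  pos <- rep(c(FALSE, TRUE), each = 20000)
  spec2 <- choose_threshold(roc_curve(scores, pos), "youden")
  expect_equal(spec2$threshold, 1.0, tolerance = 0.1)

  # identical distributions: J is approximately zero at the optimum
  set.seed(406)
  s3 <- rnorm(4000)
  spec3 <- choose_threshold(roc_curve(s3, rep(c(TRUE, FALSE), 2000)), "youden")
  expect_lt(spec3$achieved_tpr - spec3$achieved_fpr, 0.08)
})

test_that("FPR-floor thresholds respect the floor or warn when degenerate", {
  set.seed(407)
  scores <- c(rnorm(500, 0), rnorm(500, 1.5))
  pos <- rep(c(FALSE, TRUE), each = 500)
  spec <- choose_threshold(roc_curve(scores, pos), "fpr_floor", fpr_floor = 0.02)
  expect_lte(spec$achieved_fpr, 0.02)
  expect_gt(spec$achieved_tpr, 0)

  # floor unreachable except at zero sensitivity: explicit degenerate spec
  s <- c(0, 1, 1, 1, 2)
  p <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  # all thresholds admitting the positive also admit a negative above floor 0
  expect_warning(
    spec2 <- choose_threshold(roc_curve(c(1, 1, 1, 0.5), c(TRUE, FALSE, FALSE, FALSE)),
                              "fpr_floor", fpr_floor = 0.01),
    class = "hs_degenerate_threshold")
  expect_true(spec2$degenerate)
  expect_equal(spec2$achieved_tpr, 0)
})
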