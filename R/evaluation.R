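# Performance metrics, stratified splitting, and statistical summaries.

#' Confusion matrix for binary screening predictions
#'
#' "Abnormal" is the positive class: TP counts abnormal gestures correctly
#' predicted abnormal, FP normal gestures wrongly predicted abnormal, FN
#' abnormal gestures wrongly predicted normal, TN normal gestures correctly
#' predicted normal.
#'
#' @param predictions Character vector of `"normal"`/`"abnormal"` (or
#'   logical, `TRUE` = abnormal).
#' @param truth Same-length truth labels (`"abnormal"`/`"normal"`, logical,
#'   or `"target"`/`"non-target"`).
#' @return An object of class `confusion_matrix` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    hs_error("predictions and truth must have equal length", "hs_evaluation_error")
  }
  as_pos <- function(x) {
    if (is.logical(x)) x else x %in% c("abnormal", "target", "TRUE")
  }
  p <- as_pos(predictions)
  t <- as_pos(truth)
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L,
              dimnames = list(truth = c("abnormal", "normal"),
                              predicted = c("abnormal", "normal")))
  print(m)
  invisible(x)
}

#' Screening metrics from a confusion matrix
#'
#' accuracy = (TP + TN) / (TP + FP + TN + FN) x 100%,
#' sensitivity = TP / (TP + FN) x 100%,
#' specificity = TN / (FP + TN) x 100%.
#' A metric whose denominator is zero is returned as `NA` and flagged in
#' `undefined`, never silently reported as zero.
#'
#' @param matrix A [confusion()] result, or a list with TP/FP/FN/TN.
#' @param model,gesture Optional identifiers carried into the report.
#' @return An object of class `metrics_report` with percentages (unrounded;
#'   the print method shows two decimals).
#' @export
metrics <- function(matrix, model = NA_character_, gesture = NA_character_) {
  m <- matrix
  total <- m$TP + m$FP + m$FN + m$TN
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- safe(m$TP + m$TN, total)
  sens <- safe(m$TP, m$TP + m$FN)
  spec <- safe(m$TN, m$FP + m$TN)
  undefined <- c(accuracy = total == 0, sensitivity = m$TP + m$FN == 0,
                 specificity = m$FP + m$TN == 0)
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 matrix = m, undefined = undefined, model = model,
                 gesture = gesture),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  hdr <- if (!is.na(x$model) || !is.na(x$gesture)) {
    sprintf(" (%s%s)", if (is.na(x$model)) "" else x$model,
            if (is.na(x$gesture)) "" else paste0(", ", x$gesture))
  } else ""
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("screening metrics%s: accuracy %s, sensitivity %s, specificity %s\n",
              hdr, fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity)))
  invisible(x)
}

#' Stratified train/test split
#'
#' Within each stratum the held-out fraction is `test_fraction` up to
#' integer rounding; the assignment is deterministic per seed, disjoint,
#' and exhaustive. A stratum with fewer than 2 members falls back to
#' training with a warning.
#'
#' @param labels Stratum labels, one per record.
#' @param test_fraction Held-out fraction (default 1/4, i.e. a ~3:1
#'   train:test ratio).
#' @param seed Integer seed.
#' @param unit Optional grouping vector (e.g. hand identifiers): all records
#'   of one unit stay on the same side of the split, and stratified sampling
#'   operates over units.
#' @return Character vector of `"train"`/`"test"` per record.
#' @export
stratified_split <- function(labels, test_fraction = 0.25, seed = 1L,
                             unit = NULL) {
  n <- length(labels)
  out <- rep("train", n)
  withr::with_seed(seed, {
    for (s in unique(labels)) {
      idx <- which(labels == s)
      if (is.null(unit)) {
        if (length(idx) < 2L) {
          hs_warning(sprintf("stratum '%s' has fewer than 2 records; kept in training", s),
                     "hs_split_warning")
          next
        }
        n_test <- round(length(idx) * test_fraction)
        out[sample(idx, n_test)] <- "test"
      } else {
        units <- unique(unit[idx])
        if (length(units) < 2L) {
          hs_warning(sprintf("stratum '%s' has fewer than 2 units; kept in training", s),
                     "hs_split_warning")
          next
        }
        n_test <- round(length(units) * test_fraction)
        test_units <- sample(units, n_test)
        out[idx][unit[idx] %in% test_units] <- "test"
      }
    }
  })
  out
}

#' Per-group mean, SD, and 95% confidence interval
#'
#' SD uses the n-1 denominator; the CI is the normal approximation
#' mean +/- 1.96 SD/sqrt(n) by default, or the t-quantile variant.
#'
#' @param values Numeric vector.
#' @param groups Group labels, one per value.
#' @param ci `"normal"` or `"t"`.
#' @return Data frame with `group`, `n`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper`.
#' @export
group_summary <- function(values, groups, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  out <- lapply(unique(groups), function(g) {
    x <- values[groups == g]
    n <- length(x)
    if (n < 2L) {
      hs_error(sprintf("group '%s' has fewer than 2 values", g), "hs_summary_error")
    }
    m <- mean(x)
    s <- sd(x)
    q <- if (ci == "normal") 1.96 else stats::qt(0.975, n - 1L)
    half <- q * s / sqrt(n)
    data.frame(group = g, n = n, mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Independent two-sample t-test
#'
#' Welch's unequal-variance test by default (the group SDs of the screening
#' features differ severalfold); the pooled-variance variant is available.
#' Two constant samples with equal means return t = 0, p = 1 with a flag.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param var_equal Use the pooled-variance test.
#' @param alpha Significance level for the `significant` flag.
#' @return List of class `hs_ttest` with `t`, `df`, `p`, `significant`,
#'   `degenerate`.
#' @export
independent_t_test <- function(a, b, var_equal = FALSE, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L) {
    hs_error("both groups need at least 2 values", "hs_summary_error")
  }
  res <- tryCatch(
    t.test(a, b, var.equal = var_equal),
    error = function(e) NULL
  )
  if (is.null(res)) {
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      return(structure(list(t = 0, df = NA_real_, p = 1, significant = FALSE,
                            degenerate = TRUE), class = "hs_ttest"))
    }
    hs_error("t-test failed on degenerate input with unequal means",
             "hs_summary_error")
  }
  structure(list(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, significant = res$p.value < alpha,
                 degenerate = FALSE),
            class = "hs_ttest")
}

#' Pairwise subgroup analysis of selected features
#'
#' For each feature, runs independent t-tests between all pairs of the three
#' clinical subgroups (non-injury, untargeted injury, targeted injury).
#' Consistency with the anatomical rationale means the untargeted-injury vs
#' non-injury pair is mostly non-significant while any pair involving the
#' targeted injury separates. No multiple-testing correction is applied;
#' each test is reported marginally at `alpha`.
#'
#' @param features Feature data frame.
#' @param subgroups Subgroup label per row; exactly three distinct values
#'   expected, e.g. `"non-injury"`, `"untargeted"`, `"targeted"`.
#' @param feature_names Features to analyze (default: all feature columns
#'   present in the registry).
#' @param ... Passed to [independent_t_test()].
#' @return Data frame with `feature`, `group_a`, `group_b`, `t`, `p`,
#'   `significant`.
#' @export
subgroup_analysis <- function(features, subgroups, feature_names = NULL, ...) {
  lv <- unique(subgroups)
  if (length(lv) != 3L) {
    hs_error("subgroup analysis expects exactly three subgroups present",
             "hs_analysis_error")
  }
  feature_names <- feature_names %||%
    intersect(feature_registry()$name, names(features))
  pairs <- combn(lv, 2L, simplify = FALSE)
  rows <- list()
  for (f in feature_names) {
    for (pr in pairs) {
      tt <- independent_t_test(features[[f]][subgroups == pr[1L]],
                               features[[f]][subgroups == pr[2L]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group_a = pr[1L], group_b = pr[2L],
        t = tt$t, p = tt$p, significant = tt$significant,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(feature = character(0), group_a = character(0),
                      group_b = character(0), t = numeric(0), p = numeric(0),
                      significant = logical(0)))
  }
  do.call(rbind, rows)
}
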