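# ROC construction, AUC, AUC-filtered feature selection, and threshold
# choice. All features are oriented "greater = more abnormal" by the sign
# conventions of the feature extractor, so every ROC is built in the
# greater-is-positive direction.

#' Empirical ROC curve
#'
#' One curve point per distinct score plus the (0, 0) endpoint. Candidate
#' thresholds are placed midway between adjacent distinct scores (the
#' extreme thresholds extend half a step beyond the observed range), so a
#' strict `score > threshold` decision is unambiguous on ties.
#'
#' @param scores Numeric scores, larger = more abnormal.
#' @param labels Group labels; `positive` marks the target class.
#' @param positive Value of `labels` treated as positive (default
#'   `"target"`; logical labels use `TRUE`).
#' @return A data frame of class `hs_roc` with columns `threshold`, `tpr`,
#'   `fpr`, ordered by decreasing threshold, and attributes `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = if (is.logical(labels)) TRUE else "target") {
  if (length(scores) != length(labels)) {
    hs_error("scores and labels must have equal length", "hs_calibration_error")
  }
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  pos <- labels[keep] == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    hs_error("ROC requires both classes present", "hs_calibration_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # last index of each tie block of distinct score values
  last <- which(c(s[-1L] != s[-length(s)], TRUE))
  v <- s[last]
  tpr <- cumsum(p)[last] / n_pos
  fpr <- cumsum(!p)[last] / n_neg
  gap_hi <- if (length(v) > 1L) v[1L] - v[2L] else 1
  gap_lo <- if (length(v) > 1L) v[length(v) - 1L] - v[length(v)] else 1
  thr <- c(v[1L] + gap_hi / 2,
           if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2,
           v[length(v)] - gap_lo / 2)
  out <- data.frame(threshold = thr, tpr = c(0, tpr), fpr = c(0, fpr))
  structure(out, class = c("hs_roc", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under an [roc_curve()]. Because curve points are grouped
#' by distinct score value, the trapezoid rule across tie blocks is exactly
#' the rank-statistic (concordance) formulation with half credit for tied
#' pairs. AUC of 0.5 means no separation; above 0.8 is conventionally read
#' as very good and above 0.9 as excellent discrimination.
#'
#' @param x An `hs_roc` curve, or raw scores (with `labels` supplied).
#' @param ... Passed to [roc_curve()] when `x` is a score vector.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.hs_roc <- function(x, ...) {
  f <- x$fpr
  t <- x$tpr
  # append the (1, 1) endpoint (always present as the final tie block)
  sum(diff(f) * (t[-1L] + t[-length(t)]) / 2)
}

#' @rdname auc
#' @param labels Labels as in [roc_curve()].
#' @export
auc.default <- function(x, labels, ...) {
  auc(roc_curve(x, labels, ...))
}

#' AUC table for a gesture's feature block
#'
#' @param features Feature data frame (one column per feature).
#' @param labels Group labels (`"target"` / `"non-target"` or logical).
#' @param gesture Restrict to this gesture's registered features (optional).
#' @return Data frame with `feature`, `number`, `auc`, `n_target`,
#'   `n_nontarget`.
#' @export
feature_aucs <- function(features, labels, gesture = NULL) {
  reg <- feature_registry()
  if (!is.null(gesture)) reg <- reg[reg$gesture == gesture, , drop = FALSE]
  reg <- reg[reg$name %in% names(features), , drop = FALSE]
  if (nrow(reg) == 0L) {
    hs_error("no registered features found among the supplied columns",
             "hs_calibration_error")
  }
  pos <- labels == (if (is.logical(labels)) TRUE else "target")
  data.frame(
    feature = reg$name,
    number = reg$number,
    auc = vapply(reg$name, function(f) auc(features[[f]], pos), numeric(1L)),
    n_target = sum(pos),
    n_nontarget = sum(!pos),
    row.names = NULL
  )
}

#' AUC-filtered feature selection with a minimum-count fallback
#'
#' Keeps every feature with AUC at or above `min_auc` (default 0.8, the
#' "very good" discrimination cutoff). If fewer than `min_count` survive the
#' filter, the highest-AUC remaining features are back-filled until
#' `min_count` is reached, so each gesture model always has at least two
#' classifiers. Ties are broken deterministically by ascending feature
#' number.
#'
#' @param aucs Data frame with columns `feature`, `auc`, and optionally
#'   `number` (defaults to row order).
#' @param min_auc AUC filter cutoff.
#' @param min_count Minimum number of selected features.
#' @param gesture Optional gesture tag stored in the result.
#' @return List of class `hs_selection` with elements `gesture`, `selected`
#'   (feature names in ascending feature-number order), and `rule_applied`
#'   (`"auc-filter"` or `"minimum-two-fallback"`).
#' @export
select_features <- function(aucs, min_auc = 0.8, min_count = 2L, gesture = NULL) {
  if (is.null(aucs) || nrow(aucs) == 0L) {
    hs_error("empty AUC table", "hs_calibration_error")
  }
  number <- aucs$number %||% seq_len(nrow(aucs))
  keep <- aucs$auc >= min_auc - 1e-12
  rule <- "auc-filter"
  if (sum(keep) < min_count) {
    rule <- "minimum-two-fallback"
    rest <- which(!keep)
    rest <- rest[order(-aucs$auc[rest], number[rest])]
    need <- min(min_count - sum(keep), length(rest))
    keep[rest[seq_len(need)]] <- TRUE
  }
  sel <- which(keep)
  sel <- sel[order(number[sel])]
  structure(list(gesture = gesture, selected = aucs$feature[sel],
                 rule_applied = rule),
            class = "hs_selection")
}

#' Choose a decision threshold from a ROC curve
#'
#' Two criteria are supported:
#' * `"youden"`: maximizes Youden's J = TPR - FPR, with ties broken toward
#'   higher specificity (then toward the higher threshold).
#' * `"fpr_floor"`: the highest-sensitivity threshold whose training FPR
#'   does not exceed `fpr_floor`. Conservative per-feature cutoffs suit an
#'   OR-ensemble, whose false-positive rates accumulate across classifiers.
#'
#' Thresholds always sit midway between adjacent distinct scores, never on
#' an observed value.
#'
#' @param curve An `hs_roc` curve from [roc_curve()].
#' @param criterion `"youden"` or `"fpr_floor"`.
#' @param fpr_floor Maximum tolerated FPR for the `"fpr_floor"` criterion.
#' @param feature Optional feature name carried into the result.
#' @return List of class `hs_threshold` with `feature`, `threshold`,
#'   `criterion`, `achieved_tpr`, `achieved_fpr`, and `degenerate` (`TRUE`
#'   when the floor is only achievable at zero sensitivity).
#' @export
choose_threshold <- function(curve, criterion = c("youden", "fpr_floor"),
                             fpr_floor = 0.02, feature = NA_character_) {
  criterion <- match.arg(criterion)
  if (!inherits(curve, "hs_roc")) {
    hs_error("curve must be an hs_roc object", "hs_calibration_error")
  }
  degenerate <- FALSE
  if (criterion == "youden") {
    j <- curve$tpr - curve$fpr
    best <- which(j > max(j) - 1e-12)
    best <- best[order(curve$fpr[best], -curve$threshold[best])][1L]
  } else {
    ok <- which(curve$fpr <= fpr_floor + 1e-12)
    best <- ok[order(-curve$tpr[ok], curve$fpr[ok])][1L]
    if (curve$tpr[best] == 0) {
      degenerate <- TRUE
      hs_warning(sprintf("FPR floor %.3f only achievable at zero sensitivity%s",
                         fpr_floor,
                         if (is.na(feature)) "" else sprintf(" for feature '%s'", feature)),
                 "hs_degenerate_threshold")
    }
  }
  structure(list(feature = feature, threshold = curve$threshold[best],
                 criterion = criterion, achieved_tpr = curve$tpr[best],
                 achieved_fpr = curve$fpr[best], degenerate = degenerate),
            class = "hs_threshold")
}
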