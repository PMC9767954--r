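# The rule-based expert classifier: per gesture, an OR-ensemble of
# thresholded single-feature classifiers. A record is predicted abnormal --
# screened positive for the gesture's target nerve -- as soon as any
# selected feature strictly exceeds its calibrated threshold; it is normal
# only when every classifier stays at or below threshold.

#' Fit a rule-based gesture model
#'
#' Composes AUC-filtered feature selection ([select_features()]) with
#' per-feature ROC threshold calibration ([choose_threshold()]) on a
#' training set.
#'
#' @param features Training feature data frame (columns include the
#'   gesture's registered features).
#' @param labels Training group labels (`"target"`/`"non-target"` or
#'   logical, `TRUE` = target).
#' @param gesture `"G1"`, `"G2"`, or `"G3"`.
#' @param criterion Threshold criterion, `"youden"` (default) or
#'   `"fpr_floor"`.
#' @param fpr_floor Per-feature FPR ceiling for the `"fpr_floor"` criterion.
#' @param min_auc,min_count Selection parameters, see [select_features()].
#' @return An object of class `rule_model`: gesture, target nerve, the
#'   selection result, a classifier table (feature, threshold, achieved
#'   training TPR/FPR), and the full AUC table.
#' @export
fit_rule_model <- function(features, labels, gesture,
                           criterion = c("youden", "fpr_floor"),
                           fpr_floor = 0.02, min_auc = 0.8, min_count = 2L) {
  criterion <- match.arg(criterion)
  pos <- labels == (if (is.logical(labels)) TRUE else "target")
  if (length(unique(pos)) < 2L) {
    hs_error("rule-model fit requires both target and non-target records",
             "hs_fit_error")
  }
  aucs <- feature_aucs(features, labels, gesture = gesture)
  selection <- select_features(aucs, min_auc = min_auc, min_count = min_count,
                               gesture = gesture)
  classifiers <- do.call(rbind, lapply(selection$selected, function(f) {
    spec <- choose_threshold(roc_curve(features[[f]], labels),
                             criterion = criterion, fpr_floor = fpr_floor,
                             feature = f)
    data.frame(feature = f, threshold = spec$threshold,
               achieved_tpr = spec$achieved_tpr,
               achieved_fpr = spec$achieved_fpr,
               degenerate = spec$degenerate, stringsAsFactors = FALSE)
  }))
  structure(list(gesture = gesture,
                 target_injury = gesture_target_nerve(gesture),
                 classifiers = classifiers, criterion = criterion,
                 fpr_floor = if (criterion == "fpr_floor") fpr_floor else NA_real_,
                 selection = selection, auc_table = aucs),
            class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("<rule_model %s: screens for %s nerve injury, %d classifiers (%s), OR-ensemble>\n",
              x$gesture, x$target_injury, nrow(x$classifiers), x$criterion))
  print(x$classifiers, row.names = FALSE)
  invisible(x)
}

#' Predict normal/abnormal with a rule model
#'
#' A record is `"abnormal"` iff any selected feature value strictly exceeds
#' its threshold; values exactly at a threshold count as normal. Prediction
#' is a pure function of the model and the feature values and is monotone:
#' increasing any feature can never turn an abnormal record normal.
#'
#' @param object A `rule_model`.
#' @param newdata Named numeric vector (one record) or a data frame with the
#'   model's feature columns.
#' @param detail If `TRUE`, also return which classifiers fired per record.
#' @param ... Unused.
#' @return Character vector of `"normal"`/`"abnormal"`, one per record;
#'   with `detail = TRUE`, a data frame with per-classifier firing flags and
#'   the final `prediction`.
#' @export
predict.rule_model <- function(object, newdata, detail = FALSE, ...) {
  feats <- object$classifiers$feature
  if (is.vector(newdata) && !is.list(newdata)) {
    newdata <- as.data.frame(as.list(newdata))
  }
  missing <- setdiff(feats, names(newdata))
  if (length(missing) > 0L) {
    hs_error(sprintf("prediction requires feature(s) missing from input: %s",
                     paste(missing, collapse = ", ")),
             "hs_prediction_error")
  }
  vals <- as.matrix(newdata[, feats, drop = FALSE])
  if (nrow(vals) > 0L && !all(is.finite(vals))) {
    hs_error("non-finite feature values in prediction input", "hs_prediction_error")
  }
  fired <- sweep(vals, 2L, object$classifiers$threshold, `>`)
  pred <- ifelse(rowSums(fired) > 0L, "abnormal", "normal")
  if (!detail) {
    return(unname(pred))
  }
  out <- as.data.frame(fired)
  names(out) <- paste0("fired_", feats)
  out$prediction <- unname(pred)
  out
}

#' Predict a cohort feature table, preserving record order
#'
#' @param model A `rule_model`.
#' @param features Feature data frame carrying a `gesture` column (or
#'   attribute) matching the model's gesture.
#' @return Character vector of predictions, one per row.
#' @export
predict_batch <- function(model, features) {
  g <- features$gesture %||% attr(features, "gesture")
  if (!is.null(g) && nrow(features) > 0L && !all(g == model$gesture)) {
    hs_error(sprintf("gesture mismatch: model is %s but records include %s",
                     model$gesture, paste(setdiff(unique(g), model$gesture), collapse = ", ")),
             "hs_prediction_error")
  }
  if (nrow(features) == 0L) {
    return(character(0))
  }
  predict(model, features)
}

#' Serialize a rule model to JSON
#'
#' @param model A `rule_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_model <- function(model, path) {
  payload <- list(gesture = model$gesture, target_injury = model$target_injury,
                  criterion = model$criterion, fpr_floor = model$fpr_floor,
                  selection_rule = model$selection$rule_applied,
                  classifiers = model$classifiers, auc_table = model$auc_table)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rule model serialized by [write_rule_model()]
#'
#' @param path JSON path.
#' @return A `rule_model`.
#' @export
read_rule_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(list(gesture = p$gesture, target_injury = p$target_injury,
                 classifiers = p$classifiers, criterion = p$criterion,
                 fpr_floor = p$fpr_floor %||% NA_real_,
                 selection = structure(list(gesture = p$gesture,
                                            selected = p$classifiers$feature,
                                            rule_applied = p$selection_rule),
                                       class = "hs_selection"),
                 auc_table = p$auc_table),
            class = "rule_model")
}
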