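# End-to-end screening study: fit per-gesture models on the training split,
# evaluate on the held-out split.

#' Run the full screening study on a synthetic (or imported) cohort
#'
#' For each gesture task, fits the rule-based model (and optionally the
#' three ML baselines) on the training split and evaluates accuracy,
#' sensitivity, and specificity on the held-out test split.
#'
#' @param cohort A `synthetic_cohort` from [build_study_cohort()], or a
#'   named list of per-gesture feature tables with `group` and `split`
#'   columns.
#' @param criterion Rule-model threshold criterion (`"youden"` or
#'   `"fpr_floor"`).
#' @param fpr_floor Per-feature FPR ceiling for `"fpr_floor"`.
#' @param with_ml Also fit the logistic-regression, SVM, and random-forest
#'   baselines.
#' @param seed Seed for the ML fits.
#' @return A list with `models` (per gesture) and `report`, a data frame of
#'   one row per (model, gesture) with the confusion counts and metrics.
#' @export
run_screening_study <- function(cohort, criterion = c("youden", "fpr_floor"),
                                fpr_floor = 0.02, with_ml = FALSE, seed = 1L) {
  criterion <- match.arg(criterion)
  features <- if (inherits(cohort, "synthetic_cohort")) cohort$features else cohort
  models <- list()
  rows <- list()
  for (g in names(features)) {
    f <- features[[g]]
    tr <- f[f$split == "train", , drop = FALSE]
    te <- f[f$split == "test", , drop = FALSE]
    rule <- fit_rule_model(tr, tr$group, g, criterion = criterion,
                           fpr_floor = fpr_floor)
    fitted <- list(rule_based = rule)
    preds <- list(rule_based = predict_batch(rule, te))
    if (with_ml) {
      for (fam in c("logistic", "svm", "rf")) {
        m <- fit_ml(tr, tr$group, ml_spec(fam, seed = derive_seed(seed, match(fam, c("logistic", "svm", "rf")))))
        fitted[[fam]] <- m
        preds[[fam]] <- predict(m, te)
      }
    }
    models[[g]] <- fitted
    for (nm in names(preds)) {
      cm <- confusion(preds[[nm]], te$group == "target")
      mr <- metrics(cm, model = nm, gesture = g)
      rows[[length(rows) + 1L]] <- data.frame(
        gesture = g, model = nm, TP = cm$TP, FP = cm$FP, FN = cm$FN, TN = cm$TN,
        accuracy = mr$accuracy, sensitivity = mr$sensitivity,
        specificity = mr$specificity, stringsAsFactors = FALSE)
    }
  }
  list(models = models, report = do.call(rbind, rows))
}
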