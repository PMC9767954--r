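# Machine-learning baselines: logistic regression (ridge), support vector
# machine, and random forest, trained on all predetermined features of a
# gesture with training-set standardization and seeded 5-fold grid-search
# cross-validation.

default_grid <- function(family) {
  switch(family,
    logistic = data.frame(lambda = c(1, 0.1, 0.01, 0.001)),
    svm = expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    rf = expand.grid(ntree = c(200L, 500L), mtry_frac = c(0.33, 0.6))
  )
}

#' Specification of an ML baseline model
#'
#' @param family `"logistic"`, `"svm"`, or `"rf"`.
#' @param grid Hyperparameter grid data frame (one column per parameter);
#'   defaults to a small conventional grid per family.
#' @param cv_folds Cross-validation folds (default 5).
#' @param standardize Standardize features using training-fold statistics.
#' @param seed Integer seed controlling fold assignment and stochastic fits.
#' @return An `ml_spec` list.
#' @export
ml_spec <- function(family = c("logistic", "svm", "rf"), grid = NULL,
                    cv_folds = 5L, standardize = TRUE, seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, grid = grid %||% default_grid(family),
                 cv_folds = as.integer(cv_folds), standardize = standardize,
                 seed = as.integer(seed)),
            class = "ml_spec")
}

fit_family <- function(family, x, y, params, seed) {
  withr::with_seed(seed, switch(
    family,
    logistic = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                              lambda = params$lambda, standardize = FALSE),
    svm = e1071::svm(x, y, kernel = params$kernel, cost = params$cost,
                     scale = FALSE),
    rf = randomForest::randomForest(
      x, y, ntree = params$ntree,
      mtry = max(1L, floor(params$mtry_frac * ncol(x))))
  ))
}

predict_family <- function(family, fit, x) {
  if (family == "logistic") {
    as.vector(predict(fit, newx = x, type = "response") > 0.5)
  } else {
    predict(fit, x) == "TRUE"
  }
}

#' Fit an ML baseline with grid-searched hyperparameters
#'
#' Standardizes the features (training statistics only), runs a seeded
#' stratified 5-fold cross-validated grid search, refits the best grid row
#' on the full training set, and retains the CV table. Everything is
#' deterministic for a fixed spec seed.
#'
#' @param features Training feature data frame (all predetermined features
#'   of the gesture).
#' @param labels `"target"`/`"non-target"` (or logical) training labels.
#' @param spec An [ml_spec()].
#' @return An `ml_model` handle with the fitted model, the scaling, the CV
#'   table, and the chosen hyperparameters.
#' @export
fit_ml <- function(features, labels, spec = ml_spec()) {
  feats <- intersect(feature_registry()$name, names(features))
  x <- as.matrix(features[, feats, drop = FALSE])
  pos <- labels == (if (is.logical(labels)) TRUE else "target")
  if (length(unique(pos)) < 2L) {
    hs_error("ML fit requires both classes present", "hs_fit_error")
  }
  if (min(sum(pos), sum(!pos)) < spec$cv_folds) {
    hs_error(sprintf("smallest class has %d records, fewer than the %d CV folds; reduce cv_folds in ml_spec()",
                     min(sum(pos), sum(!pos)), spec$cv_folds),
             "hs_fit_error")
  }
  center <- if (spec$standardize) colMeans(x) else rep(0, ncol(x))
  scale_ <- if (spec$standardize) {
    s <- apply(x, 2L, sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(x))
  xs <- scale(x, center = center, scale = scale_)
  y <- factor(pos, levels = c(FALSE, TRUE))

  # stratified fold assignment, fixed by the spec seed
  folds <- integer(nrow(xs))
  withr::with_seed(derive_seed(spec$seed, 17L), {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(pos == cl)
      folds[idx] <- sample(rep(seq_len(spec$cv_folds), length.out = length(idx)))
    }
  })

  grid <- spec$grid
  cv_acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    correct <- 0L
    for (k in seq_len(spec$cv_folds)) {
      tr <- folds != k
      fit <- fit_family(spec$family, xs[tr, , drop = FALSE], y[tr], params,
                        derive_seed(spec$seed, 1000L * gi + k))
      pred <- predict_family(spec$family, fit, xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == pos[!tr])
    }
    cv_acc[gi] <- correct / nrow(xs)
  }
  best <- which.max(cv_acc)
  final <- fit_family(spec$family, xs, y, as.list(grid[best, , drop = FALSE]),
                      derive_seed(spec$seed, 99L))
  structure(list(family = spec$family, fit = final, features = feats,
                 center = center, scale = scale_,
                 cv_table = cbind(grid, cv_accuracy = cv_acc),
                 best = as.list(grid[best, , drop = FALSE]), spec = spec),
            class = "ml_model")
}

#' Predict with a fitted ML baseline
#'
#' @param object An `ml_model` from [fit_ml()].
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @return Character vector of `"normal"`/`"abnormal"` predictions.
#' @export
predict.ml_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  pos <- predict_family(object$family, object$fit, xs)
  ifelse(pos, "abnormal", "normal")
}

#' Feature weight / importance report
#'
#' Absolute standardized coefficients for the linear families (logistic
#' regression and linear-kernel SVM), impurity importances normalized to
#' sum 1 for the random forest, sorted descending.
#'
#' @param handle An `ml_model` from [fit_ml()].
#' @return Data frame of class `importance_report` with `feature`, `weight`,
#'   sorted by decreasing weight, and attribute `"family"`.
#' @export
importance_report <- function(handle) {
  if (!inherits(handle, "ml_model")) {
    hs_error("importance_report needs a fitted ml_model handle", "hs_state_error")
  }
  w <- switch(handle$family,
    logistic = {
      cf <- as.numeric(coef(handle$fit, s = handle$best$lambda))[-1L]
      abs(cf)
    },
    svm = {
      if (handle$best$kernel != "linear") {
        hs_error("coefficient-based importance requires a linear SVM kernel; the selected kernel is radial",
                 "hs_state_error")
      }
      abs(as.vector(t(handle$fit$coefs) %*% handle$fit$SV))
    },
    rf = {
      imp <- randomForest::importance(handle$fit)[, 1L]
      imp <- pmax(imp, 0)
      if (sum(imp) > 0) imp / sum(imp) else imp
    })
  out <- data.frame(feature = handle$features, weight = unname(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("importance_report", "data.frame"),
            family = handle$family)
}
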