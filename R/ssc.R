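#' Semi-supervised self-training classifier
#'
#' Yarowsky-style self-training around a random-forest base learner. The
#' forest is first fitted on the labelled samples; the unlabelled pool is
#' then scored, and at each iteration the most confident predictions (at
#' most `batch_fraction` of the initial pool, each with class-maximum
#' probability at or above `confidence_floor`) are moved into the training
#' set with their predicted pseudo-labels and the forest is refitted. The
#' loop stops when `stop_fraction` of the initial pool has been consumed,
#' `max_iter` is reached, or no sample qualifies. Original labels are never
#' removed or flipped. With the same seed and inputs the result is
#' bit-identical across runs.
#'
#' @param x A normalised `feature_matrix` (or plain matrix) containing at
#'   least the config's features.
#' @param status Per-sample status: `"positive"`, `"negative"`,
#'   `"unknown"` (unknowns form the unlabelled pool).
#' @param config A [model_config()].
#' @return An `hrd_classifier`: the fitted ensemble, the config, a training
#'   log of pseudo-labels added per iteration, feature importances, and an
#'   (initially NA) decision threshold.
#' @export
self_train <- function(x, status, config) {
  xm <- model_matrix_for(x, config$features)
  status <- as.character(status)
  stopifnot(length(status) == nrow(xm))
  lab <- which(status %in% c("positive", "negative"))
  unl <- which(status == "unknown")
  y <- factor(status[lab], levels = c("negative", "positive"))
  if (any(table(y) == 0)) stop("a labelled class is empty")
  if (all(apply(xm, 2, function(v) all(v == v[1]))))
    stop("all features are constant")
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(xm)))) else config$mtry
  fit_rf <- function(xx, yy)
    randomForest::randomForest(xx, yy, ntree = config$n_trees, mtry = mtry,
                               nodesize = config$min_node,
                               importance = config$importance_mode == "permutation")
  set.seed(config$seed)
  fit <- fit_rf(xm[lab, , drop = FALSE], y)
  pool <- unl
  n0 <- length(pool)
  train_idx <- lab
  train_y <- y
  log <- list()
  iter <- 0
  consumed <- 0
  while (length(pool) > 0 && consumed < config$stop_fraction * n0 &&
         iter < config$max_iter) {
    iter <- iter + 1
    pr <- stats::predict(fit, xm[pool, , drop = FALSE], type = "prob")
    conf <- apply(pr, 1, max)
    pred_cls <- colnames(pr)[max.col(pr, ties.method = "first")]
    # pseudo-labels are added in proportion to the labelled class
    # distribution, guarding against class drift over the iterations
    batch_n <- max(1, ceiling(config$batch_fraction * n0))
    prop_pos <- mean(y == "positive")
    quota <- c(negative = batch_n - round(batch_n * prop_pos),
               positive = round(batch_n * prop_pos))
    take <- integer(0)
    for (cl in levels(y)) {
      ok <- which(conf >= config$confidence_floor & pred_cls == cl)
      if (length(ok) == 0) next
      ok <- ok[order(-pr[ok, cl], seq_along(ok))]
      take <- c(take, ok[seq_len(min(quota[cl], length(ok)))])
    }
    if (length(take) == 0) break
    pseudo <- factor(pred_cls[take], levels = levels(y))
    train_idx <- c(train_idx, pool[take])
    train_y <- factor(c(as.character(train_y), as.character(pseudo)),
                      levels = levels(y))
    log[[iter]] <- data.frame(iteration = iter, added = length(take),
                              positive = sum(pseudo == "positive"),
                              negative = sum(pseudo == "negative"))
    pool <- pool[-take]
    consumed <- consumed + length(take)
    fit <- fit_rf(xm[train_idx, , drop = FALSE], train_y)
  }
  structure(list(model = fit, config = config, features = config$features,
                 threshold = NA_real_, norm_params = NULL,
                 n_labelled = length(lab), n_pseudo = consumed,
                 training_log = if (length(log)) do.call(rbind, log) else
                   data.frame(iteration = integer(0), added = integer(0),
                              positive = integer(0), negative = integer(0))),
            class = "hrd_classifier")
}

model_matrix_for <- function(x, features) {
  xm <- unclass(x)
  missing_feat <- setdiff(features, colnames(xm))
  if (length(missing_feat) > 0)
    stop("missing feature column(s): ", paste(missing_feat, collapse = ", "))
  xm[, features, drop = FALSE]
}

#' @export
print.hrd_classifier <- function(x, ...) {
  cat(sprintf("hrd_classifier '%s': %d features, %d labelled + %d pseudo, %s\n",
              x$config$model_id, length(x$features), x$n_labelled, x$n_pseudo,
              if (is.na(x$threshold)) "uncalibrated"
              else sprintf("threshold %.3f", x$threshold)))
  invisible(x)
}

#' Predict HRD probability and call
#'
#' Returns the positive-class probability and, when the classifier carries
#' a calibrated threshold, the thresholded call. Calls at exactly the
#' threshold are positive (`>=` convention). Feature columns are bound by
#' name, so column order is irrelevant.
#'
#' @param object An `hrd_classifier`.
#' @param newdata A `feature_matrix` (or matrix) containing all model
#'   features.
#' @param ... Unused.
#' @return Data frame with `sample_id`, `probability` and (if calibrated)
#'   logical `call`.
#' @export
predict.hrd_classifier <- function(object, newdata, ...) {
  xm <- model_matrix_for(newdata, object$features)
  pr <- stats::predict(object$model, xm, type = "prob")[, "positive"]
  out <- data.frame(sample_id = rownames(xm), probability = as.numeric(pr),
                    stringsAsFactors = FALSE)
  if (!is.na(object$threshold)) out$call <- out$probability >= object$threshold
  out
}

#' Leave-one-out cross-validated probabilities
#'
#' For each labelled sample the classifier is retrained without it (with
#' all unknown-status samples still available as the unlabelled pool) and
#' the held-out sample is scored. Probabilities are returned in the input
#' order of the labelled samples. Deterministic: fold `i` uses seed
#' `config$seed + i`.
#'
#' @inheritParams self_train
#' @return Data frame `sample_id`, `status`, `probability` for the
#'   labelled samples.
#' @export
loocv_probabilities <- function(x, status, config) {
  status <- as.character(status)
  lab <- which(status %in% c("positive", "negative"))
  probs <- numeric(length(lab))
  for (k in seq_along(lab)) {
    i <- lab[k]
    cfg <- config
    cfg$seed <- config$seed + k
    st <- status
    st_train <- st[-i]
    clf <- self_train(unclass(x)[-i, , drop = FALSE], st_train, cfg)
    probs[k] <- predict(clf, unclass(x)[i, , drop = FALSE])$probability
  }
  data.frame(sample_id = rownames(x)[lab], status = status[lab],
             probability = probs, stringsAsFactors = FALSE)
}

#' F1-optimal decision threshold
#'
#' Scans candidate thresholds at the midpoints between consecutive sorted
#' unique probabilities, plus the 0 and 1 boundaries, computing the F1
#' score of the positive class under the `probability >= threshold`
#' convention, and returns the candidate with the maximum F1 (ties: the
#' smallest threshold).
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param status `"positive"` / `"negative"` per sample.
#' @return A list: `threshold`, `f1`.
#' @export
optimal_threshold <- function(probabilities, status) {
  status <- as.character(status)
  keep <- status %in% c("positive", "negative")
  p <- probabilities[keep]; s <- status[keep]
  if (length(unique(s)) < 2) stop("both classes must be present")
  u <- sort(unique(p))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  f1 <- vapply(cand, function(t) f1_score(p >= t, s == "positive"), numeric(1))
  best <- which.max(f1)  # which.max takes the first (= smallest) on ties
  list(threshold = cand[best], f1 = f1[best])
}

f1_score <- function(call, truth) {
  tp <- sum(call & truth); fp <- sum(call & !truth); fn <- sum(!call & truth)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Calibrate a classifier's threshold by LOOCV
#'
#' Runs [loocv_probabilities()] and [optimal_threshold()] and stores the
#' result on the classifier.
#'
#' @inheritParams self_train
#' @param classifier An `hrd_classifier` trained with `config` on `x`.
#' @return The classifier with `threshold` set (and the LOOCV table in
#'   `loocv`).
#' @export
calibrate_threshold <- function(classifier, x, status) {
  cv <- loocv_probabilities(x, status, classifier$config)
  thr <- optimal_threshold(cv$probability, cv$status)
  classifier$threshold <- thr$threshold
  classifier$loocv <- cv
  classifier
}

#' Feature importance scores
#'
#' Importance of each model feature from the fitted forest: mean decrease
#' in Gini impurity (default) or permutation-based mean decrease in
#' accuracy, reported sorted decreasingly.
#'
#' @param classifier An `hrd_classifier`.
#' @return Named numeric vector, sorted decreasingly.
#' @export
feature_importance <- function(classifier) {
  imp <- randomForest::importance(classifier$model)
  v <- imp[, ncol(imp)]
  if (classifier$config$importance_mode == "permutation" &&
      "MeanDecreaseAccuracy" %in% colnames(imp))
    v <- imp[, "MeanDecreaseAccuracy"]
  sort(v, decreasing = TRUE)
}
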