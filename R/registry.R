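#' Model registry
#'
#' The five primary model configurations -- CNA, ASCN, SNV, SNV+CNA and
#' SNV+ASCN, with 9, 14, 16, 25 and 30 features respectively -- plus two
#' auxiliary configurations used for comparison: `no_scarHRD` (the ASCN
#' model without the scarHRD score) and `scarHRD_only`. Feature lists are
#' the package's defaults and can be overridden per model. The published
#' decision thresholds (0.382, 0.450, 0.344, 0.296, 0.374 for the five
#' primary models) are recorded as reference metadata, not used as
#' defaults: a threshold is always calibrated on the data at hand.
#'
#' @param overrides Named list mapping model id to a replacement feature
#'   character vector.
#' @return Named list of `model_config` objects.
#' @export
model_registry <- function(overrides = NULL) {
  cna9 <- c("cna_burden", "cna_load", "macn", "td_score",
            "chromothripsis_score", "CX1", "CX2", "CX3", "CX5")
  ascn5 <- c("scarHRD", "CN1", "CN2", "CN9", "CN17")
  snv16 <- c("SBS1", "SBS3", "SBS5", "SBS8", "SBS13", "SBS17b", "SBS18",
             "SBS26", "SBS30", "ID1", "ID2", "ID4", "ID6", "ID8", "ID9",
             "ID15")
  feats <- list(
    "CNA" = cna9,
    "ASCN" = c(cna9, ascn5),
    "SNV" = snv16,
    "SNV+CNA" = c(snv16, cna9),
    "SNV+ASCN" = c(snv16, cna9, ascn5),
    "no_scarHRD" = c(cna9, setdiff(ascn5, "scarHRD")),
    "scarHRD_only" = "scarHRD")
  ref_thr <- c("CNA" = 0.382, "ASCN" = 0.450, "SNV" = 0.344,
               "SNV+CNA" = 0.296, "SNV+ASCN" = 0.374)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(feats))
    if (length(bad) > 0) stop("unknown model id(s): ", paste(bad, collapse = ", "))
    feats[names(overrides)] <- overrides
  }
  out <- lapply(names(feats), function(id)
    model_config(id, features = feats[[id]],
                 reference_threshold = unname(ref_thr[id])))
  names(out) <- names(feats)
  out
}

#' Model configuration
#'
#' Bundles a feature list with the random-forest and self-training
#' controls. The self-training defaults (confidence floor 0.5 on the
#' class-maximum probability, 10% of the initial unlabelled pool per
#' iteration, stop after 70% of the pool is consumed, at most 40
#' iterations) follow common self-training practice and are all
#' configurable. Forest defaults: 500 trees, `mtry = floor(sqrt(p))`,
#' minimum node size 1, no class rebalancing (class imbalance is handled
#' by the calibrated threshold, not by resampling).
#'
#' @param model_id Identifier (free-form; registry ids listed in
#'   [model_registry()]).
#' @param features Character vector of feature names.
#' @param n_trees,mtry,min_node Forest controls; `mtry = NULL` means
#'   `floor(sqrt(p))`.
#' @param confidence_floor,batch_fraction,stop_fraction,max_iter
#'   Self-training controls.
#' @param importance_mode `"impurity"` (mean decrease in Gini) or
#'   `"permutation"` (mean decrease in accuracy).
#' @param seed Integer seed making training deterministic.
#' @param reference_threshold Published threshold, metadata only.
#' @return A `model_config` object.
#' @export
model_config <- function(model_id, features, n_trees = 500, mtry = NULL,
                         min_node = 1, confidence_floor = 0.5,
                         batch_fraction = 0.1, stop_fraction = 0.7,
                         max_iter = 40, importance_mode = c("impurity",
                                                            "permutation"),
                         seed = 1, reference_threshold = NA_real_) {
  stopifnot(length(features) >= 1, !anyDuplicated(features),
            confidence_floor >= 0, batch_fraction > 0, batch_fraction <= 1,
            stop_fraction >= 0, stop_fraction <= 1, max_iter >= 0)
  structure(list(model_id = model_id, features = features,
                 n_trees = n_trees, mtry = mtry, min_node = min_node,
                 confidence_floor = confidence_floor,
                 batch_fraction = batch_fraction,
                 stop_fraction = stop_fraction, max_iter = max_iter,
                 importance_mode = match.arg(importance_mode),
                 seed = as.integer(seed),
                 reference_threshold = reference_threshold),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model_config '%s': %d features, %d trees, seed %d\n",
              x$model_id, length(x$features), x$n_trees, x$seed))
  invisible(x)
}
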