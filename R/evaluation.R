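#' ROC area under the curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, counting ties as one half.
#'
#' @param probabilities Numeric scores.
#' @param status `"positive"` / `"negative"` per sample (other values are
#'   dropped).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, status) {
  status <- as.character(status)
  keep <- status %in% c("positive", "negative")
  p <- probabilities[keep]; s <- status[keep]
  np <- sum(s == "positive"); nn <- sum(s == "negative")
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(p)  # midranks handle ties
  (sum(r[s == "positive"]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision-recall area under the curve
#'
#' Area under the step-wise precision-recall curve over the achievable
#' operating points: scores are swept from high to low, one point per
#' distinct score, and each recall increment contributes its width times
#' the precision at the new point. With constant (uninformative) scores the
#' area equals the prevalence P/(P+N); with perfect ranking it is 1.
#'
#' @inheritParams roc_auc
#' @return AUCPR in `[0, 1]`.
#' @export
pr_auc <- function(probabilities, status) {
  status <- as.character(status)
  keep <- status %in% c("positive", "negative")
  p <- probabilities[keep]; y <- status[keep] == "positive"
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(-p)
  p <- p[o]; y <- y[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(p[-1] != p[-length(p)], TRUE)  # end of each tied score group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics
#'
#' Tallies TP/FN/FP/TN over the labelled samples, counts positive calls
#' among unknown-status samples separately, and derives sensitivity,
#' specificity, precision and the Matthews correlation coefficient
#' (MCC = 0 when any marginal is empty).
#'
#' @param calls Logical vector (TRUE = positive call) aligned with
#'   `status`; or pass counts directly via `counts`.
#' @param status `"positive"` / `"negative"` / `"unknown"` per sample.
#' @param counts Alternative input: named vector/list with `tp`, `fn`,
#'   `fp`, `tn` (and optionally `unknown_pos`, `unknown_neg`).
#' @return An `evaluation_report` list: the four counts, unknown-call
#'   tallies, and the derived metrics.
#' @export
confusion_metrics <- function(calls = NULL, status = NULL, counts = NULL) {
  if (is.null(counts)) {
    status <- as.character(status)
    if (length(calls) != length(status)) stop("calls and status are misaligned")
    tp <- sum(calls & status == "positive")
    fn <- sum(!calls & status == "positive")
    fp <- sum(calls & status == "negative")
    tn <- sum(!calls & status == "negative")
    up <- sum(calls & status == "unknown")
    un <- sum(!calls & status == "unknown")
  } else {
    counts <- as.list(counts)
    tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
    up <- if (is.null(counts$unknown_pos)) 0 else counts$unknown_pos
    un <- if (is.null(counts$unknown_neg)) 0 else counts$unknown_neg
  }
  den <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 unknown_pos = up, unknown_neg = un,
                 sensitivity = den(tp, fn), specificity = den(tn, fp),
                 precision = den(tp, fp), mcc = mcc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d  (unknown: %d+/%d-)\n",
              x$tp, x$fn, x$fp, x$tn, x$unknown_pos, x$unknown_neg))
  cat(sprintf("sensitivity %.3f  specificity %.3f  precision %.3f  mcc %.3f\n",
              x$sensitivity, x$specificity, x$precision, x$mcc))
  invisible(x)
}

#' Full evaluation of probabilistic predictions
#' @param probabilities Scores per sample.
#' @param status Labels incl. unknowns.
#' @param threshold Calling threshold (`>=` positive).
#' @return An `evaluation_report` with `auc` and `aucpr` added.
#' @export
evaluate_predictions <- function(probabilities, status, threshold) {
  rep <- confusion_metrics(probabilities >= threshold, status)
  rep$auc <- roc_auc(probabilities, status)
  rep$aucpr <- pr_auc(probabilities, status)
  rep
}

#' Fisher association between binary genomic events and HRD calls
#'
#' For every event column (e.g. presence of a somatic mutation in a gene,
#' or a copy-number loss/gain contrast built with [cn_state_events()]), a
#' two-sided Fisher's exact test against the predicted HRD call, with an
#' odds ratio computed as the cross-product `(a d)/(b c)` after adding 0.5
#' to every cell when any cell is zero (Haldane correction; note this
#' differs from the conditional-MLE odds ratio some packages report), and
#' Benjamini-Hochberg adjusted q-values over the event list.
#'
#' @param events Samples x events binary (0/1 or logical) matrix.
#' @param calls Logical HRD call per sample.
#' @return Data frame `event`, `odds_ratio`, `p`, `q`.
#' @export
fisher_association <- function(events, calls) {
  events <- as.matrix(events)
  if (!all(events %in% c(0, 1) | is.na(events))) stop("events must be binary")
  calls <- as.logical(calls)
  stopifnot(nrow(events) == length(calls))
  res <- lapply(colnames(events), function(e) {
    keep <- !is.na(events[, e])  # e.g. the excluded CN state
    ev <- events[keep, e] == 1
    cl <- calls[keep]
    a <- sum(ev & cl); b <- sum(ev & !cl)
    c_ <- sum(!ev & cl); d <- sum(!ev & !cl)
    tab <- matrix(c(a, b, c_, d), 2)
    p <- stats::fisher.test(tab)$p.value
    if (any(tab == 0)) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    data.frame(event = e, odds_ratio = (a * d) / (b * c_), p = p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Copy-number state event contrasts
#'
#' Discretises per-gene copy number into loss / neutral / gain states
#' (-1, 0, 1 for CN < 2, = 2, > 2) and builds the two binary contrasts
#' used in association testing: loss-vs-neutral and gain-vs-neutral
#' (samples in the excluded state get NA and are dropped per event by
#' [fisher_association()] if pre-filtered by the caller).
#'
#' @param cn Samples x genes numeric copy-number matrix.
#' @return A list with `state` (-1/0/1 matrix), `loss` and `gain` binary
#'   matrices (NA where the sample is in the excluded state).
#' @export
cn_state_events <- function(cn) {
  cn <- as.matrix(cn)
  state <- sign(cn - 2)
  loss <- ifelse(state == 1, NA, as.integer(state == -1))
  gain <- ifelse(state == -1, NA, as.integer(state == 1))
  list(state = state, loss = loss, gain = gain)
}

#' Per-gene, per-variant-class probability summaries
#'
#' Groups predicted HRD probabilities of mutated samples by gene and
#' variant class and reports n, median and quartiles. Empty groups are
#' omitted; a group of one sample reports its value as all three
#' quartiles.
#'
#' @param mutations A `mutation_table` with an additional `gene` column.
#' @param probabilities Named vector of per-sample probabilities.
#' @return Data frame `gene`, `variant_class`, `n`, `q1`, `median`, `q3`.
#' @export
variant_type_summary <- function(mutations, probabilities) {
  if (is.null(mutations$gene)) stop("mutations need a 'gene' column")
  key <- paste(mutations$gene, mutations$variant_class, sep = "\r")
  res <- lapply(sort(unique(key)), function(k) {
    rows <- mutations[key == k, , drop = FALSE]
    pr <- probabilities[unique(rows$sample_id)]
    pr <- pr[!is.na(pr)]
    if (length(pr) == 0) return(NULL)
    q <- stats::quantile(pr, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(gene = rows$gene[1], variant_class = rows$variant_class[1],
               n = length(pr), q1 = q[1], median = q[2], q3 = q[3])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
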