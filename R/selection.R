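#' Per-cohort log z-score normalisation
#'
#' Within each cohort and feature, values are transformed as
#' `z = (x' - mean(x')) / sd(x')` with `x' = ln(x + 1)`, using the sample
#' standard deviation. The per-cohort parameters are stored so that new
#' samples can be normalised with the training parameters. A feature that
#' is constant within a cohort (sd = 0) is set to all-zero for that cohort
#' with a warning.
#'
#' @param x A raw `feature_matrix` (non-negative values).
#' @param group Cohort id per sample (recycled if length 1).
#' @return A list: `matrix` (normalised `feature_matrix`) and `params`
#'   (data frame `group`, `feature`, `mean`, `sd` of the log-transformed
#'   values).
#' @export
lognorm <- function(x, group = "cohort") {
  if (!identical(fm_state(x), "raw")) stop("lognorm expects a raw matrix")
  if (any(x < 0)) stop("negative raw feature value")
  group <- rep_len(as.character(group), nrow(x))
  lx <- log(unclass(x) + 1)
  out <- lx
  params <- list()
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(i) < 2) stop("cohort ", g, " has fewer than 2 samples")
    mu <- colMeans(lx[i, , drop = FALSE])
    sd_ <- apply(lx[i, , drop = FALSE], 2, stats::sd)
    degen <- sd_ == 0
    if (any(degen))
      warning("constant feature(s) in cohort ", g, " set to zero: ",
              paste(colnames(x)[degen], collapse = ", "))
    z <- sweep(lx[i, , drop = FALSE], 2, mu, "-")
    z <- sweep(z, 2, ifelse(degen, 1, sd_), "/")
    z[, degen] <- 0
    out[i, ] <- z
    params[[g]] <- data.frame(group = g, feature = colnames(x),
                              mean = mu, sd = sd_, row.names = NULL)
  }
  list(matrix = feature_matrix(out, fm_blocks(x), state = "normalised"),
       params = do.call(rbind, params))
}

#' Apply stored normalisation parameters to new raw data
#'
#' Used at prediction time for small cohorts: when the new cohort has at
#' least `min_self_norm` samples it is normalised within itself (the
#' training behaviour); below that the stored training parameters are
#' applied, with a warning.
#'
#' @param x A raw `feature_matrix`.
#' @param params Parameter table from [lognorm()] (a single training group
#'   is used; if several, the first).
#' @param min_self_norm Minimum cohort size for self-normalisation.
#' @return A normalised `feature_matrix`.
#' @export
apply_lognorm <- function(x, params, min_self_norm = 20) {
  if (nrow(x) >= min_self_norm) return(lognorm(x)$matrix)
  warning("cohort of ", nrow(x), " sample(s): applying stored ",
          "training normalisation parameters")
  g <- params[params$group == params$group[1], ]
  p <- g[match(colnames(x), g$feature), ]
  if (anyNA(p$mean)) stop("stored parameters missing feature(s)")
  z <- sweep(log(unclass(x) + 1), 2, p$mean, "-")
  z <- sweep(z, 2, ifelse(p$sd == 0, 1, p$sd), "/")
  z[, p$sd == 0] <- 0
  feature_matrix(z, fm_blocks(x), state = "normalised")
}

#' Univariate Wilcoxon screen
#'
#' Two-sided Wilcoxon rank-sum test of each feature between HRD-positive
#' and HRD-negative samples (unknown-status samples are excluded). A
#' feature is retained when `p <= alpha`. By design there is no
#' multiple-testing adjustment: the screen is a deliberately permissive
#' pre-filter.
#'
#' @param x A `feature_matrix`.
#' @param status Character vector per sample: `"positive"`, `"negative"`,
#'   `"unknown"`.
#' @param alpha Retention threshold (default 0.05).
#' @return A `selection_report` data frame: `feature`, `block`,
#'   `wilcoxon_p`, `retained_after_screen`, `pruned_by`, `final_retained`.
#' @export
wilcoxon_screen <- function(x, status, alpha = 0.05) {
  status <- as.character(status)
  pos <- which(status == "positive")
  neg <- which(status == "negative")
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 samples in each of the positive/negative classes")
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- unclass(x)[pos, j]; b <- unclass(x)[neg, j]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
  }, numeric(1))
  rep <- data.frame(feature = colnames(x), block = unname(fm_blocks(x)),
                    wilcoxon_p = p, retained_after_screen = p <= alpha,
                    pruned_by = NA_character_,
                    final_retained = p <= alpha,
                    stringsAsFactors = FALSE)
  class(rep) <- c("selection_report", "data.frame")
  rep
}

#' Within-block correlation pruning
#'
#' Among the features that survived the screen, Pearson correlations are
#' computed within each data block. Pairs with `|r|` above the threshold
#' are processed in order of descending `|r|`; in each still-live pair the
#' member with the larger Wilcoxon p is dropped, unless a manual override
#' names a member of the pair, in which case that member is dropped. The
#' shipped override list reproduces published manual choices (dropping the
#' tandem-duplication region size and SBS2).
#'
#' @param x The `feature_matrix` used for the screen.
#' @param report A `selection_report` from [wilcoxon_screen()].
#' @param r_threshold Absolute Pearson correlation threshold (default 0.8;
#'   pruning applies strictly above it).
#' @param manual_overrides Character vector of feature names to prefer as
#'   the dropped member of any offending pair they belong to.
#' @return The updated `selection_report`.
#' @export
correlation_prune <- function(x, report, r_threshold = 0.8,
                              manual_overrides = character(0)) {
  unknown <- setdiff(manual_overrides, report$feature)
  if (length(unknown) > 0)
    stop("override names unknown feature(s): ", paste(unknown, collapse = ", "))
  for (blk in unique(report$block)) {
    feats <- report$feature[report$block == blk & report$retained_after_screen]
    if (length(feats) < 2) next
    cm <- stats::cor(unclass(x)[, feats, drop = FALSE])
    pairs <- which(upper.tri(cm) & abs(cm) > r_threshold, arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    ord <- order(-abs(cm[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      f1 <- feats[pairs[k, 1]]; f2 <- feats[pairs[k, 2]]
      alive <- report$final_retained[match(c(f1, f2), report$feature)]
      if (!all(alive)) next
      in_ovr <- c(f1, f2) %in% manual_overrides
      victim <- if (xor(in_ovr[1], in_ovr[2])) {
        c(f1, f2)[in_ovr]
      } else {
        p1 <- report$wilcoxon_p[report$feature == f1]
        p2 <- report$wilcoxon_p[report$feature == f2]
        if (p1 >= p2) f1 else f2
      }
      keeper <- setdiff(c(f1, f2), victim)
      i <- match(victim, report$feature)
      report$final_retained[i] <- FALSE
      report$pruned_by[i] <- keeper
    }
  }
  report
}

#' Screen and prune in one call
#' @inheritParams wilcoxon_screen
#' @inheritParams correlation_prune
#' @return A `selection_report`.
#' @export
select_features <- function(x, status, alpha = 0.05, r_threshold = 0.8,
                            manual_overrides = character(0)) {
  rep <- wilcoxon_screen(x, status, alpha = alpha)
  correlation_prune(x, rep, r_threshold = r_threshold,
                    manual_overrides = manual_overrides)
}

#' Write / read a selection report TSV
#' @param report A `selection_report`.
#' @param path File path.
#' @export
write_selection_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
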