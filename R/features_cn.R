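#' Total copy-number summary scores
#'
#' Six per-sample summaries of a total copy-number profile that quantify the
#' copy-number aberration (CNA) landscape: the fraction of the genome
#' altered (`cna_burden`), the number of altered segments (`cna_load`), the
#' mean copy number of altered segments (`macn`), a tandem-duplication event
#' count and mean event size (`td_score`, `td_region_size`), and a
#' chromothripsis-like oscillation score (`chromothripsis_score`). A segment
#' is "altered" when `|total_cn - neutral_cn| > altered_margin`. All scores
#' are computed on the merged profile (see [merge_adjacent()]) so they are
#' invariant to how finely the profile was segmented.
#'
#' These definitions are documented re-derivations of one-line descriptions
#' of the corresponding published scores; every threshold is an argument.
#'
#' @param segments A `segment_table` (total CN).
#' @param genome A [genome_annotation()] (needed by `cna_burden` and the TD
#'   scores for context; sex chromosomes, if present in the genome, can be
#'   excluded with `autosomes_only`).
#' @param neutral_cn Neutral total copy number (default 2).
#' @param altered_margin Margin around `neutral_cn` that still counts as
#'   neutral (default 0.1 on absolute CN).
#' @param autosomes_only Drop chromosomes named X/Y/chrX/chrY (default TRUE).
#' @name cn_scores
NULL

drop_sex <- function(segments, autosomes_only) {
  if (!autosomes_only) return(segments)
  sex <- c("X", "Y", "chrX", "chrY")
  out <- segments[!segments$chrom %in% sex, , drop = FALSE]
  out
}

per_sample <- function(segments, samples = NULL, fn) {
  ids <- if (is.null(samples)) sort(unique(segments$sample_id)) else samples
  vapply(ids, function(s)
    fn(segments[segments$sample_id == s, , drop = FALSE]), numeric(1))
}

altered_idx <- function(d, neutral_cn, altered_margin)
  abs(d$total_cn - neutral_cn) > altered_margin

#' @rdname cn_scores
#' @param samples Optional sample-id vector fixing the output order.
#' @return Named numeric vector, one value per sample.
#' @export
cna_burden <- function(segments, genome = NULL, neutral_cn = 2,
                       altered_margin = 0.1, autosomes_only = TRUE,
                       samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  per_sample(segments, samples, function(d) {
    if (nrow(d) == 0) { warning("empty segment table; cna_burden = 0"); return(0) }
    alt <- altered_idx(d, neutral_cn, altered_margin)
    sum(seg_len(d)[alt]) / sum(seg_len(d))
  })
}

#' @rdname cn_scores
#' @export
cna_load <- function(segments, neutral_cn = 2, altered_margin = 0.1,
                     autosomes_only = TRUE, samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  per_sample(segments, samples, function(d)
    sum(altered_idx(d, neutral_cn, altered_margin)))
}

#' @rdname cn_scores
#' @export
macn <- function(segments, neutral_cn = 2, altered_margin = 0.1,
                 autosomes_only = TRUE, samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  per_sample(segments, samples, function(d) {
    alt <- altered_idx(d, neutral_cn, altered_margin)
    if (!any(alt)) return(neutral_cn)  # sentinel: no altered segment
    mean(d$total_cn[alt])
  })
}

#' @rdname cn_scores
#' @param td_max_len Maximum length (bp) of a gained segment counted as a
#'   tandem-duplication event (default 10 Mb).
#' @return `tandem_duplication_scores` returns a data frame with columns
#'   `sample_id`, `td_score`, `td_region_size` (mean event length in Mb, 0
#'   when there is no event).
#' @export
tandem_duplication_scores <- function(segments, genome = NULL,
                                      td_max_len = 10e6,
                                      autosomes_only = TRUE, samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  ids <- if (is.null(samples)) sort(unique(segments$sample_id)) else samples
  res <- lapply(ids, function(s) {
    d <- segments[segments$sample_id == s, , drop = FALSE]
    lens <- numeric(0)
    for (ch in unique(d$chrom)) {
      dc <- d[d$chrom == ch, , drop = FALSE]
      dc <- dc[order(dc$start_bp), , drop = FALSE]
      n <- nrow(dc)
      if (n < 2) next  # single segment: no flank to be gained against
      for (i in seq_len(n)) {
        gained <- if (i == 1) dc$total_cn[1] > dc$total_cn[2]
        else if (i == n) dc$total_cn[n] > dc$total_cn[n - 1]
        else dc$total_cn[i] > dc$total_cn[i - 1] &&
             dc$total_cn[i] > dc$total_cn[i + 1]
        len <- dc$end_bp[i] - dc$start_bp[i] + 1
        if (gained && len <= td_max_len) lens <- c(lens, len)
      }
    }
    data.frame(sample_id = s, td_score = length(lens),
               td_region_size = if (length(lens)) mean(lens) / 1e6 else 0)
  })
  do.call(rbind, res)
}

#' @rdname cn_scores
#' @param min_oscillations Minimum number of consecutive segments
#'   oscillating between two CN states for a chromosome to count (default 10).
#' @param states_tolerance CN tolerance when matching a segment to one of
#'   the two oscillating states (default 0.1).
#' @export
chromothripsis_score <- function(segments, min_oscillations = 10,
                                 states_tolerance = 0.1,
                                 autosomes_only = TRUE, samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  per_sample(segments, samples, function(d) {
    hit <- 0
    for (ch in unique(d$chrom)) {
      cn <- d$total_cn[d$chrom == ch][order(d$start_bp[d$chrom == ch])]
      if (longest_oscillation(cn, states_tolerance) >= min_oscillations)
        hit <- hit + 1
    }
    hit
  })
}

# Longest run of consecutive segments alternating between exactly two CN
# states, each state matched within `tol`.
longest_oscillation <- function(cn, tol = 0.1) {
  n <- length(cn)
  if (n == 0) return(0)
  best <- 1
  for (i in seq_len(n - 1)) {
    a <- cn[i]; b <- cn[i + 1]
    if (abs(a - b) <= tol) next  # the two states must differ
    len <- 2
    expect <- a  # state expected at position i+2
    j <- i + 2
    while (j <= n && abs(cn[j] - expect) <= tol) {
      len <- len + 1
      expect <- if (abs(expect - a) <= tol) b else a
      j <- j + 1
    }
    best <- max(best, len)
  }
  best
}

#' Copy-number signature (CX) exposures
#'
#' The production path accepts a precomputed per-sample exposure table for
#' the breast-cancer copy-number signatures (CX1, CX2, CX3, CX4, CX5, CX9)
#' and validates it. Alternatively, a per-sample channel encoding matching a
#' CX catalogue's channels can be refit by non-negative least squares; that
#' route is intended for synthetic data and testing, not for reproducing the
#' published mixture-model quantification.
#'
#' @param input Either a data frame / matrix of precomputed exposures
#'   (samples in rows, signatures in columns) or, with `catalogue`, a
#'   samples x channels encoding matrix.
#' @param catalogue Optional `signature_catalogue` with schema `"CX"`.
#' @param wanted Signature names to return.
#' @return Samples x wanted-signatures numeric matrix.
#' @export
cx_exposures <- function(input, catalogue = NULL,
                         wanted = c("CX1", "CX2", "CX3", "CX4", "CX5", "CX9")) {
  if (is.null(catalogue)) {
    m <- as.matrix(input)
    missing_sig <- setdiff(wanted, colnames(m))
    if (length(missing_sig) > 0)
      stop("requested signature(s) absent from exposure table: ",
           paste(missing_sig, collapse = ", "))
    if (any(m[, wanted] < 0)) stop("negative exposure in precomputed table")
    return(m[, wanted, drop = FALSE])
  }
  missing_sig <- setdiff(wanted, colnames(catalogue))
  if (length(missing_sig) > 0)
    stop("requested signature(s) absent from catalogue: ",
         paste(missing_sig, collapse = ", "))
  enc <- as.matrix(input)
  fit <- t(apply(enc, 1, function(v)
    nnls_refit(v, catalogue, wanted = colnames(catalogue))))
  fit[, wanted, drop = FALSE]
}

#' Build the CNA-block feature matrix
#'
#' Runs [merge_adjacent()] and the six summary scores, joins the CX
#' exposures, and returns a raw-state [feature_matrix()] tagged block = CNA.
#'
#' @param segments A `segment_table` (total CN).
#' @param genome A [genome_annotation()].
#' @param cx Precomputed CX exposure table (samples x signatures), or NULL
#'   to omit the CX columns.
#' @param ... Passed to the score functions.
#' @return A raw `feature_matrix` with block tag `CNA`.
#' @export
cn_feature_matrix <- function(segments, genome, cx = NULL, ...) {
  seg <- merge_adjacent(segments)
  ids <- sort(unique(seg$sample_id))
  td <- tandem_duplication_scores(seg, genome, samples = ids, ...)
  m <- cbind(cna_burden = cna_burden(seg, genome, samples = ids, ...),
             cna_load = cna_load(seg, samples = ids, ...),
             macn = macn(seg, samples = ids, ...),
             td_score = td$td_score,
             td_region_size = td$td_region_size,
             chromothripsis_score = chromothripsis_score(seg, samples = ids, ...))
  rownames(m) <- ids
  if (!is.null(cx)) {
    cxm <- cx_exposures(cx)
    cxm <- cxm[match(ids, rownames(cxm)), , drop = FALSE]
    if (anyNA(cxm)) stop("CX exposure table is missing sample(s)")
    m <- cbind(m, cxm)
  }
  feature_matrix(m, blocks = rep("CNA", ncol(m)), state = "raw")
}
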