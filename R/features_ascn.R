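#' Genomic scar scores: LOH, TAI, LST
#'
#' Three counts of allele-specific copy-number "scars" that accumulate in
#' tumours with defective homologous recombination, plus their sum (the
#' scarHRD score, conventionally called positive at >= 42):
#' \itemize{
#'   \item LOH -- loss-of-heterozygosity regions (`minor_cn = 0`,
#'     `total_cn >= 1`) longer than `min_len` (15 Mb) but shorter than the
#'     chromosome's covered length (whole-chromosome LOH is excluded);
#'   \item TAI -- allelic-imbalance regions (`major_cn != minor_cn`) that
#'     reach a chromosome end (within `telomere_slack` of the covered
#'     extent) without crossing the centromere;
#'   \item LST -- chromosome-arm-wise transitions between adjacent large
#'     (>= `min_seg` = 10 Mb) segments after removing segments smaller than
#'     `smooth_below` (3 Mb), with an inter-segment gap of at most
#'     `max_gap` (3 Mb).
#' }
#'
#' Regions are maximal runs of adjacent qualifying segments (gap <= 1 bp).
#' Sex chromosomes are excluded by default.
#'
#' @param segments An `ascn_segment_table`.
#' @param genome A [genome_annotation()].
#' @param min_len Minimum region length in bp.
#' @param autosomes_only Drop X/Y (default TRUE).
#' @param samples Optional sample-id vector fixing output order.
#' @return Named numeric vector of per-sample counts.
#' @name scar_scores_ops
NULL

# maximal runs of adjacent segments satisfying `flag`; returns a data frame
# of regions (start, end) per chromosome of ONE sample
regions_where <- function(d, flag, gap = 1) {
  out <- list()
  for (ch in unique(d$chrom)) {
    dc <- d[d$chrom == ch, , drop = FALSE]
    o <- order(dc$start_bp)
    dc <- dc[o, , drop = FALSE]
    f <- flag(dc)
    i <- 1
    while (i <= nrow(dc)) {
      if (!f[i]) { i <- i + 1; next }
      j <- i
      while (j < nrow(dc) && f[j + 1] &&
             dc$start_bp[j + 1] - dc$end_bp[j] - 1 <= gap) j <- j + 1
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = dc$start_bp[i], end_bp = dc$end_bp[j])
      i <- j + 1
    }
  }
  if (length(out) == 0)
    data.frame(chrom = character(0), start_bp = numeric(0), end_bp = numeric(0))
  else do.call(rbind, out)
}

coverage_extent <- function(d) {
  res <- lapply(split(d, d$chrom), function(dc)
    c(start = min(dc$start_bp), end = max(dc$end_bp)))
  res
}

#' @rdname scar_scores_ops
#' @export
loh_score <- function(segments, genome = NULL, min_len = 15e6,
                      autosomes_only = TRUE, samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  per_sample(segments, samples, function(d) {
    cov <- coverage_extent(d)
    reg <- regions_where(d, function(dc) dc$minor_cn == 0 & dc$total_cn >= 1)
    if (nrow(reg) == 0) return(0)
    len <- reg$end_bp - reg$start_bp + 1
    chrom_cov <- vapply(reg$chrom, function(ch)
      cov[[ch]]["end"] - cov[[ch]]["start"] + 1, numeric(1))
    sum(len > min_len & len < chrom_cov)
  })
}

#' @rdname scar_scores_ops
#' @param telomere_slack Distance (bp) from the covered chromosome ends
#'   within which a region still counts as telomeric (default 0).
#' @export
tai_score <- function(segments, genome, min_len = 0, telomere_slack = 0,
                      autosomes_only = TRUE, samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  cen <- genome[, c("chrom", "cen_start", "cen_end")]
  per_sample(segments, samples, function(d) {
    cov <- coverage_extent(d)
    reg <- regions_where(d, function(dc) dc$major_cn != dc$minor_cn)
    if (nrow(reg) == 0) return(0)
    n <- 0
    for (i in seq_len(nrow(reg))) {
      ch <- reg$chrom[i]
      ci <- cen[cen$chrom == ch, ]
      telomeric <-
        reg$start_bp[i] <= cov[[ch]]["start"] + telomere_slack ||
        reg$end_bp[i] >= cov[[ch]]["end"] - telomere_slack
      crosses <- reg$start_bp[i] < ci$cen_start && reg$end_bp[i] > ci$cen_end
      long_enough <- (reg$end_bp[i] - reg$start_bp[i] + 1) >= min_len
      if (telomeric && !crosses && long_enough) n <- n + 1
    }
    n
  })
}

# split ASCN segments of one sample at centromere midpoints and tag arms
split_arms <- function(d, genome) {
  mid <- centromere_mid(genome)
  rows <- list()
  for (i in seq_len(nrow(d))) {
    m <- mid[d$chrom[i]]
    if (d$start_bp[i] <= m && d$end_bp[i] > m) {
      a <- d[i, ]; a$end_bp <- floor(m)
      b <- d[i, ]; b$start_bp <- floor(m) + 1
      rows[[length(rows) + 1]] <- cbind(a, arm = "p")
      rows[[length(rows) + 1]] <- cbind(b, arm = "q")
    } else {
      rows[[length(rows) + 1]] <-
        cbind(d[i, ], arm = if (d$end_bp[i] <= m) "p" else "q")
    }
  }
  do.call(rbind, rows)
}

# smoothing for LST: repeatedly drop the smallest sub-threshold segment,
# extending the larger neighbour over it, then merge same-state neighbours
smooth_arm <- function(a, smooth_below, merge_gap) {
  a <- a[order(a$start_bp), , drop = FALSE]
  repeat {
    # merge same-state neighbours within merge_gap
    i <- 1
    while (i < nrow(a)) {
      if (a$major_cn[i] == a$major_cn[i + 1] &&
          a$minor_cn[i] == a$minor_cn[i + 1] &&
          a$start_bp[i + 1] - a$end_bp[i] - 1 <= merge_gap) {
        a$end_bp[i] <- a$end_bp[i + 1]
        a <- a[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    len <- a$end_bp - a$start_bp + 1
    small <- which(len < smooth_below)
    if (length(small) == 0 || nrow(a) == 1) break
    k <- small[which.min(len[small])]  # smallest first; ties -> leftmost
    left_len <- if (k > 1) len[k - 1] else -1
    right_len <- if (k < nrow(a)) len[k + 1] else -1
    if (left_len >= right_len) {
      a$end_bp[k - 1] <- a$end_bp[k]
    } else {
      a$start_bp[k + 1] <- a$start_bp[k]
    }
    a <- a[-k, , drop = FALSE]
  }
  a
}

#' @rdname scar_scores_ops
#' @param min_seg Minimum flanking-segment length for a transition (10 Mb).
#' @param max_gap Maximum gap between the flanking segments (3 Mb).
#' @param smooth_below Segments shorter than this are smoothed away before
#'   counting (3 Mb).
#' @export
lst_score <- function(segments, genome, min_seg = 10e6, max_gap = 3e6,
                      smooth_below = 3e6, autosomes_only = TRUE,
                      samples = NULL) {
  segments <- drop_sex(segments, autosomes_only)
  per_sample(segments, samples, function(d) {
    d2 <- split_arms(d, genome)
    n <- 0
    for (key in unique(paste(d2$chrom, d2$arm))) {
      a <- d2[paste(d2$chrom, d2$arm) == key, , drop = FALSE]
      a <- smooth_arm(a, smooth_below, merge_gap = max_gap)
      if (nrow(a) < 2) next
      len <- a$end_bp - a$start_bp + 1
      for (i in seq_len(nrow(a) - 1)) {
        gap <- a$start_bp[i + 1] - a$end_bp[i] - 1
        differs <- a$major_cn[i] != a$major_cn[i + 1] ||
          a$minor_cn[i] != a$minor_cn[i + 1]
        if (differs && len[i] >= min_seg && len[i + 1] >= min_seg &&
            gap <= max_gap) n <- n + 1
      }
    }
    n
  })
}

#' scarHRD score and call
#'
#' Sum of the three scar scores with the conventional positivity threshold
#' of 42.
#'
#' @param loh,tai,lst Per-sample counts (equal length).
#' @param threshold Positivity threshold (default 42; calls are positive at
#'   `score >= threshold`).
#' @return Data frame with `scarhrd` and logical `scarhrd_call`.
#' @export
scarhrd_score <- function(loh, tai, lst, threshold = 42) {
  score <- loh + tai + lst
  data.frame(scarhrd = score, scarhrd_call = score >= threshold)
}

#' All scar scores for a cohort
#' @inheritParams scar_scores_ops
#' @param ... Passed on to the individual score functions.
#' @return Data frame: `sample_id`, `loh`, `tai`, `lst`, `scarhrd`,
#'   `scarhrd_call`.
#' @export
scar_scores <- function(segments, genome, samples = NULL, ...) {
  ids <- if (is.null(samples)) sort(unique(segments$sample_id)) else samples
  loh <- loh_score(segments, genome, samples = ids, ...)
  tai <- tai_score(segments, genome, samples = ids, ...)
  lst <- lst_score(segments, genome, samples = ids, ...)
  cbind(data.frame(sample_id = ids), scarhrd_score(loh, tai, lst),
        loh = loh, tai = tai, lst = lst)[,
    c("sample_id", "loh", "tai", "lst", "scarhrd", "scarhrd_call")]
}

#' Allele-specific copy-number channel counts (CN48)
#'
#' Assigns every segment to one of 48 channels defined by heterozygosity
#' state (homozygous deletion / LOH / heterozygous), total-copy-number bin
#' and segment-length bin, per the channel-definition file shipped with the
#' package, and counts channels per sample. The channel sum equals the
#' number of segments (conservation).
#'
#' @param segments An `ascn_segment_table`.
#' @param samples Optional sample-id vector fixing row order.
#' @return Samples x 48 integer matrix with canonical channel columns.
#' @export
cn48_catalogue <- function(segments, samples = NULL) {
  defs <- cn48_channel_defs()
  ids <- if (is.null(samples)) sort(unique(segments$sample_id)) else samples
  m <- matrix(0L, nrow = length(ids), ncol = nrow(defs),
              dimnames = list(ids, defs$channel))
  state <- ifelse(segments$total_cn == 0, "homdel",
                  ifelse(segments$minor_cn == 0, "LOH", "het"))
  len <- seg_len(segments)
  for (i in seq_len(nrow(segments))) {
    hit <- which(defs$state == state[i] &
                 segments$total_cn[i] >= defs$cn_min &
                 segments$total_cn[i] <= defs$cn_max &
                 len[i] > defs$len_min & len[i] <= defs$len_max)
    if (length(hit) != 1)
      stop("segment does not map to exactly one CN48 channel (row ", i, ")")
    m[segments$sample_id[i], hit] <- m[segments$sample_id[i], hit] + 1L
  }
  m
}

#' Copy-number signature exposures from CN48 counts
#'
#' Non-negative least-squares refit of per-sample channel counts onto a
#' CN48 catalogue, restricted afterwards to the wanted breast-cancer
#' signatures (or, with `refit_restricted = TRUE`, fit on the wanted
#' columns only).
#'
#' @param counts Samples x channels count matrix (see [cn48_catalogue()]).
#' @param catalogue A `signature_catalogue` with schema `"CN48"`.
#' @param wanted Signature names to report.
#' @param refit_restricted Fit only the wanted columns instead of the full
#'   catalogue.
#' @return Samples x wanted-signatures exposure matrix.
#' @export
cn_exposures <- function(counts, catalogue,
                         wanted = c("CN1", "CN2", "CN6", "CN7", "CN8",
                                    "CN9", "CN11", "CN17"),
                         refit_restricted = FALSE) {
  if (!identical(catalogue_schema(catalogue), "CN48"))
    stop("catalogue schema must be CN48")
  missing_sig <- setdiff(wanted, colnames(catalogue))
  if (length(missing_sig) > 0)
    stop("requested signature(s) absent from catalogue: ",
         paste(missing_sig, collapse = ", "))
  fit_cols <- if (refit_restricted) wanted else colnames(catalogue)
  expo <- t(apply(counts, 1, function(v)
    nnls_refit(v, catalogue, wanted = fit_cols)))
  colnames(expo) <- fit_cols
  expo[, wanted, drop = FALSE]
}

#' Build the ASCN-block feature matrix
#'
#' Scar scores (LOH, TAI, LST, scarHRD) plus CN48-signature exposures,
#' tagged block = ASCN.
#'
#' @param segments An `ascn_segment_table`.
#' @param genome A [genome_annotation()].
#' @param cn_catalogue Optional CN48 `signature_catalogue`; when NULL the
#'   CN-exposure columns are omitted.
#' @param wanted_cn Signatures to report from the catalogue.
#' @param ... Passed to [scar_scores()].
#' @return A raw `feature_matrix` with block tag `ASCN`.
#' @export
ascn_feature_matrix <- function(segments, genome, cn_catalogue = NULL,
                                wanted_cn = c("CN1", "CN2", "CN6", "CN7",
                                              "CN8", "CN9", "CN11", "CN17"),
                                ...) {
  sc <- scar_scores(segments, genome, ...)
  m <- as.matrix(sc[, c("loh", "tai", "lst", "scarhrd")])
  colnames(m) <- c("LOH", "TAI", "LST", "scarHRD")
  rownames(m) <- sc$sample_id
  if (!is.null(cn_catalogue)) {
    counts <- cn48_catalogue(segments, samples = sc$sample_id)
    m <- cbind(m, cn_exposures(counts, cn_catalogue, wanted = wanted_cn))
  }
  feature_matrix(m, blocks = rep("ASCN", ncol(m)), state = "raw")
}
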