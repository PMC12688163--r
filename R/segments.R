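#' Copy-number segment tables
#'
#' Two table types share one representation: a total copy-number table
#' (columns `sample_id`, `chrom`, `start_bp`, `end_bp`, `total_cn`) and an
#' allele-specific table adding integer `major_cn` and `minor_cn` with
#' `total_cn = major_cn + minor_cn` and `major_cn >= minor_cn >= 0`.
#' Coordinates are 1-based inclusive, segments within one sample-chromosome
#' must not overlap, and `total_cn` is a non-negative real (it may be
#' log-ratio derived and therefore fractional in the total-CN case).
#'
#' @param df Data frame with the columns above.
#' @param allele_specific Logical; if `TRUE` `major_cn`/`minor_cn` are
#'   required and checked.
#' @param genome Optional [genome_annotation()]; when given, chromosome names
#'   are harmonised to its convention and coordinates are bounds-checked.
#' @return A validated data frame of class `segment_table` (and
#'   `ascn_segment_table` when allele-specific).
#' @export
segment_table <- function(df, allele_specific = FALSE, genome = NULL) {
  need <- c("sample_id", "chrom", "start_bp", "end_bp", "total_cn")
  if (allele_specific) need <- c(need, "major_cn", "minor_cn")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  if (!is.null(genome)) {
    df$chrom <- harmonise_chrom(df$chrom, genome)
    unknown <- setdiff(unique(df$chrom), genome$chrom)
    if (length(unknown) > 0)
      stop("chromosome(s) absent from genome annotation: ",
           paste(unknown, collapse = ", "))
  }
  if (any(df$start_bp < 1) || any(df$start_bp > df$end_bp))
    stop("invalid segment coordinates: need 1 <= start_bp <= end_bp")
  if (any(df$total_cn < 0)) stop("negative total_cn")
  if (allele_specific) {
    if (any(df$major_cn != round(df$major_cn)) ||
        any(df$minor_cn != round(df$minor_cn)))
      stop("major_cn/minor_cn must be integers")
    if (any(df$minor_cn < 0) || any(df$major_cn < df$minor_cn))
      stop("need major_cn >= minor_cn >= 0")
    if (any(abs(df$total_cn - (df$major_cn + df$minor_cn)) > 1e-8))
      stop("total_cn must equal major_cn + minor_cn")
  }
  if (!is.null(genome)) {
    lim <- stats::setNames(genome$length, genome$chrom)
    over <- df$end_bp > lim[df$chrom]
    if (any(over))
      stop("segment end exceeds chromosome length (first offender: sample ",
           df$sample_id[which(over)[1]], ", chrom ", df$chrom[which(over)[1]], ")")
  }
  # overlap check per sample-chromosome
  key <- paste(df$sample_id, df$chrom, sep = "\r")
  for (k in unique(key)) {
    i <- which(key == k)
    o <- i[order(df$start_bp[i])]
    if (length(o) > 1 && any(df$start_bp[o][-1] <= df$end_bp[o][-length(o)])) {
      stop("overlapping segments for sample ", df$sample_id[o[1]],
           " on chromosome ", df$chrom[o[1]])
    }
  }
  df <- df[order(df$sample_id, df$chrom, df$start_bp), , drop = FALSE]
  rownames(df) <- NULL
  cls <- c(if (allele_specific) "ascn_segment_table", "segment_table",
           "data.frame")
  class(df) <- cls
  df
}

#' Read a segment table from a SEG/ASCAT-like TSV
#'
#' The file must be tab-delimited with a header naming at least `sample_id`,
#' `chrom`, `start_bp`, `end_bp`, `total_cn` (plus `major_cn`, `minor_cn`
#' when `allele_specific = TRUE`). Chromosome dialects ("chr1" vs "1") are
#' harmonised to the genome annotation's convention.
#'
#' @inheritParams segment_table
#' @param path Path to the TSV file.
#' @return A validated `segment_table`.
#' @export
read_segments <- function(path, allele_specific = FALSE, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  segment_table(df, allele_specific = allele_specific, genome = genome)
}

#' Write a segment table to TSV
#' @param segments A `segment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(as.data.frame(segments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

seg_len <- function(segments) segments$end_bp - segments$start_bp + 1

is_ascn <- function(segments) inherits(segments, "ascn_segment_table")

#' Merge adjacent segments with equal copy-number state
#'
#' Pre-step that makes segment counts robust to how finely a profile was
#' segmented. Adjacent segments of one sample-chromosome whose copy numbers
#' differ by at most `cn_tolerance` (total CN; for allele-specific tables
#' both alleles must match exactly) and whose gap is at most `gap_max` bp are
#' merged into one segment carrying the length-weighted mean CN.
#'
#' @param segments A `segment_table`.
#' @param cn_tolerance Maximum absolute total-CN difference to merge
#'   (ignored for allele-specific tables, which merge on identical states).
#' @param gap_max Maximum gap in bp between mergeable neighbours.
#' @return A merged `segment_table` of the same type.
#' @export
merge_adjacent <- function(segments, cn_tolerance = 0.1, gap_max = 1) {
  ascn <- is_ascn(segments)
  df <- as.data.frame(segments)
  key <- paste(df$sample_id, df$chrom, sep = "\r")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$start_bp), , drop = FALSE]
    i <- 1
    while (i < nrow(d)) {
      gap <- d$start_bp[i + 1] - d$end_bp[i] - 1
      same <- if (ascn) {
        d$major_cn[i] == d$major_cn[i + 1] && d$minor_cn[i] == d$minor_cn[i + 1]
      } else {
        abs(d$total_cn[i] - d$total_cn[i + 1]) <= cn_tolerance
      }
      if (gap <= gap_max && same) {
        l1 <- d$end_bp[i] - d$start_bp[i] + 1
        l2 <- d$end_bp[i + 1] - d$start_bp[i + 1] + 1
        d$total_cn[i] <- (d$total_cn[i] * l1 + d$total_cn[i + 1] * l2) / (l1 + l2)
        if (ascn) d$total_cn[i] <- d$major_cn[i] + d$minor_cn[i]
        d$end_bp[i] <- d$end_bp[i + 1]
        d <- d[-(i + 1), , drop = FALSE]
      } else {
        i <- i + 1
      }
    }
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  segment_table(res, allele_specific = ascn)
}
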