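#' HRD label table
#'
#' Per-sample BRCA1/2 evidence flags and (optionally) the derived HRD
#' status. Flags are tri-state -- `"yes"`, `"no"`, `"missing"` -- and
#' serialise to TSV as 1 / 0 / NA so that missingness is unambiguous.
#'
#' The label is the gold standard used throughout: biallelic BRCA1/2
#' inactivation (pathogenic mutation or BRCA1 promoter methylation combined
#' with loss of the second allele) defines HRD-positive.
#'
#' @param df Data frame with columns `sample_id`, `germline_brca1`,
#'   `germline_brca2`, `somatic_brca1`, `somatic_brca2`,
#'   `brca1_methylation`, `loh_brca1`, `loh_brca2` (tri-state, accepted as
#'   1/0/NA, logical, or "yes"/"no"/"missing"), optional `hrd_status`.
#' @return A validated data frame of class `hrd_label_table` with
#'   character tri-state columns.
#' @export
hrd_label_table <- function(df) {
  flags <- c("germline_brca1", "germline_brca2", "somatic_brca1",
             "somatic_brca2", "brca1_methylation", "loh_brca1", "loh_brca2")
  miss <- setdiff(c("sample_id", flags), names(df))
  if (length(miss) > 0)
    stop("label table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  for (f in flags) df[[f]] <- as_tristate(df[[f]], f)
  if (!is.null(df$hrd_status)) {
    bad <- !df$hrd_status %in% c("positive", "negative", "unknown")
    if (any(bad)) stop("invalid hrd_status value(s)")
  }
  keep <- c("sample_id", flags, if (!is.null(df$hrd_status)) "hrd_status")
  df <- df[keep]
  rownames(df) <- NULL
  class(df) <- c("hrd_label_table", "data.frame")
  df
}

as_tristate <- function(x, what = "flag") {
  if (is.logical(x)) x <- ifelse(is.na(x), "missing", ifelse(x, "yes", "no"))
  if (is.numeric(x)) {
    if (any(!(x %in% c(0, 1) | is.na(x))))
      stop(what, ": numeric tri-state flags must be 1, 0 or NA")
    x <- ifelse(is.na(x), "missing", ifelse(x == 1, "yes", "no"))
  }
  x <- as.character(x)
  x[is.na(x)] <- "missing"
  bad <- !x %in% c("yes", "no", "missing")
  if (any(bad))
    stop(what, ": flag value outside {yes, no, missing}: ",
         paste(unique(x[bad]), collapse = ", "))
  x
}

#' Derive HRD status from BRCA1/2 evidence flags
#'
#' Rule, applied with positive clauses first, then negative, else unknown:
#' \itemize{
#'   \item positive -- a pathogenic germline or somatic BRCA1/2 mutation
#'     together with LOH of the same gene, or BRCA1 promoter methylation
#'     together with BRCA1 LOH;
#'   \item negative -- all four mutation flags are "no" (missing does not
#'     count as "no"; the methylation flag does not enter this clause), or
#'     both genes show LOH = "no";
#'   \item unknown -- anything else.
#' }
#'
#' A sample with `brca1_methylation = "yes"` but `loh_brca1 = "no"` and
#' `loh_brca2 = "no"` is classified negative by the LOH clause; this literal
#' reading of the rule is kept and reported via a message.
#'
#' @param evidence An `hrd_label_table` (or data frame coercible to one).
#' @param quiet Suppress the edge-case message.
#' @return Character vector of statuses, one per row.
#' @export
derive_hrd_status <- function(evidence, quiet = FALSE) {
  ev <- hrd_label_table(evidence)
  yes <- function(f) ev[[f]] == "yes"
  no <- function(f) ev[[f]] == "no"
  positive <-
    (yes("germline_brca1") & yes("loh_brca1")) |
    (yes("germline_brca2") & yes("loh_brca2")) |
    (yes("somatic_brca1") & yes("loh_brca1")) |
    (yes("somatic_brca2") & yes("loh_brca2")) |
    (yes("brca1_methylation") & yes("loh_brca1"))
  no_mutations <- no("germline_brca1") & no("germline_brca2") &
    no("somatic_brca1") & no("somatic_brca2")
  no_loh <- no("loh_brca1") & no("loh_brca2")
  negative <- !positive & (no_mutations | no_loh)
  edge <- negative & ev$brca1_methylation == "yes" & no_loh
  if (any(edge) && !quiet)
    message(sum(edge), " sample(s) with BRCA1 methylation but no LOH on ",
            "either gene classified negative by the LOH clause")
  ifelse(positive, "positive", ifelse(negative, "negative", "unknown"))
}

#' Label a cohort and tally statuses
#'
#' Applies [derive_hrd_status()] row-wise and returns the filled table plus
#' per-status counts. Deterministic and order-independent.
#'
#' @param table An `hrd_label_table`.
#' @param quiet Passed to [derive_hrd_status()].
#' @return A list with `labels` (the table with `hrd_status` filled) and
#'   `counts` (named integer vector: positive, negative, unknown).
#' @export
label_cohort <- function(table, quiet = FALSE) {
  tab <- hrd_label_table(table)
  if (nrow(tab) == 0) {
    tab$hrd_status <- character(0)
  } else {
    tab$hrd_status <- derive_hrd_status(tab, quiet = quiet)
  }
  counts <- vapply(c("positive", "negative", "unknown"),
                   function(s) sum(tab$hrd_status == s), integer(1))
  list(labels = hrd_label_table(tab), counts = counts)
}

#' Read / write an HRD label table (tri-state flags as 1/0/NA)
#' @param path File path.
#' @return An `hrd_label_table` (read) or `path` (write).
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  hrd_label_table(df)
}

#' @rdname read_labels
#' @param labels An `hrd_label_table`.
#' @export
write_labels <- function(labels, path) {
  df <- as.data.frame(labels)
  flags <- c("germline_brca1", "germline_brca2", "somatic_brca1",
             "somatic_brca2", "brca1_methylation", "loh_brca1", "loh_brca2")
  for (f in flags)
    df[[f]] <- ifelse(df[[f]] == "missing", NA_integer_,
                      as.integer(df[[f]] == "yes"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
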