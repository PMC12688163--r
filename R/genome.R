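#' Genome annotation
#'
#' A genome annotation holds the chromosome names, their lengths and the
#' centromere interval of each chromosome. It is required by the scar scores
#' (TAI needs telomere/centromere positions, LST is computed per chromosome
#' arm) and by segment-table validation.
#'
#' @param chrom Character vector of chromosome names (order is kept).
#' @param length Integer vector of chromosome lengths in base pairs.
#' @param cen_start,cen_end Centromere interval per chromosome, 1-based
#'   inclusive, with `0 < cen_start < cen_end <= length`.
#' @return An object of class `genome_annotation`: a data frame with columns
#'   `chrom`, `length`, `cen_start`, `cen_end`.
#' @export
genome_annotation <- function(chrom, length, cen_start, cen_end) {
  chrom <- as.character(chrom)
  n <- base::length(chrom)
  if (anyDuplicated(chrom))
    stop("duplicate chromosome names in genome annotation")
  stopifnot(base::length(length) == n, base::length(cen_start) == n,
            base::length(cen_end) == n)
  length <- as.numeric(length)
  cen_start <- as.numeric(cen_start)
  cen_end <- as.numeric(cen_end)
  bad <- !(cen_start > 0 & cen_start < cen_end & cen_end <= length)
  if (any(bad))
    stop("invalid centromere interval for chromosome(s): ",
         paste(chrom[bad], collapse = ", "))
  g <- data.frame(chrom = chrom, length = length,
                  cen_start = cen_start, cen_end = cen_end,
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_annotation", "data.frame")
  g
}

#' Read a genome annotation TSV
#'
#' Expects a tab-delimited file with header columns `chrom`, `length`,
#' `cen_start`, `cen_end`.
#'
#' @param path Path to the TSV file.
#' @return A [genome_annotation()] object.
#' @export
read_genome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length", "cen_start", "cen_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("genome annotation is missing column(s): ", paste(miss, collapse = ", "))
  genome_annotation(df$chrom, df$length, df$cen_start, df$cen_end)
}

#' Write a genome annotation TSV
#' @param genome A [genome_annotation()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  utils::write.table(as.data.frame(genome), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Toy genome for simulation and tests
#'
#' Four autosome-like chromosomes of 200/150/120/100 Mb with centromeres
#' placed at 40% of the chromosome length (3 Mb wide). Small enough for fast
#' tests while leaving room for > 15 Mb scar events on both arms.
#'
#' @return A [genome_annotation()] object.
#' @export
toy_genome <- function() {
  len <- c(200e6, 150e6, 120e6, 100e6)
  cs <- round(0.4 * len)
  genome_annotation(chrom = as.character(1:4), length = len,
                    cen_start = cs, cen_end = cs + 3e6)
}

#' Harmonise chromosome-name style to a genome annotation
#'
#' Maps "chr1"-style and "1"-style names onto whichever convention the genome
#' annotation uses. Idempotent; names that match neither dialect are returned
#' unchanged (validation downstream will reject them if unknown).
#'
#' @param chrom Character vector of chromosome names.
#' @param genome A [genome_annotation()] object.
#' @return Character vector of harmonised names.
#' @export
harmonise_chrom <- function(chrom, genome) {
  chrom <- as.character(chrom)
  target_has_prefix <- any(grepl("^chr", genome$chrom))
  stripped <- sub("^chr", "", chrom)
  if (target_has_prefix) {
    out <- ifelse(paste0("chr", stripped) %in% genome$chrom,
                  paste0("chr", stripped), chrom)
  } else {
    out <- ifelse(stripped %in% genome$chrom, stripped, chrom)
  }
  out
}

# Chromosome arm of a position: "p" before the centromere midpoint, "q" after.
# Used when splitting segments for arm-wise LST counting.
centromere_mid <- function(genome) {
  stats::setNames((genome$cen_start + genome$cen_end) / 2, genome$chrom)
}
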