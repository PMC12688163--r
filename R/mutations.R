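#' Somatic mutation table
#'
#' Rows of (`sample_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`,
#' `variant_class`, `flank_5p`, `flank_3p`). The variant class is derived
#' from the allele lengths: equal length 1 is an SNV, equal length 2 a DNV,
#' longer equal-length substitutions are `other`, and unequal lengths are
#' insertions/deletions. Flanking sequence (>= 10 bp each side when
#' available) is needed for SBS96/ID83 channelization.
#'
#' @param df Data frame with at least `sample_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`; `flank_5p`/`flank_3p` optional.
#' @return A validated data frame of class `mutation_table`.
#' @export
mutation_table <- function(df) {
  need <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("mutation table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$ref_allele <- toupper(as.character(df$ref_allele))
  df$alt_allele <- toupper(as.character(df$alt_allele))
  if (is.null(df$flank_5p)) df$flank_5p <- rep(NA_character_, nrow(df))
  if (is.null(df$flank_3p)) df$flank_3p <- rep(NA_character_, nrow(df))
  df$flank_5p <- toupper(as.character(df$flank_5p))
  df$flank_3p <- toupper(as.character(df$flank_3p))
  if (any(df$ref_allele == df$alt_allele))
    stop("ref_allele equals alt_allele in row ",
         which(df$ref_allele == df$alt_allele)[1])
  df$variant_class <- classify_variant(df$ref_allele, df$alt_allele)
  df <- df[c(need, "variant_class", "flank_5p", "flank_3p")]
  rownames(df) <- NULL
  class(df) <- c("mutation_table", "data.frame")
  df
}

classify_variant <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == na,
         ifelse(nr == 1, "SNV", ifelse(nr == 2, "DNV", "other")),
         ifelse(na > nr, "insertion", "deletion"))
}

#' Read somatic mutations from VCF or MAF-like TSV
#'
#' VCF records are parsed with `vcfR`; multi-allelic records are split into
#' one row per alternate allele. A MAF-like TSV must carry the
#' [mutation_table()] columns in its header. When a reference FASTA is
#' given, flanking sequence (`flank_width` bp each side) is extracted and
#' the reference allele is checked against the FASTA (a mismatch is a
#' provenance error). Without flanks or a FASTA the table is still returned;
#' channelization will fail later if it needs context.
#'
#' @param path Path to the input file.
#' @param format `"vcf"` or `"tsv"`.
#' @param reference_fasta Optional path to an (uncompressed) FASTA file.
#' @param sample_id Sample id for VCF input; defaults to the VCF's first
#'   genotype column name, or the file name when the VCF has no samples.
#' @param flank_width Flank length to extract from the FASTA (>= 10).
#' @return A `mutation_table`.
#' @export
read_mutations <- function(path, format = c("vcf", "tsv"),
                           reference_fasta = NULL, sample_id = NULL,
                           flank_width = 10) {
  format <- match.arg(format)
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("package 'vcfR' is required to read VCF input")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    if (is.null(sample_id)) {
      gt <- colnames(v@gt)
      sample_id <- if (length(gt) > 1) gt[2] else
        sub("\\.vcf(\\.gz)?$", "", basename(path))
    }
    rows <- lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      data.frame(sample_id = sample_id, chrom = fix$CHROM[i],
                 pos = as.numeric(fix$POS[i]), ref_allele = fix$REF[i],
                 alt_allele = alts, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  mt <- mutation_table(df)
  if (!is.null(reference_fasta))
    mt <- add_flanks(mt, reference_fasta, flank_width = flank_width)
  mt
}

#' Extract flanking sequence from a reference FASTA
#'
#' Fills `flank_5p`/`flank_3p` for every row and verifies that the
#' reference allele matches the FASTA at the stated position.
#'
#' @param mutations A `mutation_table`.
#' @param reference_fasta Path to a FASTA file whose sequence names contain
#'   the chromosome names used in the table.
#' @param flank_width Flank length in bp (>= 10).
#' @return The `mutation_table` with flanks filled.
#' @export
add_flanks <- function(mutations, reference_fasta, flank_width = 10) {
  if (flank_width < 10) stop("flank_width must be >= 10")
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("package 'Biostrings' is required for FASTA flank extraction")
  seqs <- Biostrings::readDNAStringSet(reference_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  for (i in seq_len(nrow(mutations))) {
    chrom <- mutations$chrom[i]
    s <- seqs[[match(chrom, names(seqs))]]
    if (is.null(s)) stop("chromosome ", chrom, " absent from FASTA")
    pos <- mutations$pos[i]
    ref <- mutations$ref_allele[i]
    # indel alleles are VCF-anchored: the REF string starts at pos
    ref_chk <- if (ref %in% c("-", "")) "" else ref
    if (nchar(ref_chk) > 0) {
      obs <- as.character(Biostrings::subseq(s, pos, pos + nchar(ref_chk) - 1))
      if (obs != ref_chk)
        stop("reference mismatch at ", chrom, ":", pos, " (table ", ref_chk,
             ", FASTA ", obs, ")")
    }
    from5 <- max(1, pos - flank_width)
    mutations$flank_5p[i] <-
      if (pos > 1) as.character(Biostrings::subseq(s, from5, pos - 1)) else ""
    end_ref <- pos + max(nchar(ref_chk), 1) - 1
    to3 <- min(length(s), end_ref + flank_width)
    mutations$flank_3p[i] <-
      if (end_ref < length(s)) as.character(Biostrings::subseq(s, end_ref + 1, to3)) else ""
  }
  mutations
}

#' Write a mutation table to TSV
#' @param mutations A `mutation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(as.data.frame(mutations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
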