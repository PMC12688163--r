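#' SBS96 channel of a single-base substitution
#'
#' Expresses the substitution on the pyrimidine strand (C or T reference;
#' purine-reference variants are reverse-complemented together with their
#' context) and returns the `5'base[ref>alt]3'base` channel name. Variants
#' whose needed context contains an ambiguous base return `NA`
#' (unclassifiable).
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @param flank_5p,flank_3p Flanking sequences (>= 1 bp used from each).
#' @return Character vector of channel names (or `NA`).
#' @export
sbs96_channel <- function(ref, alt, flank_5p, flank_3p) {
  mapply(function(r, a, f5, f3) {
    if (is.na(f5) || is.na(f3) || nchar(f5) < 1 || nchar(f3) < 1)
      return(NA_character_)
    p5 <- substr(f5, nchar(f5), nchar(f5))
    p3 <- substr(f3, 1, 1)
    if (r %in% c("G", "A")) {
      r <- comp_base(r); a <- comp_base(a)
      tmp <- comp_base(p5); p5 <- comp_base(p3); p3 <- tmp
    }
    if (any(!c(r, a, p5, p3) %in% c("A", "C", "G", "T")))
      return(NA_character_)
    paste0(p5, "[", r, ">", a, "]", p3)
  }, ref, alt, flank_5p, flank_3p, USE.NAMES = FALSE)
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

revcomp <- function(s) {
  vapply(s, function(x) paste(rev(vapply(strsplit(x, "")[[1]], comp_base, "")),
                              collapse = ""), "", USE.NAMES = FALSE)
}

# Reduce a (possibly VCF-anchored, possibly "-"-style) ref/alt pair to the
# inserted or deleted sequence, moving stripped anchor bases onto the
# flanks so that homopolymer/repeat counting sees the true local context.
normalize_indel <- function(ref, alt, flank_5p, flank_3p) {
  if (ref %in% c("-", "")) ref <- ""
  if (alt %in% c("-", "")) alt <- ""
  # strip common prefix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    flank_5p <- paste0(flank_5p, substr(ref, 1, 1))
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
  }
  # strip common suffix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    flank_3p <- paste0(substr(ref, nchar(ref), nchar(ref)), flank_3p)
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  if (nchar(ref) > 0 && nchar(alt) > 0) return(NULL)  # not a clean indel
  list(type = if (nchar(ref) > 0) "Del" else "Ins",
       seq = if (nchar(ref) > 0) ref else alt,
       flank_5p = flank_5p, flank_3p = flank_3p)
}

count_head_copies <- function(flank, unit) {
  L <- nchar(unit); k <- 0
  while (substr(flank, k * L + 1, (k + 1) * L) == unit) k <- k + 1
  k
}

count_tail_copies <- function(flank, unit) {
  L <- nchar(unit); n <- nchar(flank); k <- 0
  while (n - (k + 1) * L + 1 >= 1 &&
         substr(flank, n - (k + 1) * L + 1, n - k * L) == unit) k <- k + 1
  k
}

#' ID83 channel of a small insertion or deletion
#'
#' Classification per the 83-channel indel schema defined by the channel
#' file shipped with the package: 1-bp indels by base (C/T after strand
#' collapse) and homopolymer-run bin; longer indels by length bin (2, 3, 4,
#' 5+) and repeat-unit bin; deletions not in a repeat are additionally
#' checked for microhomology with the 3' flank. Repeat bins count reference
#' repeat units including the deleted copy (and excluding the inserted
#' copy), as recorded in the channel-definition file. Variants with
#' insufficient flank return `NA`.
#'
#' @inheritParams sbs96_channel
#' @return Character vector of channel names (or `NA`).
#' @export
id83_channel <- function(ref, alt, flank_5p, flank_3p) {
  defs <- id83_channel_defs()
  mapply(function(r, a, f5, f3) {
    if (is.na(f5) || is.na(f3)) return(NA_character_)
    z <- normalize_indel(r, a, f5, f3)
    if (is.null(z)) return(NA_character_)
    s <- z$seq; L <- nchar(s)
    if (L == 0) return(NA_character_)
    if (nchar(z$flank_3p) < L || grepl("N", paste0(s, z$flank_5p, z$flank_3p)))
      return(NA_character_)
    if (L == 1) {
      run_flank <- count_tail_copies(z$flank_5p, s) + count_head_copies(z$flank_3p, s)
      motif <- if (s %in% c("C", "T")) s else comp_base(s)
      units <- if (z$type == "Del") run_flank + 1 else run_flank
      row <- defs[defs$indel_type == z$type & defs$length_bin == 1 &
                  defs$motif == motif & units >= defs$unit_min &
                  units <= defs$unit_max, ]
      return(row$channel[1])
    }
    len_bin <- min(L, 5)
    copies <- count_tail_copies(z$flank_5p, s) + count_head_copies(z$flank_3p, s)
    units <- if (z$type == "Del") copies + 1 else copies
    if (z$type == "Del" && units == 1) {
      # not in a repeat: microhomology with the 3' flank
      mh <- 0
      while (mh < L - 1 &&
             substr(s, mh + 1, mh + 1) == substr(z$flank_3p, mh + 1, mh + 1))
        mh <- mh + 1
      if (mh > 0) {
        row <- defs[defs$indel_type == "Del" & defs$length_bin == len_bin &
                    defs$motif == "M" & mh >= defs$unit_min &
                    mh <= defs$unit_max, ]
        return(row$channel[1])
      }
    }
    row <- defs[defs$indel_type == z$type & defs$length_bin == len_bin &
                defs$motif == "R" & units >= defs$unit_min &
                units <= defs$unit_max, ]
    row$channel[1]
  }, ref, alt, flank_5p, flank_3p, USE.NAMES = FALSE)
}

#' Build a per-sample mutation catalogue
#'
#' Counts SBS96 channels over SNV rows or ID83 channels over indel rows.
#' DNVs and `other` variants are excluded from both schemas. Rows whose
#' context cannot be resolved are tallied in the `unclassified` attribute.
#'
#' @param mutations A `mutation_table`.
#' @param schema_id `"SBS96"` or `"ID83"`.
#' @param reference_fasta Optional FASTA used to fill missing flanks.
#' @param samples Optional sample-id vector fixing the row order.
#' @return Samples x channels integer matrix with attribute
#'   `unclassified` (named per-sample counts).
#' @export
build_catalogue <- function(mutations, schema_id = c("SBS96", "ID83"),
                            reference_fasta = NULL, samples = NULL) {
  schema_id <- match.arg(schema_id)
  keep_class <- if (schema_id == "SBS96") "SNV" else c("insertion", "deletion")
  mut <- mutations[mutations$variant_class %in% keep_class, , drop = FALSE]
  need_flank <- is.na(mut$flank_5p) | is.na(mut$flank_3p)
  if (any(need_flank)) {
    if (is.null(reference_fasta))
      stop("no flanking sequence for row ", which(need_flank)[1],
           " and no reference FASTA given")
    mut <- add_flanks(mut, reference_fasta,
                      flank_width = max(10, 6 * max(nchar(mut$ref_allele),
                                                    nchar(mut$alt_allele))))
  }
  chans <- schema_channels(schema_id)
  ids <- if (is.null(samples)) sort(unique(mutations$sample_id)) else samples
  m <- matrix(0L, length(ids), length(chans), dimnames = list(ids, chans))
  uncl <- stats::setNames(integer(length(ids)), ids)
  if (nrow(mut) > 0) {
    ch <- if (schema_id == "SBS96")
      sbs96_channel(mut$ref_allele, mut$alt_allele, mut$flank_5p, mut$flank_3p)
    else
      id83_channel(mut$ref_allele, mut$alt_allele, mut$flank_5p, mut$flank_3p)
    for (i in seq_along(ch)) {
      s <- mut$sample_id[i]
      if (!s %in% ids) next
      if (is.na(ch[i])) uncl[s] <- uncl[s] + 1L
      else m[s, ch[i]] <- m[s, ch[i]] + 1L
    }
  }
  attr(m, "unclassified") <- uncl
  attr(m, "schema_id") <- schema_id
  m
}

#' Non-negative least-squares signature refit
#'
#' Finds exposures `e >= 0` minimising `||counts - S e||_2` over the wanted
#' catalogue columns `S`. Deterministic (active-set NNLS).
#'
#' @param counts Channel count vector, named by channel or in canonical
#'   channel order of the catalogue's schema.
#' @param catalogue A `signature_catalogue`.
#' @param wanted Signature names to fit (default: all in the catalogue).
#' @param normalise Rescale exposures to sum to the total count.
#' @return Named non-negative exposure vector over `wanted`.
#' @export
nnls_refit <- function(counts, catalogue, wanted = colnames(catalogue),
                       normalise = FALSE) {
  missing_sig <- setdiff(wanted, colnames(catalogue))
  if (length(missing_sig) > 0)
    stop("signature(s) absent from catalogue: ",
         paste(missing_sig, collapse = ", "))
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), rownames(catalogue)))
      stop("channel names do not match the catalogue schema")
    counts <- counts[rownames(catalogue)]
  } else if (length(counts) != nrow(catalogue)) {
    stop("count vector length does not match the catalogue schema")
  }
  S <- unclass(catalogue)[, wanted, drop = FALSE]
  e <- pracma::lsqnonneg(S, as.numeric(counts))$x
  names(e) <- wanted
  if (normalise && sum(e) > 0) e <- e * sum(counts) / sum(e)
  e
}

#' Build the SNV-block feature matrix
#'
#' SBS96 and ID83 catalogues are built from the mutation table and refit
#' against the given catalogues; the exposures are returned as a raw
#' feature matrix tagged block = SNV.
#'
#' @param mutations A `mutation_table`.
#' @param sbs_catalogue,id_catalogue `signature_catalogue` objects with
#'   schemas SBS96 and ID83.
#' @param wanted_sbs,wanted_id Signatures to fit and report.
#' @param reference_fasta Optional FASTA for flank extraction.
#' @param normalise Passed to [nnls_refit()] (default raw count-scale
#'   exposures).
#' @param samples Optional sample-id vector fixing row order.
#' @return A raw `feature_matrix` with block tag `SNV`.
#' @export
snv_feature_matrix <- function(mutations, sbs_catalogue, id_catalogue,
                               wanted_sbs = colnames(sbs_catalogue),
                               wanted_id = colnames(id_catalogue),
                               reference_fasta = NULL, normalise = FALSE,
                               samples = NULL) {
  sbs <- build_catalogue(mutations, "SBS96", reference_fasta, samples = samples)
  id <- build_catalogue(mutations, "ID83", reference_fasta, samples = samples)
  es <- t(apply(sbs, 1, nnls_refit, catalogue = sbs_catalogue,
                wanted = wanted_sbs, normalise = normalise))
  ei <- t(apply(id, 1, nnls_refit, catalogue = id_catalogue,
                wanted = wanted_id, normalise = normalise))
  colnames(es) <- wanted_sbs
  colnames(ei) <- wanted_id
  m <- cbind(es, ei)
  feature_matrix(m, blocks = rep("SNV", ncol(m)), state = "raw")
}

#' Construct an example variant for an ID83 channel
#'
#' Inverse of [id83_channel()]: builds a (ref, alt, flank_5p, flank_3p)
#' tuple, in VCF-anchored style, that classifies into the requested
#' channel. Channels with open-ended bins use the smallest qualifying
#' repeat/homopolymer count. Used by the synthetic cohort generator and as
#' a round-trip oracle in tests.
#'
#' @param channel An ID83 channel name.
#' @return A list with `ref`, `alt`, `flank_5p`, `flank_3p`.
#' @export
id83_example_variant <- function(channel) {
  defs <- id83_channel_defs()
  row <- defs[defs$channel == channel, ]
  if (nrow(row) != 1) stop("unknown ID83 channel: ", channel)
  L <- row$length_bin
  if (row$motif == "M" && row$unit_min >= L)
    L <- row$unit_min + 1  # microhomology must be shorter than the deletion
  s <- if (row$motif %in% c("C", "T")) row$motif else substr("ACGGTACGGTA", 1, L)
  first <- substr(s, 1, 1); last <- substr(s, L, L)
  anchor <- setdiff(c("G", "A", "C", "T"), c(first, last))[1]
  pad_of <- function(avoid) strrep(setdiff(c("G", "A", "C", "T"), avoid)[1], 12)
  f5 <- paste0(pad_of(c(last, first)), "")
  if (row$motif == "M") {
    mh <- row$unit_min
    stopper <- substr(s, mh + 1, mh + 1)
    f3 <- paste0(substr(s, 1, mh), pad_of(c(stopper, first)))
    return(list(ref = paste0(anchor, s), alt = anchor,
                flank_5p = f5, flank_3p = f3))
  }
  units <- row$unit_min
  copies3 <- if (row$indel_type == "Del") units - 1 else units
  f3 <- paste0(strrep(s, copies3), pad_of(first))
  if (row$indel_type == "Del")
    list(ref = paste0(anchor, s), alt = anchor, flank_5p = f5, flank_3p = f3)
  else
    list(ref = anchor, alt = paste0(anchor, s), flank_5p = f5, flank_3p = f3)
}
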