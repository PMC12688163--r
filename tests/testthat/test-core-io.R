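test_that("segment tables read, validate and round-trip", {
  g <- toy_genome()
  df <- data.frame(sample_id = "A", chrom = c("1", "1", "2"),
                   start_bp = c(1, 101, 1), end_bp = c(100, 200, 500),
                   total_cn = c(2, 3, 1.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_segments(path, genome = g)
  expect_s3_class(st, "segment_table")
  expect_equal(nrow(st), 3)

  # round trip
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_segments(st, p2)
  expect_equal(as.data.frame(read_segments(p2, genome = g)),
               as.data.frame(st))

  # overlap by 1 bp rejected, naming sample and chromosome
  bad <- df; bad$start_bp[2] <- 100
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_segments(path, genome = g), "sample A.*chromosome 1")

  # bounds error
  bad2 <- df; bad2$end_bp[3] <- 1e12
  write.table(bad2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_segments(path, genome = g), "exceeds chromosome length")

  # missing column named in the error
  write.table(df[-5], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_segments(path), "total_cn")
})

test_that("chromosome-name harmonisation is dialect-aware and idempotent", {
  g <- toy_genome()  # "1"-style names
  mixed <- c("chr1", "1", "chr2", "4")
  h <- harmonise_chrom(mixed, g)
  expect_equal(h, c("1", "1", "2", "4"))
  expect_equal(harmonise_chrom(h, g), h)

  gc <- genome_annotation(paste0("chr", 1:2), c(2e8, 1.5e8),
                          c(8e7, 6e7), c(8.3e7, 6.3e7))
  expect_equal(harmonise_chrom(c("1", "chr2"), gc), c("chr1", "chr2"))

  # mixed dialects harmonise through the reader and round-trip identically
  df <- data.frame(sample_id = "A", chrom = c("chr1", "1"),
                   start_bp = c(1, 1e6 + 1), end_bp = c(1e6, 2e6),
                   total_cn = 2:3)
  st <- segment_table(df, genome = g)
  expect_equal(unique(st$chrom), "1")
})

test_that("allele-specific invariants are enforced", {
  df <- data.frame(sample_id = "A", chrom = "1", start_bp = 1, end_bp = 100,
                   total_cn = 3, major_cn = 2, minor_cn = 1)
  expect_s3_class(segment_table(df, allele_specific = TRUE),
                  "ascn_segment_table")
  bad <- df; bad$minor_cn <- 3
  expect_error(segment_table(bad, allele_specific = TRUE), "major_cn >= minor_cn")
  bad2 <- df; bad2$total_cn <- 4
  expect_error(segment_table(bad2, allele_specific = TRUE), "total_cn")
})

test_that("mutation reader classifies variants and splits multi-allelics", {
  df <- data.frame(sample_id = "A", chrom = "1", pos = c(100, 200, 300),
                   ref_allele = c("C", "CTT", "C"),
                   alt_allele = c("A", "C", "CAG"))
  mt <- mutation_table(df)
  expect_equal(mt$variant_class, c("SNV", "deletion", "insertion"))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t100\t.\tC\tA\t.\tPASS\t.",
               "1\t200\t.\tCTT\tC\t.\tPASS\t.",
               "1\t300\t.\tC\tA,T\t.\tPASS\t."), vcf)
  mt2 <- read_mutations(vcf, format = "vcf", sample_id = "A")
  expect_equal(nrow(mt2), 4)  # multi-allelic split by hand: C>A plus C>T
  expect_equal(sum(mt2$pos == 300), 2)
  expect_setequal(mt2$alt_allele[mt2$pos == 300], c("A", "T"))
  expect_equal(mt2$variant_class[mt2$pos == 200], "deletion")
})

test_that("flank extraction checks the reference and fills context", {
  fa <- withr::local_tempfile(fileext = ".fa")
  seq1 <- paste(rep("ACGTACGTAC", 10), collapse = "")
  writeLines(c(">1", seq1), fa)
  mt <- mutation_table(data.frame(sample_id = "A", chrom = "1", pos = 21,
                                  ref_allele = "A", alt_allele = "G"))
  out <- add_flanks(mt, fa)
  expect_equal(nchar(out$flank_5p), 10)
  expect_equal(substr(out$flank_3p, 1, 1), "C")
  bad <- mutation_table(data.frame(sample_id = "A", chrom = "1", pos = 21,
                                   ref_allele = "T", alt_allele = "G"))
  expect_error(add_flanks(bad, fa), "reference mismatch")
})

test_that("signature catalogues validate schema and renormalise columns", {
  cat96 <- synthetic_signature_catalogue("SBS96", paste0("S", 1:12), seed = 4)
  expect_equal(dim(cat96), c(96, 12))
  expect_true(all(abs(colSums(cat96) - 1) < 1e-9))

  path <- withr::local_tempfile(fileext = ".tsv")
  w <- unclass(cat96)
  w[, 1] <- w[, 1] * 0.999  # column summing to 0.999: renormalised on read
  write.table(data.frame(channel = rownames(w), w, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_signature_catalogue(path, "SBS96")
  expect_true(all(abs(colSums(back) - 1) < 1e-9))

  # wrong channel count / unknown channel
  expect_error(signature_catalogue(w[-1, ], "SBS96"), "96 channels")
  w2 <- w; rownames(w2)[1] <- "bogus"
  expect_error(signature_catalogue(w2, "SBS96"), "unknown channel")
  w3 <- w; w3[1, 1] <- -0.1
  expect_error(signature_catalogue(w3, "SBS96"), "negative")
  w4 <- w; w4[, 2] <- w4[, 2] * 0.9  # 10% off: too far to renormalise
  expect_error(signature_catalogue(w4, "SBS96"), "sum to 1")
})

test_that("feature matrices round-trip with block tags and reject bad input", {
  set.seed(1)
  m <- matrix(abs(rnorm(35)), 5, 7,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:7)))
  fm <- feature_matrix(m, blocks = rep(c("CNA", "ASCN", "SNV"), c(3, 2, 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(unclass(back), unclass(fm), tolerance = 1e-11)
  expect_equal(attr(back, "blocks"), attr(fm, "blocks"))
  expect_equal(attr(back, "state"), "raw")

  m2 <- m; colnames(m2)[2] <- "f1"
  expect_error(feature_matrix(m2, rep("SNV", 7)), "duplicate feature")
  m3 <- m; m3[1, 1] <- -1
  expect_error(feature_matrix(m3, rep("SNV", 7)), "non-negative")
})

test_that("label tables serialise tri-state flags as 1/0/NA", {
  tab <- hrd_label_table(data.frame(
    sample_id = c("a", "b"), germline_brca1 = c(1, NA),
    germline_brca2 = 0, somatic_brca1 = 0, somatic_brca2 = 0,
    brca1_methylation = c(0, NA), loh_brca1 = c(1, NA), loh_brca2 = 0))
  expect_equal(tab$germline_brca1, c("yes", "missing"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(tab, path)
  expect_equal(as.data.frame(read_labels(path)), as.data.frame(tab))
  expect_error(hrd_label_table(data.frame(
    sample_id = "a", germline_brca1 = "maybe", germline_brca2 = "no",
    somatic_brca1 = "no", somatic_brca2 = "no", brca1_methylation = "no",
    loh_brca1 = "no", loh_brca2 = "no")), "yes, no, missing")
})
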