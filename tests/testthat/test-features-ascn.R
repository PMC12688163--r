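ascn_profile <- function(states, lens_mb, chrom = "1", sample_id = "S1",
                         genome = NULL) {
  ends <- cumsum(lens_mb * 1e6)
  starts <- c(1, utils::head(ends, -1) + 1)
  maj <- vapply(states, `[`, numeric(1), 1)
  mino <- vapply(states, `[`, numeric(1), 2)
  segment_table(data.frame(sample_id = sample_id, chrom = chrom,
                           start_bp = starts, end_bp = ends,
                           total_cn = maj + mino, major_cn = maj,
                           minor_cn = mino),
                allele_specific = TRUE, genome = genome)
}

test_that("LOH score counts bounded sub-chromosomal LOH regions", {
  g1 <- genome_annotation("1", 200e6, 80e6, 83e6)
  st <- ascn_profile(list(c(1, 1), c(1, 0), c(1, 1)), c(100, 20, 80))
  expect_equal(unname(loh_score(st, g1)), 1)
  short <- ascn_profile(list(c(1, 1), c(1, 0), c(1, 1)), c(100, 10, 90))
  expect_equal(unname(loh_score(short, g1)), 0)
  whole <- ascn_profile(list(c(1, 0)), c(200))
  expect_equal(unname(loh_score(whole, g1)), 0)  # whole-chromosome excluded
  # homozygous deletion (total 0) is not an LOH region
  homdel <- ascn_profile(list(c(1, 1), c(0, 0), c(1, 1)), c(100, 20, 80))
  expect_equal(unname(loh_score(homdel, g1)), 0)
})

test_that("TAI counts telomeric non-centromere-crossing imbalance", {
  g1 <- genome_annotation("1", 100e6, 45e6, 50e6)
  telo <- ascn_profile(list(c(1, 1), c(2, 1)), c(80, 20))
  expect_equal(unname(tai_score(telo, g1)), 1)
  crossing <- ascn_profile(list(c(1, 1), c(2, 1), c(1, 1)), c(40, 20, 40))
  expect_equal(unname(tai_score(crossing, g1)), 0)
  interstitial <- ascn_profile(list(c(1, 1), c(2, 1), c(1, 1)), c(60, 20, 20))
  expect_equal(unname(tai_score(interstitial, g1)), 0)
  # whole-arm imbalance touching the start counts once
  parm <- ascn_profile(list(c(2, 1), c(1, 1)), c(30, 70))
  expect_equal(unname(tai_score(parm, g1)), 1)
})

test_that("LST counts arm-wise transitions after smoothing", {
  g1 <- genome_annotation("1", 200e6, 95e6, 100e6)
  two <- ascn_profile(list(c(2, 1), c(3, 1)), c(40, 50))
  expect_equal(unname(lst_score(two, g1)), 1)
  # a 2 Mb interposed third state is smoothed away
  smoothed <- ascn_profile(list(c(2, 1), c(4, 0), c(3, 1)), c(40, 2, 48))
  expect_equal(unname(lst_score(smoothed, g1)), 1)
  single <- ascn_profile(list(c(2, 1)), c(90))
  expect_equal(unname(lst_score(single, g1)), 0)
  # transition with a short flank does not count
  shortflank <- ascn_profile(list(c(2, 1), c(3, 1)), c(8, 82))
  expect_equal(unname(lst_score(shortflank, g1)), 0)
})

test_that("scar scores equal the brute-force oracle on random profiles", {
  set.seed(101)
  g <- toy_genome()
  for (r in 1:60) {
    st <- random_ascn_profile(g, max_segs = 7)
    expect_equal(unname(loh_score(st, g)), unname(oracle_loh(st, g)))
    expect_equal(unname(tai_score(st, g)), unname(oracle_tai(st, g)))
    expect_equal(unname(lst_score(st, g)), unname(oracle_lst(st, g)))
  }
})

test_that("scar scores are invariant under state-preserving refragmentation", {
  set.seed(103)
  g <- toy_genome()
  for (r in 1:10) {
    st <- random_ascn_profile(g, max_segs = 5)
    frag <- refragment(st, n_cuts = 15)
    expect_equal(loh_score(st, g), loh_score(frag, g))
    expect_equal(tai_score(st, g), tai_score(frag, g))
    expect_equal(lst_score(st, g), lst_score(frag, g))
  }
})

test_that("scarHRD sums components and calls at 42", {
  res <- scarhrd_score(10, 15, 17)
  expect_equal(res$scarhrd, 42)
  expect_true(res$scarhrd_call)
  expect_false(scarhrd_score(20, 20, 1)$scarhrd_call)  # 41: below threshold
  expect_equal(scarhrd_score(0, 0, 0)$scarhrd, 0)
})

test_that("CN48 channelization follows the shipped schema and conserves counts", {
  g1 <- genome_annotation("1", 200e6, 80e6, 83e6)
  st <- ascn_profile(list(c(2, 0), c(1, 1), c(0, 0), c(1, 1)),
                     c(25, 75, 0.05, 99.95))
  counts <- cn48_catalogue(st)
  expect_equal(unname(counts[1, "2:LOH:10Mb-40Mb"]), 1)
  expect_equal(unname(counts[1, "0:homdel:0-100kb"]), 1)
  expect_equal(sum(counts), nrow(st))  # conservation

  set.seed(17)
  for (r in 1:10) {
    stp <- random_ascn_profile(toy_genome())
    expect_equal(sum(cn48_catalogue(stp)), nrow(stp))
  }
})

test_that("CN exposures recover planted mixtures and dominate a grid oracle", {
  cat <- synthetic_signature_catalogue("CN48", paste0("CN", c(1, 2, 6, 9, 17)),
                                       seed = 5)
  e <- c(CN1 = 20, CN2 = 0, CN6 = 7, CN9 = 0, CN17 = 12)
  counts <- rbind(S1 = as.numeric(unclass(cat) %*% e))
  rec <- cn_exposures(counts, cat, wanted = names(e))
  expect_equal(rec["S1", ], e, tolerance = 1e-6)

  zero <- rbind(S1 = rep(0, 48))
  expect_equal(unname(cn_exposures(zero, cat, wanted = names(e))["S1", ]),
               rep(0, 5))

  # noisy counts: NNLS residual must not exceed any coarse grid candidate
  set.seed(31)
  cat3 <- synthetic_signature_catalogue("CN48", c("CN1", "CN2", "CN17"), seed = 6)
  noisy <- as.numeric(unclass(cat3) %*% c(10, 4, 8)) + abs(rnorm(48, sd = 0.5))
  fit <- nnls_refit(noisy, cat3)
  res_fit <- sum((noisy - unclass(cat3) %*% fit)^2)
  grid <- seq(0, 20, length.out = 11)
  best_grid <- Inf
  for (a in grid) for (b in grid) for (c_ in grid)
    best_grid <- min(best_grid,
                     sum((noisy - unclass(cat3) %*% c(a, b, c_))^2))
  expect_lte(res_fit, best_grid + 1e-9)
})
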