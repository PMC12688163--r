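test_that("lognorm z-scores ln(x+1) within each cohort", {
  m <- matrix(c(0, exp(1) - 1, 2, 7), 2, 2,
              dimnames = list(c("a", "b"), c("f1", "f2")))
  fm <- feature_matrix(m, blocks = c("CNA", "CNA"))
  res <- lognorm(fm)
  # cohort values (0, e-1): ln+1 gives (0, 1), z with sample sd = +/- 0.7071
  expect_equal(unname(unclass(res$matrix)[, "f1"]),
               c(-sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-9)
  expect_equal(attr(res$matrix, "state"), "normalised")

  # per-cohort mean 0 / sd 1 on random data
  set.seed(5)
  big <- feature_matrix(matrix(abs(rnorm(200)), 20, 10,
                               dimnames = list(paste0("s", 1:20),
                                               paste0("f", 1:10))),
                        blocks = rep("SNV", 10))
  grp <- rep(c("c1", "c2"), each = 10)
  res2 <- lognorm(big, grp)
  for (g in c("c1", "c2")) {
    sub <- unclass(res2$matrix)[grp == g, ]
    expect_equal(unname(colMeans(sub)), rep(0, 10), tolerance = 1e-9)
    expect_equal(unname(apply(sub, 2, sd)), rep(1, 10), tolerance = 1e-9)
  }

  # constant feature -> zeros with warning
  cm <- feature_matrix(matrix(c(1, 1, 1, 2, 3, 4), 3, 2,
                              dimnames = list(1:3, c("k", "v"))),
                       blocks = c("CNA", "CNA"))
  expect_warning(rc <- lognorm(cm), "constant")
  expect_equal(unname(unclass(rc$matrix)[, "k"]), rep(0, 3))
})

test_that("stored parameters apply to small new cohorts", {
  set.seed(6)
  train <- feature_matrix(matrix(abs(rnorm(100)), 25, 4,
                                 dimnames = list(paste0("s", 1:25),
                                                 paste0("f", 1:4))),
                          blocks = rep("CNA", 4))
  res <- lognorm(train)
  small <- feature_matrix(unclass(train)[1:3, ], blocks = rep("CNA", 4))
  expect_warning(z <- apply_lognorm(small, res$params), "stored")
  expect_equal(unclass(z), unclass(res$matrix)[1:3, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  # large new cohorts are self-normalised
  expect_equal(unclass(apply_lognorm(train, res$params)),
               unclass(res$matrix), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Wilcoxon screen retains separated features and drops flat ones", {
  m0 <- cbind(flat = rep(1, 20), sep = c(abs(rnorm(10)), abs(rnorm(10)) + 50))
  rownames(m0) <- paste0("s", 1:20)
  x <- feature_matrix(m0, blocks = c("CNA", "CNA"))
  status <- rep(c("negative", "positive"), each = 10)
  rep_ <- wilcoxon_screen(x, status)
  expect_equal(rep_$wilcoxon_p[rep_$feature == "flat"], 1)
  expect_false(rep_$retained_after_screen[rep_$feature == "flat"])
  # complete separation 10 vs 10: exact p = 2 / choose(20, 10)
  expect_equal(rep_$wilcoxon_p[rep_$feature == "sep"], 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_true(rep_$retained_after_screen[rep_$feature == "sep"])

  # statistic equals an independent rank-sum computation on random features
  set.seed(20)
  m <- matrix(abs(rnorm(30 * 25)), 30, 25,
              dimnames = list(paste0("t", 1:30), paste0("f", 1:25)))
  fm <- feature_matrix(m, rep("SNV", 25))
  st <- rep(c("positive", "negative"), c(12, 18))
  got <- wilcoxon_screen(fm, st)$wilcoxon_p
  ora <- apply(m, 2, function(v)
    wilcox.test(v[st == "positive"], v[st == "negative"])$p.value)
  expect_equal(got, unname(ora), tolerance = 1e-12)

  expect_error(wilcoxon_screen(fm, rep("positive", 30)), "classes")
})

test_that("correlation pruning drops the larger-p member, overrides win", {
  set.seed(8)
  base <- abs(rnorm(40))
  m1 <- cbind(a = base, a_copy = base, b = abs(rnorm(40)),
              c = c(abs(rnorm(20)), abs(rnorm(20)) + 3))
  rownames(m1) <- paste0("s", 1:40)
  x <- feature_matrix(m1, blocks = rep("CNA", 4))
  status <- rep(c("negative", "positive"), each = 20)
  rep0 <- wilcoxon_screen(x, status, alpha = 1.1)  # keep all for the test
  pruned <- correlation_prune(x, rep0)
  dup <- pruned[pruned$feature %in% c("a", "a_copy"), ]
  expect_equal(sum(dup$final_retained), 1)  # exactly one copy survives
  expect_equal(na.omit(dup$pruned_by)[[1]],
               dup$feature[dup$final_retained])

  # r below the threshold: both kept
  m2 <- cbind(u = base, v = base + abs(rnorm(40, sd = 2)))
  rownames(m2) <- paste0("s", 1:40)
  y <- feature_matrix(m2, blocks = rep("SNV", 2))
  if (abs(cor(unclass(y))[1, 2]) <= 0.8) {
    repy <- correlation_prune(y, wilcoxon_screen(y, status, alpha = 1.1))
    expect_true(all(repy$final_retained))
  }

  # manual override forces the named victim
  ovr <- correlation_prune(x, rep0, manual_overrides = "a")
  expect_false(ovr$final_retained[ovr$feature == "a"])
  expect_true(ovr$final_retained[ovr$feature == "a_copy"])
  expect_error(correlation_prune(x, rep0, manual_overrides = "nope"), "nope")
})

test_that("selection is invariant to sample order", {
  set.seed(9)
  sim <- simulate_feature_level(sim_config(n_samples = 40, seed = 21))
  norm <- lognorm(sim$features)$matrix
  status <- sim$labels$hrd_status
  r1 <- select_features(norm, status)
  perm <- sample(nrow(norm))
  normp <- feature_matrix(unclass(norm)[perm, ], attr(norm, "blocks"),
                          state = "normalised")
  r2 <- select_features(normp, status[perm])
  expect_equal(r1, r2)
})

test_that("planted signal passes the screen; noise fails at about alpha", {
  set.seed(30)
  reps <- 60
  strong <- c("scarHRD", "SBS3", "CX3", "ID6")
  strong_kept <- stats::setNames(numeric(length(strong)), strong)
  noise_kept <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_samples = 80, unknown_fraction = 0, seed = 1000 + r)
    sim <- simulate_feature_level(cfg)
    norm <- lognorm(sim$features)$matrix
    rep_ <- wilcoxon_screen(norm, sim$labels$hrd_status)
    strong_kept <- strong_kept +
      rep_$retained_after_screen[match(strong, rep_$feature)]
    noise_kept <- noise_kept + rep_$retained_after_screen[rep_$feature == "CX2"]
  }
  # strong planted features nearly always pass the screen
  expect_true(all(strong_kept / reps >= 0.9))
  # pure-noise feature retained at roughly the alpha rate
  expect_lt(noise_kept / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
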