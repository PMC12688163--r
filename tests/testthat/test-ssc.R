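mk_training_data <- function(n = 60, seed = 7, unknown_fraction = 0.3) {
  sim <- simulate_feature_level(sim_config(n_samples = n, seed = seed,
                                           unknown_fraction = unknown_fraction))
  list(x = lognorm(sim$features)$matrix,
       status = sim$labels$hrd_status,
       truth = sim$truth$class)
}

test_that("self-training with no unlabelled pool equals the supervised fit", {
  d <- mk_training_data(n = 50, unknown_fraction = 0)
  cfg <- model_config("ASCN", model_registry()[["ASCN"]]$features,
                      n_trees = 100, seed = 42)
  clf <- self_train(d$x, d$status, cfg)
  expect_equal(clf$n_pseudo, 0)

  # plain forest with the same seed and arguments, fitted independently
  xm <- unclass(d$x)[, cfg$features]
  y <- factor(d$status, levels = c("negative", "positive"))
  set.seed(42)
  ref <- randomForest::randomForest(xm, y, ntree = 100,
                                    mtry = floor(sqrt(ncol(xm))),
                                    nodesize = 1, importance = FALSE)
  expect_identical(predict(clf, d$x)$probability,
                   unname(predict(ref, xm, type = "prob")[, "positive"]))
})

test_that("an unreachable confidence floor reduces to the supervised fit", {
  d <- mk_training_data(n = 50, unknown_fraction = 0.4)
  feats <- model_registry()[["ASCN"]]$features
  cfg_hi <- model_config("ASCN", feats, n_trees = 80, seed = 5,
                         confidence_floor = 1.01)
  clf_hi <- self_train(d$x, d$status, cfg_hi)
  expect_equal(clf_hi$n_pseudo, 0)
  sup <- self_train(unclass(d$x)[d$status != "unknown", ],
                    d$status[d$status != "unknown"],
                    model_config("ASCN", feats, n_trees = 80, seed = 5))
  expect_identical(predict(clf_hi, d$x)$probability,
                   predict(sup, d$x)$probability)
})

test_that("self-training respects its budget and never touches original labels", {
  d <- mk_training_data(n = 80, unknown_fraction = 0.5)
  cfg <- model_config("SNV+ASCN", model_registry()[["SNV+ASCN"]]$features,
                      n_trees = 80, seed = 9, batch_fraction = 0.1,
                      stop_fraction = 0.7)
  clf <- self_train(d$x, d$status, cfg)
  n_unl <- sum(d$status == "unknown")
  expect_lte(clf$n_pseudo, ceiling(0.7 * n_unl) + ceiling(0.1 * n_unl))
  expect_true(all(clf$training_log$added <= max(1, ceiling(0.1 * n_unl))))
  expect_equal(clf$n_labelled, sum(d$status != "unknown"))

  # reproducibility: same seed, bit-identical output
  clf2 <- self_train(d$x, d$status, cfg)
  expect_identical(predict(clf, d$x)$probability,
                   predict(clf2, d$x)$probability)
  expect_identical(clf$training_log, clf2$training_log)
})

test_that("prediction binds features by name and applies the >= convention", {
  d <- mk_training_data(n = 40, unknown_fraction = 0)
  feats <- model_registry()[["CNA"]]$features
  cfg <- model_config("CNA", feats, n_trees = 60, seed = 3)
  clf <- self_train(d$x, d$status, cfg)
  p <- predict(clf, d$x)
  shuffled <- unclass(d$x)[, rev(colnames(d$x))]
  expect_equal(predict(clf, shuffled)$probability, p$probability)
  clf$threshold <- p$probability[1]
  expect_true(predict(clf, d$x)$call[1])  # equality counts as positive
  expect_error(predict(clf, unclass(d$x)[, 1:3]), "missing feature")
})

test_that("max-F1 threshold equals the exhaustive scan on random sets", {
  thr <- optimal_threshold(c(0.2, 0.6, 0.9),
                           c("negative", "positive", "positive"))
  expect_equal(thr$threshold, 0.4)
  expect_equal(thr$f1, 1)

  # constant probabilities: boundary candidates only
  allsame <- optimal_threshold(rep(0.5, 6),
                               rep(c("positive", "negative"), 3))
  expect_equal(allsame$f1, oracle_best_f1(rep(0.5, 6),
                                          rep(c("positive", "negative"), 3)))

  set.seed(123)
  for (r in 1:200) {
    n <- sample(5:40, 1)
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    y <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- optimal_threshold(p, y)
    expect_equal(got$f1, oracle_best_f1(p, y), info = paste("rep", r))
  }
  expect_error(optimal_threshold(c(0.1, 0.9), rep("positive", 2)), "classes")
})

test_that("LOOCV runs one fold per labelled sample, deterministically", {
  d <- mk_training_data(n = 24, unknown_fraction = 0.25, seed = 15)
  feats <- model_registry()[["ASCN"]]$features
  cfg <- model_config("ASCN", feats, n_trees = 50, seed = 11)
  cv <- loocv_probabilities(d$x, d$status, cfg)
  expect_equal(nrow(cv), sum(d$status != "unknown"))
  expect_equal(cv$sample_id, rownames(d$x)[d$status != "unknown"])
  cv2 <- loocv_probabilities(d$x, d$status, cfg)
  expect_identical(cv$probability, cv2$probability)

  clf <- self_train(d$x, d$status, cfg)
  clf <- calibrate_threshold(clf, d$x, d$status)
  expect_gt(clf$threshold, 0)
  expect_lt(clf$threshold, 1)
})

test_that("feature importance covers the model features and ranks signal high", {
  d <- mk_training_data(n = 80, unknown_fraction = 0, seed = 33)
  feats <- model_registry()[["SNV+ASCN"]]$features
  cfg <- model_config("SNV+ASCN", feats, n_trees = 200, seed = 2)
  clf <- self_train(d$x, d$status, cfg)
  imp <- feature_importance(clf)
  expect_equal(sort(names(imp)), sort(feats))
  # the strongest planted feature outranks the pure-noise features
  noise <- intersect(c("CX2", "CN2", "SBS17b", "ID9", "ID15"), names(imp))
  expect_gt(imp["scarHRD"], max(imp[noise]))
})

test_that("pseudo-labels are added class-proportionally and accurately on separated data", {
  set.seed(88)
  d <- 6
  mk <- function(n, tag) {
    cls <- rep(c("positive", "negative"), length.out = n)
    x <- matrix(rnorm(n * d), n, d) +
      outer(as.numeric(cls == "positive"), rep(3, d))  # wide separation
    rownames(x) <- paste0(tag, seq_len(n))
    colnames(x) <- paste0("f", 1:d)
    list(x = x, cls = cls)
  }
  tr <- mk(20, "l"); un <- mk(100, "u")
  cfg <- model_config("bench", paste0("f", 1:d), n_trees = 80, seed = 4)
  clf <- self_train(rbind(tr$x, un$x), c(tr$cls, rep("unknown", 100)), cfg)
  expect_gt(clf$n_pseudo, 0)
  # additions stay near the labelled 50/50 class balance
  log <- clf$training_log
  expect_true(all(abs(log$positive - log$negative) <= 1))
  # with clear separation the self-trained model classifies held-out data
  # essentially perfectly
  te <- mk(100, "t")
  expect_gte(mean((predict(clf, te$x)$probability >= 0.5) ==
                    (te$cls == "positive")), 0.97)
})
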