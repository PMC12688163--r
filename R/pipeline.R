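#' Run the full analysis pipeline
#'
#' Chains the stages -- simulate (or load) a cohort, label it, extract the
#' three feature blocks, normalise, screen and prune features, train the
#' semi-supervised classifier, calibrate or set the threshold, predict and
#' evaluate -- writing every artifact into `out_dir` together with a
#' `run_manifest.yaml` recording the package version, seed and
#' configuration. Reruns with the same configuration are bit-identical.
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' top-level keys `seed`, `out_dir`, `model` (a registry id), `simulate`
#' (passed to [sim_config()]) or `inputs` (paths to `segments`,
#' `mutations`, `labels`, optional `genome`, `cx_exposures`), optional
#' `train` (overrides for [model_config()]), and optional `threshold`
#' (fixed threshold; when absent and `calibrate: true`, LOOCV max-F1
#' calibration is run).
#'
#' @param config Path to a YAML configuration file, or a list.
#' @return Invisibly, a list with the trained classifier, predictions,
#'   selection report and evaluation report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model_id <- if (is.null(config$model)) "SNV+ASCN" else config$model

  # ---- inputs: simulate or load ------------------------------------------
  if (!is.null(config$inputs)) {
    paths <- config$inputs
    for (p in unlist(paths))
      if (!file.exists(p)) stop("input file not found: ", p)
    genome <- if (is.null(paths$genome)) toy_genome() else read_genome(paths$genome)
    segments <- read_segments(paths$segments, allele_specific = TRUE,
                              genome = genome)
    mutations <- read_mutations(paths$mutations, format = "tsv")
    labels <- read_labels(paths$labels)
    cx <- if (is.null(paths$cx_exposures)) NULL else
      utils::read.delim(paths$cx_exposures, row.names = 1, check.names = FALSE)
    truth <- NULL
  } else {
    sim_args <- if (is.null(config$simulate)) list() else config$simulate
    sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
    genome <- sim$genome
    cohort <- simulate_genome_level(sim)
    segments <- cohort$segments
    mutations <- cohort$mutations
    labels <- cohort$labels
    truth <- cohort$truth
    cx <- NULL
  }
  lab <- label_cohort(labels, quiet = TRUE)
  status <- stats::setNames(lab$labels$hrd_status, lab$labels$sample_id)

  # ---- feature extraction ------------------------------------------------
  reg <- model_registry()
  sbs_cat <- synthetic_signature_catalogue(
    "SBS96", c("SBS1", "SBS2", "SBS3", "SBS5", "SBS6", "SBS8", "SBS13",
               "SBS17b", "SBS18", "SBS20", "SBS26", "SBS30"), seed = 101)
  id_cat <- synthetic_signature_catalogue("ID83", paste0("ID", 1:18), seed = 202)
  cn_cat <- synthetic_signature_catalogue(
    "CN48", paste0("CN", c(1, 2, 6, 7, 8, 9, 11, 17)), seed = 303)
  fm_cn <- cn_feature_matrix(segments, genome, cx = cx)
  fm_ascn <- ascn_feature_matrix(segments, genome, cn_catalogue = cn_cat)
  fm_snv <- snv_feature_matrix(mutations, sbs_cat, id_cat,
                               samples = rownames(fm_cn))
  fm <- cbind_features(fm_cn, fm_ascn, fm_snv)
  status <- status[rownames(fm)]
  write_feature_matrix(fm, file.path(out_dir, "features_raw.tsv"))

  norm <- lognorm(fm)
  write_feature_matrix(norm$matrix, file.path(out_dir, "features_normalised.tsv"))

  # ---- selection ---------------------------------------------------------
  report <- select_features(norm$matrix, status,
                            manual_overrides = c("td_region_size", "SBS2"))
  write_selection_report(report, file.path(out_dir, "selection_report.tsv"))

  # ---- training ----------------------------------------------------------
  wanted <- reg[[model_id]]$features
  avail <- intersect(wanted, colnames(norm$matrix))
  if (length(avail) < length(wanted))
    warning("model ", model_id, ": ", length(wanted) - length(avail),
            " registry feature(s) unavailable in this run; using ",
            length(avail))
  cfg_args <- c(list(model_id = model_id, features = avail, seed = seed),
                config$train)
  cfg <- do.call(model_config, cfg_args)
  clf <- self_train(norm$matrix, status, cfg)
  if (!is.null(config$threshold)) {
    clf$threshold <- config$threshold
  } else if (isTRUE(config$calibrate)) {
    clf <- calibrate_threshold(clf, norm$matrix, status)
  } else {
    clf$threshold <- 0.5
  }
  clf$norm_params <- norm$params

  # ---- prediction and evaluation -----------------------------------------
  preds <- predict(clf, norm$matrix)
  utils::write.table(preds, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- evaluate_predictions(preds$probability, status, clf$threshold)
  report_list <- list(model = model_id, threshold = clf$threshold,
                      n = length(status),
                      counts = as.list(lab$counts),
                      auc = ev$auc, aucpr = ev$aucpr,
                      tp = ev$tp, fn = ev$fn, fp = ev$fp, tn = ev$tn,
                      sensitivity = ev$sensitivity,
                      specificity = ev$specificity,
                      precision = ev$precision, mcc = ev$mcc)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report_list, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(report_list, file.path(out_dir, "report.yaml"))
  }
  manifest <- list(package = "hrdclass",
                   version = as.character(utils::packageVersion("hrdclass")),
                   seed = seed, model = model_id,
                   config = config,
                   artifacts = list.files(out_dir))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(list(classifier = clf, predictions = preds, selection = report,
                 evaluation = ev, truth = truth))
}
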