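#' Simulation configuration
#'
#' Study conditions for the synthetic cohorts used in testing and
#' calibration. Defaults emulate the statistical structure the classifier
#' assumes: a minority of truly HRD-positive tumours carrying many
#' large-scale scars and an HRD-like mutational-signature mixture (SBS3 and
#' ID6 enriched), a majority of HRD-negative tumours with few scars, and a
#' fraction of samples whose BRCA1/2 evidence is masked (status unknown).
#' Scar-event counts are Poisson with class-conditional means sized to the
#' toy genome (absolute counts are genome-size-limited, so the
#' human-genome scarHRD threshold of 42 is not meaningful on the toy
#' genome; only relative separation is).
#'
#' @param n_samples Cohort size.
#' @param prevalence Fraction of truly HRD-positive samples.
#' @param unknown_fraction Fraction of samples whose label is masked.
#' @param genome A [genome_annotation()] (default [toy_genome()]).
#' @param loh_mean,tai_mean,lst_mean Named `c(pos=, neg=)` Poisson means of
#'   planted LOH regions, telomeric AI regions and balanced-state LST
#'   regions (each LST region contributes two transitions).
#' @param snv_burden,indel_burden Named `c(pos=, neg=)` Poisson means of
#'   mutation counts per sample.
#' @param sbs_mixture,id_mixture Named lists `pos`/`neg` of signature
#'   mixture weights (each sums to 1).
#' @param feature_shift Named per-feature class shift (log scale) for the
#'   feature-level generator; defaults cover the registry's 30 features.
#' @param noise_sd Log-scale noise standard deviation (feature level).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 100, prevalence = 0.3,
                       unknown_fraction = 0.3, genome = toy_genome(),
                       loh_mean = c(pos = 6, neg = 1),
                       tai_mean = c(pos = 3, neg = 0.5),
                       lst_mean = c(pos = 4, neg = 0.5),
                       snv_burden = c(pos = 150, neg = 80),
                       indel_burden = c(pos = 60, neg = 30),
                       sbs_mixture = list(
                         pos = c(SBS3 = 0.45, SBS5 = 0.25, SBS1 = 0.15,
                                 SBS13 = 0.10, SBS8 = 0.05),
                         neg = c(SBS1 = 0.35, SBS5 = 0.40, SBS13 = 0.15,
                                 SBS18 = 0.10)),
                       id_mixture = list(
                         pos = c(ID6 = 0.5, ID8 = 0.2, ID1 = 0.2, ID2 = 0.1),
                         neg = c(ID1 = 0.5, ID2 = 0.3, ID4 = 0.2)),
                       feature_shift = default_feature_shift(),
                       noise_sd = 1, seed = 1) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            unknown_fraction >= 0, unknown_fraction <= 1,
            all(loh_mean >= 0), all(tai_mean >= 0), all(lst_mean >= 0))
  for (mx in c(sbs_mixture, id_mixture))
    if (abs(sum(mx) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(list(n_samples = n_samples, prevalence = prevalence,
                 unknown_fraction = unknown_fraction, genome = genome,
                 loh_mean = loh_mean, tai_mean = tai_mean,
                 lst_mean = lst_mean, snv_burden = snv_burden,
                 indel_burden = indel_burden, sbs_mixture = sbs_mixture,
                 id_mixture = id_mixture, feature_shift = feature_shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_feature_shift <- function() {
  c(cna_burden = 0.6, cna_load = 0.5, macn = 0.4, td_score = 0.3,
    chromothripsis_score = 0.2, CX1 = 0.7, CX2 = 0, CX3 = 1.0, CX5 = 0.4,
    scarHRD = 1.4, CN1 = 0.3, CN2 = 0, CN9 = 0.3, CN17 = 0.8,
    SBS1 = 0.2, SBS3 = 1.2, SBS5 = 0.2, SBS8 = 0.5, SBS13 = 0.3,
    SBS17b = 0, SBS18 = 0.2, SBS26 = 0, SBS30 = 0.3,
    ID1 = 0.2, ID2 = 0, ID4 = 0.2, ID6 = 1.0, ID8 = 0.5, ID9 = 0, ID15 = 0)
}

# draw BRCA evidence flags consistent with the true class; masked samples
# get all-missing flags (status unknown)
make_label_table <- function(sample_id, class, unknown_fraction) {
  n <- length(sample_id)
  masked <- stats::runif(n) < unknown_fraction
  flag <- function(v) v
  rows <- lapply(seq_len(n), function(i) {
    f <- stats::setNames(rep("no", 7),
                         c("germline_brca1", "germline_brca2", "somatic_brca1",
                           "somatic_brca2", "brca1_methylation", "loh_brca1",
                           "loh_brca2"))
    if (masked[i]) {
      f[] <- "missing"
    } else if (class[i] == "positive") {
      if (stats::runif(1) < 2 / 3) {  # germline mutation + LOH
        gene <- sample(1:2, 1)
        f[paste0("germline_brca", gene)] <- "yes"
        f[paste0("loh_brca", gene)] <- "yes"
      } else {                        # BRCA1 promoter methylation + LOH
        f["brca1_methylation"] <- "yes"
        f["loh_brca1"] <- "yes"
      }
    } else {
      # no mutations anywhere; LOH flags uninformative
      f["loh_brca1"] <- sample(c("yes", "no"), 1)
      f["loh_brca2"] <- sample(c("yes", "no"), 1)
    }
    data.frame(sample_id = sample_id[i], t(f), stringsAsFactors = FALSE)
  })
  hrd_label_table(do.call(rbind, rows))
}

# free-interval bookkeeping for event placement on chromosome arms
arm_table <- function(genome) {
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i)
    data.frame(chrom = genome$chrom[i],
               arm = c("p", "q"),
               start = c(1, genome$cen_end[i] + 1),
               end = c(genome$cen_start[i] - 1, genome$length[i]))))
}

#' Genome-level synthetic cohort
#'
#' Per sample: draws the true class, plants class-conditional counts of
#' qualifying scar events on a diploid (1/1) baseline -- interstitial LOH
#' regions (state 1/0, 16-25 Mb, >= 10 Mb margins), telomeric allelic
#' imbalance regions (state 2/1, 10-18 Mb, not crossing the centromere)
#' and interstitial balanced regions (state 2/2, 12-20 Mb) each creating
#' two large-segment transitions -- then draws SBS96/ID83 channel counts
#' from the class's signature mixture and materialises them as mutation
#' rows with consistent flanking sequence. Events that no longer fit on
#' the genome are skipped, and the truth record reports what was actually
#' planted, so planted counts are exactly recoverable by the scar scores.
#'
#' @param config A [sim_config()].
#' @return A list: `segments` (`ascn_segment_table`), `mutations`
#'   (`mutation_table`), `labels` (`hrd_label_table`, status filled, masked
#'   samples unknown), `truth` (per-sample class and planted event
#'   counts).
#' @export
simulate_genome_level <- function(config) {
  set.seed(config$seed)
  g <- config$genome
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  cls <- ifelse(stats::runif(n) < config$prevalence, "positive", "negative")
  margin <- 10e6
  seg_rows <- list()
  truth <- list()
  for (i in seq_len(n)) {
    k <- if (cls[i] == "positive") "pos" else "neg"
    want <- c(loh = stats::rpois(1, config$loh_mean[k]),
              tai = stats::rpois(1, config$tai_mean[k]),
              lst = stats::rpois(1, config$lst_mean[k]))
    free <- arm_table(g)
    free$telo <- TRUE  # each arm still has its telomeric end free
    events <- list()
    place <- function(len, type) {
      # interstitial events need `margin` on both sides; telomeric events
      # anchor at the arm's outer end and need one interior margin
      if (type == "tai") {
        ok <- which(free$telo & (free$end - free$start + 1) >= len + margin)
        if (length(ok) == 0) return(FALSE)
        j <- ok[sample.int(length(ok), 1)]
        outer_p <- free$arm[j] == "p" & free$start[j] == 1
        outer_q <- free$arm[j] == "q" & free$end[j] == g$length[g$chrom == free$chrom[j]]
        if (!outer_p && !outer_q) return(FALSE)
        if (outer_p) { s <- free$start[j]; e <- s + len - 1; free$start[j] <<- e + margin + 1 }
        else { e <- free$end[j]; s <- e - len + 1; free$end[j] <<- s - margin - 1 }
        free$telo[j] <<- FALSE
        events[[length(events) + 1]] <<- data.frame(
          chrom = free$chrom[j], start_bp = s, end_bp = e,
          major_cn = 2, minor_cn = 1, type = type)
        return(TRUE)
      }
      ok <- which((free$end - free$start + 1) >= len + 2 * margin)
      if (length(ok) == 0) return(FALSE)
      j <- ok[sample.int(length(ok), 1)]
      lo <- free$start[j] + margin
      hi <- free$end[j] - margin - len + 1
      s <- floor(stats::runif(1, lo, hi + 1))
      e <- s + len - 1
      # split the free interval; keep the larger remainder, add the other
      new_row <- free[j, ]
      new_row$start <- e + margin + 1
      new_row$telo <- free$telo[j] && free$arm[j] == "q"
      free$end[j] <<- s - margin - 1
      free$telo[j] <<- free$telo[j] && free$arm[j] == "p"
      free <<- rbind(free, new_row)
      st <- switch(type, loh = c(1, 0), lst = c(2, 2))
      events[[length(events) + 1]] <<- data.frame(
        chrom = free$chrom[j], start_bp = s, end_bp = e,
        major_cn = st[1], minor_cn = st[2], type = type)
      TRUE
    }
    planted <- c(loh = 0, tai = 0, lst = 0)
    for (t in seq_len(want["tai"]))
      planted["tai"] <- planted["tai"] + place(round(stats::runif(1, 10e6, 18e6)), "tai")
    for (t in seq_len(want["loh"]))
      planted["loh"] <- planted["loh"] + place(round(stats::runif(1, 16e6, 25e6)), "loh")
    for (t in seq_len(want["lst"]))
      planted["lst"] <- planted["lst"] + place(round(stats::runif(1, 12e6, 20e6)), "lst")
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(chrom = character(0), start_bp = numeric(0),
                 end_bp = numeric(0), major_cn = numeric(0),
                 minor_cn = numeric(0), type = character(0))
    # fill the rest of each chromosome with the diploid baseline
    for (ch in g$chrom) {
      evc <- ev[ev$chrom == ch, , drop = FALSE]
      evc <- evc[order(evc$start_bp), , drop = FALSE]
      bounds <- c(1, rbind(evc$start_bp - 1, evc$end_bp + 1),
                  g$length[g$chrom == ch])
      starts <- bounds[seq(1, length(bounds), 2)]
      ends <- bounds[seq(2, length(bounds), 2)]
      keep <- ends >= starts
      base <- data.frame(chrom = ch, start_bp = starts[keep],
                         end_bp = ends[keep], major_cn = 1, minor_cn = 1,
                         type = "baseline")
      ev <- rbind(ev[ev$chrom != ch, , drop = FALSE], evc, base)
    }
    ev$sample_id <- ids[i]
    ev$total_cn <- ev$major_cn + ev$minor_cn
    seg_rows[[i]] <- ev[, c("sample_id", "chrom", "start_bp", "end_bp",
                            "total_cn", "major_cn", "minor_cn")]
    truth[[i]] <- data.frame(sample_id = ids[i], class = cls[i],
                             planted_loh = planted["loh"],
                             planted_tai = planted["tai"],
                             planted_lst_regions = planted["lst"],
                             # every interstitial event contributes two
                             # large-segment transitions, a telomeric one
                             expected_lst = 2 * (planted["loh"] + planted["lst"]) +
                               planted["tai"],
                             row.names = NULL)
  }
  segments <- segment_table(do.call(rbind, seg_rows), allele_specific = TRUE,
                            genome = g)
  mutations <- simulate_mutations(ids, cls, config)
  labels <- make_label_table(ids, cls, config$unknown_fraction)
  labels <- label_cohort(labels, quiet = TRUE)$labels
  list(segments = segments, mutations = mutations, labels = labels,
       truth = do.call(rbind, truth))
}

# materialise multinomial channel draws as mutation rows with flanks
simulate_mutations <- function(ids, cls, config) {
  sbs_cat <- synthetic_signature_catalogue(
    "SBS96", union(names(config$sbs_mixture$pos), names(config$sbs_mixture$neg)),
    seed = 101)
  id_cat <- synthetic_signature_catalogue(
    "ID83", union(names(config$id_mixture$pos), names(config$id_mixture$neg)),
    seed = 202)
  # one (ref, alt, flanks) exemplar per channel, reused for every draw
  lut <- rbind(
    do.call(rbind, lapply(sbs96_channels(), function(ch)
      data.frame(channel = ch, as.data.frame(sbs96_example_variant(ch))))),
    do.call(rbind, lapply(id83_channels(), function(ch)
      data.frame(channel = ch, as.data.frame(id83_example_variant(ch))))))
  rows <- list()
  for (i in seq_along(ids)) {
    k <- if (cls[i] == "positive") "pos" else "neg"
    pr_sbs <- as.numeric(unclass(sbs_cat)[, names(config$sbs_mixture[[k]])] %*%
                           config$sbs_mixture[[k]])
    pr_id <- as.numeric(unclass(id_cat)[, names(config$id_mixture[[k]])] %*%
                          config$id_mixture[[k]])
    cnt_snv <- stats::rmultinom(1, stats::rpois(1, config$snv_burden[k]), pr_sbs)[, 1]
    cnt_id <- stats::rmultinom(1, stats::rpois(1, config$indel_burden[k]), pr_id)[, 1]
    chans <- c(rep(sbs96_channels(), cnt_snv), rep(id83_channels(), cnt_id))
    if (length(chans) == 0) next
    v <- lut[match(chans, lut$channel), ]
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = ids[i], chrom = "1", pos = 1000 * seq_along(chans) + 1000,
      ref_allele = v$ref, alt_allele = v$alt,
      flank_5p = v$flank_5p, flank_3p = v$flank_3p)
  }
  mutation_table(do.call(rbind, rows))
}

#' Construct an example variant for an SBS96 channel
#' @param channel An SBS96 channel name like `"A[C>A]A"`.
#' @return A list with `ref`, `alt`, `flank_5p`, `flank_3p`.
#' @export
sbs96_example_variant <- function(channel) {
  m <- regmatches(channel,
                  regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", channel))[[1]]
  if (length(m) != 5) stop("unknown SBS96 channel: ", channel)
  list(ref = m[3], alt = m[4],
       flank_5p = paste0("CGTACGTAC", m[2]),
       flank_3p = paste0(m[5], "CATGCATGC"))
}

#' Feature-level synthetic cohort
#'
#' Draws a raw feature matrix directly: per feature, the log-scale value is
#' Gaussian with a class shift (`feature_shift`) added for truly
#' HRD-positive samples, exponentiated back to the raw non-negative scale
#' so that the ln(x+1) z-score normalisation recovers the planted Gaussian
#' structure. Used to test selection, training and evaluation in isolation
#' from the genomic feature extraction.
#'
#' @param config A [sim_config()].
#' @return A list: `features` (raw `feature_matrix`), `labels`
#'   (`hrd_label_table` with status filled), `truth` (class and shifts).
#' @export
simulate_feature_level <- function(config) {
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  cls <- ifelse(stats::runif(n) < config$prevalence, "positive", "negative")
  shifts <- config$feature_shift
  reg <- model_registry()
  blocks <- stats::setNames(rep("SNV", length(shifts)), names(shifts))
  blocks[names(shifts) %in% reg[["CNA"]]$features] <- "CNA"
  blocks[names(shifts) %in% c("scarHRD", "CN1", "CN2", "CN6", "CN7", "CN8",
                              "CN9", "CN11", "CN17", "LOH", "TAI", "LST")] <- "ASCN"
  z <- sapply(names(shifts), function(f)
    2 + shifts[f] * (cls == "positive") +
      stats::rnorm(n, sd = config$noise_sd))
  raw <- pmax(exp(z) - 1, 0)
  rownames(raw) <- ids
  fm <- feature_matrix(raw, blocks = blocks, state = "raw")
  labels <- make_label_table(ids, cls, config$unknown_fraction)
  labels <- label_cohort(labels, quiet = TRUE)$labels
  list(features = fm, labels = labels,
       truth = list(class = stats::setNames(cls, ids), shifts = shifts))
}
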