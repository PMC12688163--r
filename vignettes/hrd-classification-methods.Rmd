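---
title: "Multi-modal semi-supervised HRD classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal semi-supervised HRD classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdclass)
```

## The problem

Homologous recombination deficiency (HRD) makes tumours sensitive to PARP
inhibitors and platinum chemotherapy, so calling HRD status reliably matters
for treatment selection. The most accurate sequencing-based callers need
whole-genome data; cheaper assays (shallow WGS, SNP arrays, WES) see only
part of the evidence. `hrdclass` implements a family of classifiers of
increasing data appetite — total copy number only, plus allele-specific copy
number (ASCN), plus SNV/indel mutational signatures — so that the model can
be matched to whatever assay is available, and quantifies what each added
data block buys.

Ground truth is defined by biallelic BRCA1/2 inactivation: a pathogenic
germline or somatic BRCA1/2 mutation, or BRCA1 promoter hypermethylation,
combined with loss of the second allele (LOH). Samples with no detected
BRCA1/2 mutation, or with LOH absent from both genes, are negatives; samples
whose evidence is incomplete are *unknown* and are exploited by the
semi-supervised learner rather than discarded.

## Labelling rule

`derive_hrd_status()` evaluates, in order: the three positive clauses
(mutation + same-gene LOH; methylation + BRCA1 LOH), then the two negative
clauses (all four mutation flags `"no"`, or both LOH flags `"no"`), else
unknown. Two deliberate readings are worth flagging:

* *Missing is never "no"*: a sample with unassayed mutation status cannot
  become a negative by the no-mutation clause. The methylation flag does not
  participate in the negative clause at all — the rule text defines
  negativity by mutations and LOH only. A sample with methylation present
  but no LOH on either gene is therefore classified negative by the LOH
  clause; the function reports these edge cases via a message.
* The rule is total: a property test enumerates all 3^7 flag combinations
  and checks every one receives exactly one status.

## Feature blocks

**CNA block.** Six summary scores of the total-CN profile — genome fraction
altered (`cna_burden`), number of altered segments (`cna_load`), mean
altered copy number (`macn`), tandem-duplication count and mean size
(`td_score`, `td_region_size`), and a chromothripsis-like oscillation score
— plus exposures of six breast-cancer copy-number signatures (CX1–CX5,
CX9). The published score set comes from an external scoring routine whose
formulas are not printed anywhere usable; the definitions here are
re-derivations of the one-line descriptions, with every threshold exposed:
a segment is *altered* when `|CN − 2| > 0.1` (absolute CN, not log-ratio); a
TD event is a segment strictly above both flanks (one flank at chromosome
ends) of length ≤ 10 Mb; the chromothripsis score counts chromosomes whose
longest run of segments oscillating between exactly two CN states (state
tolerance 0.1) reaches 10. Because the formulas are re-derived, absolute
values will differ from the original pipeline's; only ordering behaviour is
asserted, never equality with published cohort values. All scores are
computed after `merge_adjacent()`, which makes them invariant to how finely
a profile was segmented (property-tested by random refragmentation).

CX signature quantification itself (a mixture-model encoding) is out of
scope; the supported production path is a precomputed exposure table, with
an NNLS refit against a CX catalogue available for synthetic data.

**ASCN block.** The three genomic scar scores and their sum:

* **LOH score** — regions with `minor_cn = 0`, `total_cn ≥ 1`, longer than
  15 Mb but shorter than the chromosome's covered extent.
* **TAI** — allelic-imbalance regions (`major_cn ≠ minor_cn`) reaching a
  covered chromosome end without spanning the centromere. The cited primary
  definition gives no size floor, so `min_len` defaults to 0, and
  `telomere_slack` defaults to 0 bp beyond the declared coverage ends; both
  are arguments.
* **LST** — after deleting segments < 3 Mb (the larger neighbour absorbs
  the gap — a deterministic, oracle-reproducible smoothing) and merging
  same-state neighbours, transitions between adjacent segments ≥ 10 Mb with
  gap ≤ 3 Mb, counted per chromosome arm. Segments straddling the
  centromere are split at its midpoint, following the arm-wise primary
  definition.
* **scarHRD** = LOH + TAI + LST, with the conventional positivity cut-off
  of 42 (meaningful only for human-scale genomes).

The block also carries exposures of eight breast-cancer allele-specific CN
signatures (CN1, 2, 6, 7, 8, 9, 11, 17), obtained by channelizing segments
into the 48-channel schema — heterozygosity state (homozygous deletion /
LOH / heterozygous) × total-CN bin × length bin — and refitting by NNLS.
The channel list with its bin edges ships as a data file
(`inst/extdata/cn48_channels.tsv`) that the code reads; the file, not code
constants, is the source of truth, so any disagreement over binning is
inspectable.

**SNV block.** SBS96 and ID83 catalogues built from mutation tables and
refit against signature catalogues. SBS96 uses the standard
pyrimidine-strand convention (exhaustively tested: all 192 stranded
contexts map to the 96 channels exactly twice). ID83 follows the canonical
83-channel indel schema defined by `inst/extdata/id83_channels.tsv`:
repeat bins count reference repeat units *including* the deleted copy (and
excluding the inserted one), and deletions not in a repeat are checked for
microhomology against the 3' flank. Checking only the 3' side is a
documented simplification — some reference implementations also check the
5' flank — and is the most drift-prone convention in the schema, which is
why it is pinned in a data file and exercised by a round-trip test that
reconstructs an example variant for every channel. DNVs are excluded from
both catalogues (neither schema covers them). Refitting is plain
non-negative least squares over the fixed breast-cancer signature subsets;
no sparsity penalty, deterministic. Exposures default to the raw count
scale; whether to pre-normalise them to proportions before the log
transform is unspecified upstream, so it is a switch (`normalise`).

## Normalisation and feature selection

Within each cohort and feature, values are transformed as
`z = (ln(x+1) − mean) / sd` (sample sd). Degenerate features (sd = 0 within
a cohort) become all-zero with a warning rather than NaN. For prediction on
new data the package normalises the new cohort within itself when it has at
least 20 samples, otherwise it applies the stored training parameters with
a warning — cohort-internal normalisation is undefined for single samples,
so both strategies exist and the cut-over is explicit.

Screening is a two-sided Wilcoxon rank-sum test per feature
(positive vs negative samples only), retaining features with p ≤ 0.05, with
deliberately no multiplicity correction — the screen is a permissive
pre-filter. Pruning then removes within-block collinearity: pairs with
|Pearson r| > 0.8, processed by descending |r|, drop the larger-p member —
unless a manual override names the victim. The shipped override list
(`td_region_size`, `SBS2`) reproduces the published manual choices, making
the automated rule and the published set coincide.

## Model registry

Five primary configurations — CNA (9 features), ASCN (14 = 9 CNA + 5
ASCN), SNV (16), SNV+CNA (25), SNV+ASCN (30) — plus `no_scarHRD` and
`scarHRD_only` for comparison. The published work reports the per-block
*counts* of screen survivors but not their names, so the registry's default
feature lists are the package's own reconstruction: the CNA nine keep the
five summary scores (minus the pruned TD region size) and CX1, CX2, CX3,
CX5; the ASCN five are scarHRD plus CN1, CN2, CN9, CN17 (CN17 is
HRD-associated); the SNV sixteen keep nine SBS (SBS2 pruned) and seven ID
signatures. Every list is overridable per model. The published decision
thresholds (0.382 / 0.450 / 0.344 / 0.296 / 0.374) are stored as reference
metadata only — a threshold is always calibrated on the data at hand.

## Semi-supervised self-training

The base learner is a random forest (500 trees, `mtry = ⌊√p⌋`, minimum node
size 1); class imbalance is handled by the calibrated threshold, not by
resampling. Self-training follows the Yarowsky wrapper: fit on the labelled
samples, score the unlabelled pool, move the most confident predictions
into the training set as pseudo-labels, refit, and repeat until a set
fraction of the pool is consumed. The controls are not printed in the
source material, so the package fixes conventional defaults and exposes
all of them: confidence floor 0.5 on the class-maximum probability, batch
10% of the initial pool per iteration, stop after 70% of the pool, at most
40 iterations. Batches are filled class-proportionally to the labelled
class distribution, the standard guard against class drift in
self-labelling. Original labels are never removed or flipped (assertable
from the training log), and the whole procedure is bit-reproducible given
the seed; with an empty pool it reduces exactly — bit-identically — to the
supervised forest.

Thresholds are calibrated by leave-one-out cross-validation: each labelled
sample is held out, the model is retrained (unknown-status samples remain
available as the pool), and the held-out probabilities are pooled; the
decision threshold maximises F1 over candidates at midpoints between
consecutive sorted unique probabilities plus the 0/1 boundaries, ties going
to the smallest candidate. Calls at exactly the threshold are positive.

### When self-training does not help

The package's own two-Gaussian benchmark (d = 10, overall class shift 2.0,
20 labelled + 400 unlabelled, accuracy on 400 held-out samples, 25 seeds)
shows self-training *below* the supervised-only forest (≈ 0.65 vs ≈ 0.72
mean accuracy) under the default controls. The mechanism is instructive:
random-forest probabilities are overconfident far from the training data,
so confidence-ranked pseudo-labelling preferentially imports the initial
20-sample model's boundary errors and freezes them; pseudo-label accuracy
stays high (97–99%) yet the induced training-set geometry still costs
accuracy. Only a near-degenerate confidence floor (0.99) reaches parity in
a control sweep. The defaults are kept — they are the conventional
settings, and tuning them to flatter a benchmark would misrepresent the
method — but users should not expect self-training with a forest base
learner to beat supervised fitting on well-specified low-dimensional
problems; its value lies in cohorts where the unlabelled pool genuinely
extends coverage of the feature space.

## Evaluation conventions

* ROC AUC is the Mann–Whitney statistic (ties count one half), tested to
  1e-12 against an O(n²) pairwise oracle.
* PR AUC integrates the step-wise curve over achievable operating points
  (one point per distinct score, each recall increment × precision at the
  new point). PR-area conventions differ between packages, so this one is
  pinned and oracle-tested; constant scores give exactly the prevalence
  P/(P+N).
* Confusion metrics report TP/FN/FP/TN over labelled samples; unknown-status
  samples are tallied separately and never enter the denominators. MCC is 0
  when a marginal is empty.
* Fisher association tests use the exact two-sided hypergeometric p-value;
  the odds ratio is the cross-product with Haldane's +0.5 correction applied
  to all cells when any cell is zero. This differs from the conditional-MLE
  odds ratio `fisher.test()` reports — the closed form is deterministic and
  exactly testable. Multiplicity is controlled by Benjamini–Hochberg over
  the event list. Copy-number contrasts discretise CN into loss/neutral/gain
  (−1/0/1 for CN <2 / =2 / >2) and test loss-vs-neutral and gain-vs-neutral.

## The synthetic cohort generator

Real training data for this problem are controlled-access; the generator
supplies cohorts with the statistical structure the pipeline assumes, at
two levels.

*Genome level*: a 4-chromosome toy genome (200/150/120/100 Mb, centromeres
at 40%) carries a diploid baseline on which class-conditional Poisson
counts of events are planted — interstitial LOH regions (1/0, 16–25 Mb),
telomeric AI regions (2/1, 10–18 Mb, never crossing the centromere), and
balanced 2/2 regions creating large-segment transitions — with 10 Mb
margins so that every planted event is recovered *exactly* by the scar
scores. Interstitial events necessarily create two LST transitions each and
a telomeric event one, so the truth record stores the resulting expected
LST count in closed form; the round trip is exact, not approximate
(`sim_scar_recovery_fraction = 1` in the acceptance output). Default
intensities (LOH 6/1, TAI 3/0.5, LST 4/0.5 for positive/negative classes)
are sized to the toy genome: absolute scar counts are genome-size-limited,
so the human-genome scarHRD threshold of 42 is not meaningful here — only
relative class separation is. Mutations are materialised as actual variant
rows (with flanking context built per channel) from multinomial draws over
class-specific signature mixtures, HRD-positive samples enriched for SBS3
and ID6, so catalogue building and refitting are exercised end to end.
BRCA evidence flags are generated to exercise all positive clauses
(germline + LOH with probability 2/3, methylation + LOH with 1/3), and a
configurable fraction of samples has all flags masked, independently of
class (chi-square-checked).

*Feature level*: log-scale Gaussians with per-feature class shifts,
exponentiated to the raw scale so `lognorm()` recovers the planted
structure; used to test selection, training and evaluation in isolation.
The default shift vector gives every block some signal (strongest:
scarHRD 1.4, SBS3 1.2, ID6 and CX3 1.0) and leaves several features at
exactly zero as planted noise.

What the generator does **not** emulate: real segmentation noise and
purity/ploidy error, inter-feature correlation structure beyond the shared
class label, cohort batch effects, signature flat-spectrum bleed, and
human-genome scale. Passing tests therefore demonstrate algorithmic
correctness and the information ordering of the model family, not clinical
performance.

## Problem sizes and numerical choices

Simulation-based checks use cohorts of 70 samples (10 seeds) for the
information-ordering comparison, 200 samples (10 seeds) for the null
calibration, and 100-tree forests; these sizes give stable means while
keeping the default test run desk-scale. NNLS uses the active-set solver
in `pracma::lsqnonneg` (deterministic). Signature-catalogue columns must
sum to 1 within 1e-3 on read (then renormalised exactly); catalogue columns
are validated to 1e-9 afterwards. Coordinates are 1-based inclusive
throughout, as in the consumed segment formats. Sex chromosomes are kept in
I/O but excluded from scores by default (`autosomes_only`), since ASCN
calls there are unreliable. Tri-state evidence flags serialise as 1/0/NA.

## Known limitations

* CNA summary-score values are re-derivations; they rank samples like the
  originals on synthetic data but are not numerically interchangeable with
  any published cohort's values.
* CX signature quantification is pass-through by design.
* ID83 microhomology is 3'-only (see above).
* Real-genome annotations (chromosome lengths and centromeres) must be
  supplied by the caller in the documented TSV format; the package ships
  only the toy genome, deliberately, rather than approximate coordinates.
* Self-training with a forest base learner can underperform supervised
  fitting (see above); the classifier reports its full training log so this
  is auditable per run.
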