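---
title: "Consensus peaks and marker panels for cfDNA methylation profiling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus peaks and marker panels for cfDNA methylation profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cfpeakpanel` implements an analysis pipeline for enrichment-based
cell-free DNA (cfDNA) modification profiling — cfMeDIP-seq for
5-methylcytosine (5mC) and chemical-labeling pulldown for
5-hydroxymethylcytosine (5hmC) — aimed at case/control classification
(the motivating application is pancreatic ductal adenocarcinoma versus
healthy plasma). The pipeline consumes per-sample aligned-fragment BED
files and per-sample narrowPeak calls from an upstream peak caller;
everything upstream of those files (trimming, alignment, duplicate
removal, the peak caller itself) is out of scope.

The stages are:

1. **Fixed-width peaks.** Each raw peak is reduced to the 201 bp window
   `[summit - 100, summit + 101)`. Peaks whose window crosses a
   chromosome end are dropped. Fixed-width peaks concentrate the
   analysis on the highest-enrichment core of each region and make peak
   scores comparable.
2. **Score per million (SPM).** Within a sample, caller scores are
   rescaled to sum to 1e6, removing depth- and peak-count-driven scale
   differences between samples.
3. **Iterative overlap removal.** Within a peak list, the
   highest-scoring peak is kept and everything overlapping it (>= 1 bp)
   discarded, repeatedly. Ties are broken by (chromosome, start)
   ascending, which makes the procedure fully deterministic; the
   leftmost of two equal-scoring overlapping peaks wins.
4. **Reproducible group templates.** Peaks with SPM >= 5 from all of a
   group's samples are pooled and collapsed by the same iterative
   procedure; a template's coordinates are those of its highest-SPM
   instance. A template is retained when at least `ceil(N% x group
   size)` samples have an overlapping peak (SPM >= 5). The SPM >= 5
   filter is applied both when pooling and when counting support.
5. **Consensus list.** Case and control template lists are concatenated
   and collapsed once more; peaks overlapping the blacklist (>= 1 bp)
   or on chrX/chrY/chrM are removed. The result is non-overlapping,
   exactly 201 bp wide, and inside chromosome bounds — invariants the
   test suite asserts on every synthetic run.
6. **Choice of N.** For each N in 10..90% (step 10), the consensus list
   is rebuilt and a peaks-by-samples 0/1 occupancy matrix formed (1 =
   the sample has >= 1 raw fixed-width peak overlapping the consensus
   peak). Per peak, a two-sided Fisher exact test of presence/absence
   by case/control is computed with BH correction; the chosen N
   maximizes the number of peaks with FDR < 0.05. "Most significant
   peaks" is not a uniquely defined criterion; we operationalize it as
   this count and also report the per-N minimum p-value for audit. Ties
   go to the smaller N.
7. **FPKM quantification.** Fragments are counted per consensus peak
   (>= 1 bp overlap; half-open abutment does not count) and converted
   to FPKM = count / ((length/1000) x (total_mapped/1e6)). The
   library-size denominator is the sample's total mapped fragment
   count, not the in-peak total; one properly paired fragment counts as
   one unit.
8. **Differential peaks.** Per-peak Welch t-tests on FPKM with BH
   correction, a |log2FC| > 0.8 filter on pseudocount-stabilized group
   means (`log2((m1 + 0.01)/(m0 + 0.01))`), and a configurable
   threshold mode (raw p or FDR) because different analyses in this
   design use different rules (p < 0.01 for the 5mC set, p < 0.001 for
   5hmC, FDR < 0.01 inside stability selection).
9. **Stability selection.** Over the training set: R rounds of
   stratified K-fold partitioning; per training subset (all but one
   fold), the differential filter is re-applied *to that subset only*
   (no leakage from the full training set) to define candidates, then B
   elastic-net logistic fits at fixed alpha are run, each with
   re-randomized internal cross-validation folds for lambda — the only
   stochastic element available at fixed data and alpha. Candidates
   with nonzero coefficients in >= 95% of the B fits form the subset
   panel; a marker "appears in a round" when it enters any of that
   round's K subset panels, and the final panel keeps markers present
   in >= 3 rounds. The published description says both "10-fold" and
   "divided into five folds, four of which were selected"; K is a
   parameter and the operative default is K = 5, matching the
   four-in-five description. Retention is counted over rounds by
   default, with a `retention = "subsets"` alternative (the Results
   text counts subsets).
10. **Final model and wd-score.** A penalized logistic fit on the panel
    (glmnet; lambda by internal stratified cross-validation minimizing
    deviance; features standardized inside the fit, coefficients
    reported on the FPKM scale). The weighted diagnosis score is
    `wd = sum_k coef(k) x FPKM(k)` — no intercept term, matching its
    printed definition. Because wd differs from the linear predictor
    only by the constant intercept, AUC computed on wd-scores equals
    AUC computed on predicted probabilities; the suite asserts this
    exactly.
11. **Alpha selection.** `select_alpha()` maximizes *validation*
    accuracy over alpha in 0.1..0.9, ties to the smaller alpha. This
    leaks validation labels into a modeling choice; the procedure is
    retained deliberately because it is the published one, and the
    returned object carries an explicit leakage note. Per-channel
    defaults are alpha = 0.2 (5mC) and 0.1 (5hmC).
12. **Integration.** The two channels' panels are concatenated with
    channel-tagged feature ids over the paired samples (a locus present
    in both panels contributes two features) and a fresh model is fit.

# The synthetic cohort generator

The study's raw data sit behind a hospital portal with no public
accession, so the package ships a generator whose defaults *are* the
study conditions used for validation, and a ground-truth table that
makes parameter recovery testable:

- **Genome**: two 5 Mb chromosomes (plus chrX in tests that exercise
  chromosome exclusion). Small enough to run in seconds, large enough
  that 2,000 regions with >= 500 bp separation fit without crowding.
- **Regions**: 2,000 non-overlapping 300 bp enriched regions placed
  uniformly at random on a slot grid enforcing >= 500 bp gaps.
- **Counts**: per region r and sample j, fragments ~ NegBin(mu =
  mu_r x s_j x b_j x 2^(lfc_r x case_j), size phi). Negative-binomial
  rather than Poisson because enrichment data are overdispersed; phi
  defaults to 10 and is configurable so the t-test's robustness can be
  stress-tested. Baseline means mu_r scatter lognormally around
  mean_count = 50.
- **Effects**: 30 differential regions at |log2FC| = 1.5, half
  elevated in cases (`frac_hyper = 0.5`; setting most effects negative
  on the 5hmC channel reproduces the global hydroxymethylation loss
  seen in tumors).
- **Library size**: lognormal factors s_j (sdlog 0.15, mean 1).
- **Batch**: optional multiplicative factors b_j modeling
  enrichment-efficiency bias — they scale in-region signal but not
  depth, so they survive FPKM normalization and give the per-batch
  standardization knob something real to remove. Batches are assigned
  round-robin within group, so they are balanced by construction.
- **Fragments**: lengths ~ Normal(167, 30) truncated to [50, 500] bp
  (mono-nucleosomal cfDNA); centers jittered around region centers;
  uniform background fragments at 0.002/bp.
- **Peak calls**: a region is emitted as a sample peak when its count
  beats a Poisson background test at p < 1e-4, with score =
  round(-10 log10 p) and a summit jittered <= 20 bp — a deterministic
  stand-in for re-running a peak caller, keeping the generator
  self-contained.
- **Spike-ins**: three species (unmodified / 5mC / 5hmC); the
  channel-matched species receives a binomial share at the configured
  specificity (default 0.85).
- **Channels**: paired cohorts share exactly
  `round(channel_overlap x n_regions)` region coordinates (default
  0.3, bracketing the observed 16.7%–30% cross-channel overlap);
  differential regions are drawn independently per channel so the two
  channels can carry complementary signal.

Everything is driven by one seed (`withr::with_seed`), and writing the
same spec twice produces byte-identical files.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: GC and fragment-length bias,
copy-number structure, fragmentomic end motifs, correlated regions
(regions are independent given the sample factors), realistic genome
annotation, sequencing error, or the upstream caller's behavior on
marginal peaks. Results on this generator validate the pipeline's
statistical machinery and bookkeeping, not clinical performance.

# Numerical and design choices

- **Coordinates** are 0-based half-open everywhere, matching
  BED/narrowPeak; conversion to the 1-based closed convention of
  IRanges happens only inside two internal helpers, so file I/O never
  shifts coordinates. A narrowPeak summit offset of -1 falls back to
  the interval midpoint.
- **Overlap rule**: ">= 1 bp" throughout (the common reading of the
  method's "(> 1 bp)" overlap notation, consistent with interval-tool
  defaults).
- **Support threshold rounding**: `ceil(N% x group size)` — the
  stricter reading; the source is silent on rounding.
- **Fisher memoisation**: occupancy tables repeat heavily across
  peaks, so identical (present-in-case, present-in-control) pairs share
  one `fisher.test` call; this makes the 9-point N grid cheap.
- **Odds-ratio backgrounds** (the largest interpretive decision in the
  annotation module): element enrichment uses base-pair composition
  (peak bp in/out of class against class bp in/out of genome, 0.5
  continuity adjustment); region-set enrichment uses width-matched
  peaks shuffled uniformly over the genome with a seeded generator,
  per sample. The published figures do not define their background;
  both choices are explicit and documented here.
- **Promoter definition** is a parameter of the caller-supplied
  annotation (the convention TSS +/- 2 kb is used in the analysis
  scripts); no genome build is bundled.
- **Unlogged FPKM by default** for both the t-tests and the model,
  mirroring the literal "t test on FPKM" description; a
  `log2_transform` flag propagates through differential calling and
  modeling for sensitivity analysis.
- **Degenerate inputs**: all-zero peak scores, zero-margin tables,
  empty groups, singleton batches, genes shorter than two bins, and
  single-feature glmnet designs (padded with a constant zero column)
  all have defined behavior exercised by tests.
- **Seed fan-out**: one master seed hashes per stage name
  (`stage_seed`), so adding a stage never shifts another stage's
  random stream; two runs with the same config are bit-identical, and
  `run_pipeline` writes an md5 manifest to prove it.

# Problem sizes used in validation

The reference conditions for end-to-end checks are 40 cases + 40
controls, 2,000 peaks per channel, 30 truth markers at |log2FC| = 1.5,
mean count 50, dispersion 10, with stability selection scaled to R = 3
rounds, K = 5 folds and B = 25 repeats (the full-scale defaults R = 5,
B = 100 change only compute, not structure). Null-calibration checks
use 20-30 x 2,000-region cohorts with no planted signal; integration
checks use 600-region paired channels with 15 markers each. At these
sizes the pipeline recovers >= 70% of truth markers with held-out AUC
>= 0.95 in nearly every seed, null cohorts stay under 1% false
positives at FDR < 0.01, and integrated models match the best single
channel to within 0.02 AUC.

# Known limitations

- The t-test on unlogged FPKM is the published procedure, not the
  best-powered choice for overdispersed data; count-model alternatives
  (negative-binomial GLMs) are deliberately out of scope.
- Alpha selection on the validation set is optimistically biased by
  construction (see above).
- ComBat-style batch correction is not reimplemented; the per-batch
  standardization knob is plumbing for simulated batch effects, not a
  substitute analysis.
- The published cohort's headline metrics (validation AUCs 0.96-0.997)
  cannot be recomputed without the cohort itself; the package instead
  verifies every computable printed statistic (the cohort-table
  chi-squared p-values) and validates the machinery by parameter
  recovery on synthetic cohorts.

```{r example}
library(cfpeakpanel)
sim <- generate_cohort(cohort_spec(seed = 1))
res <- run_pipeline(sim, pipeline_config(seed = 1, N_fixed = 30,
                                         R = 3, K = 5, B = 25))
res$val_eval$auc
```
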