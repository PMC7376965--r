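# Shared fixtures: peak builders and independent oracles.

make_peaks <- function(chrom, start, end, score,
                       summit = floor((start + end) / 2),
                       spm = NA_real_, sample_id = "s1") {
  data.frame(chrom = chrom, start = start, end = end,
             name = sprintf("p%d", seq_along(start)), score = score,
             strand = ".", signal = score, pvalue = -1, qvalue = -1,
             summit = summit, spm = spm, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_case = 10, n_control = 10, n_regions = 120,
         n_diff = 8, lfc = 2, chroms = c(chrS1 = 2e6, chrS2 = 2e6)),
    list(...))
  do.call(cohort_spec, args)
}

# Brute-force oracle for the iterative overlap-removal procedure:
# repeatedly extract the single best remaining peak (highest score,
# ties by chrom then start) and delete everything overlapping it.
# Deliberately naive and independent of the package's implementation.
greedy_removal_oracle <- function(peaks) {
  sc <- if (!is.null(peaks$spm) && !anyNA(peaks$spm)) peaks$spm else peaks$score
  remaining <- peaks
  remaining$.score <- sc
  kept <- peaks[0, , drop = FALSE]
  while (nrow(remaining) > 0) {
    ord <- order(-remaining$.score, remaining$chrom, remaining$start)
    top <- remaining[ord[1], , drop = FALSE]
    kept <- rbind(kept, top[, names(peaks), drop = FALSE])
    ov <- remaining$chrom == top$chrom &
      remaining$start < top$end & remaining$end > top$start
    remaining <- remaining[!ov, , drop = FALSE]
  }
  kept <- kept[order(kept$chrom, kept$start, kept$end), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

random_peak_instance <- function(n, chroms = c("c1", "c2")) {
  start <- sample.int(2000, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(50:300, n, replace = TRUE),
             name = sprintf("p%d", seq_len(n)),
             score = sample(1:20, n, replace = TRUE), strand = ".",
             signal = 0, pvalue = -1, qvalue = -1,
             summit = start + 10, spm = NA_real_, sample_id = "s1",
             stringsAsFactors = FALSE)
}

# Two-sided Fisher p by full hypergeometric enumeration (the rule:
# sum of probabilities of all tables with fixed margins no more likely
# than the observed one).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  kk <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(kk, m, n, k)
  sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Overlap-based truth recovery: fraction of differential truth regions
# overlapped by at least one selected consensus peak.
truth_recovery <- function(truth, consensus, markers) {
  sel <- consensus[match(markers, consensus$peak_id), , drop = FALSE]
  tru <- truth[truth$differential, , drop = FALSE]
  if (nrow(tru) == 0) return(NA_real_)
  g1 <- GenomicRanges::GRanges(tru$chrom, IRanges::IRanges(tru$start + 1, tru$end))
  g2 <- GenomicRanges::GRanges(sel$chrom, IRanges::IRanges(sel$start + 1, sel$end))
  mean(GenomicRanges::countOverlaps(g1, g2) > 0)
}
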