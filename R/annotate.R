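#' Genomic-element distribution and enrichment of peaks
#'
#' For each element class (CDS, exon, intron, UTRs, promoter,
#' intergenic, ...): the percentage of peaks overlapping the class by
#' >= 1 bp, and a base-pair-background odds ratio
#' `(peak bp in class / peak bp outside) / (class bp / non-class bp)`
#' with a 0.5 bp continuity adjustment on every cell so fully
#' contained or fully disjoint configurations stay finite.
#'
#' @param peaks peak interval data frame.
#' @param elements named list of interval data frames, one per class.
#' @param genome_size total genome length in bp.
#' @return data frame per class: `class`, `percent`, `odds_ratio`,
#'   `log2_or`.
#' @export
element_overlap <- function(peaks, elements, genome_size) {
  if (nrow(peaks) == 0L) stop("empty peak list")
  peak_bp <- sum(peaks$end - peaks$start)
  out <- lapply(names(elements), function(cl) {
    iv <- elements[[cl]]
    pct <- 100 * mean(overlaps_any(peaks, iv))
    in_bp <- overlap_bp(peaks, iv)
    class_bp <- sum(merged_width(iv))
    or <- ((in_bp + 0.5) / (peak_bp - in_bp + 0.5)) /
      ((class_bp + 0.5) / (genome_size - class_bp + 0.5))
    data.frame(class = cl, percent = pct, odds_ratio = or,
               log2_or = log2(or), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

merged_width <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  as.numeric(GenomicRanges::width(GenomicRanges::reduce(as_granges0(iv))))
}

#' Uniformly shuffle peaks across the genome keeping widths
#'
#' @param peaks peak interval data frame.
#' @param chrom_sizes named chromosome lengths.
#' @param seed seed for reproducible placement.
#' @return data frame of shuffled intervals with the same widths.
#' @export
shuffle_peaks <- function(peaks, chrom_sizes, seed = 1L) {
  withr::with_seed(seed, {
    w <- peaks$end - peaks$start
    # chromosome chosen proportionally to placeable length
    placeable <- pmax(chrom_sizes - max(w), 1)
    ci <- sample.int(length(chrom_sizes), nrow(peaks), replace = TRUE,
                     prob = placeable)
    start <- floor(stats::runif(nrow(peaks), 0, chrom_sizes[ci] - w))
    data.frame(chrom = names(chrom_sizes)[ci], start = start,
               end = start + w, stringsAsFactors = FALSE)
  })
}

#' Per-sample overlap enrichment and FPKM in a region set
#'
#' For each sample: (a) the odds ratio of its peaks overlapping the
#' region set (>= 1 bp) against the expectation from width-matched
#' peaks shuffled uniformly over the genome (seeded), as a 2x2 table
#' overlapping/not x observed/shuffled with a 0.5 continuity
#' adjustment; (b) when fragment sets are supplied, the sample's FPKM
#' over the region set (fragments in regions, region-set length as the
#' kb denominator). Group differences are assessed with the Wilcoxon
#' rank-sum test.
#'
#' @param sample_peaks named list of per-sample peak data frames.
#' @param regions region-set interval data frame (e.g. one histone
#'   mark's domains).
#' @param chrom_sizes named chromosome lengths.
#' @param fragment_sets optional named list of `fragment_set`s.
#' @param groups optional named group labels for the comparison.
#' @param seed shuffle seed.
#' @return list with `per_sample` (data frame: `sample_id`,
#'   `log2_or`, optional `region_fpkm`) and, when `groups` is given,
#'   `or_test` / `fpkm_test` (`assoc_test`s, case vs control).
#' @export
regionset_stats <- function(sample_peaks, regions, chrom_sizes,
                            fragment_sets = NULL, groups = NULL, seed = 1L) {
  if (nrow(regions) == 0L) stop("empty region set")
  region_kb <- sum(merged_width(regions)) / 1000
  rows <- lapply(names(sample_peaks), function(sid) {
    pk <- sample_peaks[[sid]]
    obs <- sum(overlaps_any(pk, regions))
    shuf <- shuffle_peaks(pk, chrom_sizes, seed = stage_seed(seed, sid))
    exp_ <- sum(overlaps_any(shuf, regions))
    n <- nrow(pk)
    or <- ((obs + 0.5) / (n - obs + 0.5)) / ((exp_ + 0.5) / (n - exp_ + 0.5))
    row <- data.frame(sample_id = sid, n_peaks = n, n_overlap = obs,
                      n_expected = exp_, log2_or = log2(or),
                      stringsAsFactors = FALSE)
    if (!is.null(fragment_sets)) {
      fs <- fragment_sets[[sid]]
      n_in <- sum(count_overlaps0(fs$fragments, regions) > 0)
      row$region_fpkm <- n_in / region_kb / (fs$total_mapped / 1e6)
    }
    row
  })
  per_sample <- do.call(rbind, rows)
  out <- list(per_sample = per_sample)
  if (!is.null(groups)) {
    g <- groups[per_sample$sample_id]
    out$or_test <- wilcoxon_rank_sum(per_sample$log2_or[g == "case"],
                                     per_sample$log2_or[g == "control"])
    if (!is.null(per_sample$region_fpkm)) {
      out$fpkm_test <- wilcoxon_rank_sum(per_sample$region_fpkm[g == "case"],
                                         per_sample$region_fpkm[g == "control"])
    }
  }
  out
}

#' Metagene coverage profile from TSS to TES with flanks
#'
#' Bins each gene into `flank_bins` upstream bins over `flank` bp, a
#' length-normalized gene body of `body_bins` bins, and `flank_bins`
#' downstream bins; counts fragments overlapping each bin; reverses
#' minus-strand genes so profiles read 5' to 3'; averages across genes
#' and normalizes so the mean flank coverage is 1. Genes shorter than
#' 2 body bins are skipped and counted.
#'
#' @param fragments interval data frame (or `fragment_set`) of
#'   coverage fragments.
#' @param genes data frame with `chrom`, `start`, `end`, `strand`
#'   (TSS = `start` on "+", `end` on "-").
#' @param flank flanking distance in bp.
#' @param body_bins,flank_bins bin counts.
#' @return list `profile` (numeric vector of length
#'   `2*flank_bins + body_bins`), `n_genes`, `n_skipped`.
#' @export
metagene_profile <- function(fragments, genes, flank = 3000L,
                             body_bins = 100L, flank_bins = 30L) {
  frg <- if (inherits(fragments, "fragment_set")) fragments$fragments else fragments
  nbins <- 2L * flank_bins + body_bins
  total <- numeric(nbins)
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    glen <- genes$end[i] - genes$start[i]
    if (glen < 2L * body_bins) { n_skipped <- n_skipped + 1L; next }
    up <- seq(genes$start[i] - flank, genes$start[i], length.out = flank_bins + 1)
    body <- seq(genes$start[i], genes$end[i], length.out = body_bins + 1)
    down <- seq(genes$end[i], genes$end[i] + flank, length.out = flank_bins + 1)
    edges <- c(up[-(flank_bins + 1)], body, down[-1])
    bins <- data.frame(chrom = genes$chrom[i],
                       start = floor(edges[-length(edges)]),
                       end = ceiling(edges[-1]))
    cov <- bin_depth(bins, frg[frg$chrom == genes$chrom[i], , drop = FALSE])
    if (!is.na(genes$strand[i]) && genes$strand[i] == "-") cov <- rev(cov)
    total <- total + cov
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable genes")
  prof <- total / n_used
  flank_idx <- c(seq_len(flank_bins), nbins - seq_len(flank_bins) + 1L)
  denom <- mean(prof[flank_idx])
  if (denom > 0) prof <- prof / denom
  list(profile = prof, n_genes = n_used, n_skipped = n_skipped)
}

# Mean per-bp fragment depth in each bin (overlapped fragment bp
# divided by bin width).
bin_depth <- function(bins, frg) {
  w <- bins$end - bins$start
  if (nrow(frg) == 0L) return(numeric(nrow(bins)))
  hits <- GenomicRanges::findOverlaps(as_granges0(bins), as_granges0(frg))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(bins$end[q], frg$end[s]) - pmax(bins$start[q], frg$start[s])
  depth <- numeric(nrow(bins))
  if (length(q)) {
    agg <- tapply(ov, q, sum)
    depth[as.integer(names(agg))] <- agg
  }
  depth / w
}
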