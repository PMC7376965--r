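#' Reduce peaks to fixed width around their summits
#'
#' Each peak is replaced by the interval `[summit - half_width,
#' summit + half_width + 1)` — 201 bp at the default — and peaks whose
#' fixed-width interval would cross either chromosome end are dropped.
#'
#' @param peaks peak data frame (needs `summit`).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param half_width extension on either side of the summit (bp).
#' @return peak data frame with updated `start`/`end`.
#' @export
fix_width <- function(peaks, chrom_sizes, half_width = 100L) {
  missing_chr <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(missing_chr)) {
    stop("chromosome(s) missing from size table: ",
         paste(missing_chr, collapse = ", "))
  }
  start <- peaks$summit - half_width
  end <- peaks$summit + half_width + 1
  keep <- start >= 0 & end <= unname(chrom_sizes[peaks$chrom])
  out <- peaks[keep, , drop = FALSE]
  out$start <- start[keep]
  out$end <- end[keep]
  rownames(out) <- NULL
  out
}

#' Normalize one sample's peak scores to score per million
#'
#' Rescales the upstream caller scores of a single sample so that they
#' sum to 1e6, making peak scores comparable across samples with
#' different peak counts and sequencing depths.
#'
#' @param peaks peaks of one sample.
#' @return peaks with the `spm` column filled; `sum(spm) == 1e6`.
#' @export
spm_normalize <- function(peaks) {
  if (nrow(peaks) == 0L) return(peaks)
  tot <- sum(peaks$score)
  if (tot <= 0) stop("cannot normalize: all peak scores are zero")
  peaks$spm <- peaks$score / tot * 1e6
  peaks
}

#' Iterative removal of overlapping peaks
#'
#' Greedy selection: repeatedly keep the highest-scoring remaining peak
#' and discard every peak overlapping it by >= 1 bp, until none remain.
#' Scores are `spm` when filled, otherwise the raw `score`. Ties are
#' broken deterministically by (chrom, start) ascending, so the leftmost
#' of two equal-scoring overlapping peaks wins.
#'
#' @param peaks peak data frame.
#' @return the non-overlapping subset, sorted by coordinate.
#' @export
iterative_removal <- function(peaks) {
  n <- nrow(peaks)
  if (n <= 1L) return(peaks)
  sc <- peak_scores(peaks)
  ord <- order(-sc, peaks$chrom, peaks$start)
  gr <- as_granges0(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep_self <- qh != sh
  adj <- split(sh[keep_self], factor(qh[keep_self], levels = seq_len(n)))
  alive <- rep(TRUE, n)
  kept <- logical(n)
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    nb <- adj[[i]]
    if (length(nb)) alive[nb] <- FALSE
  }
  out <- sort_intervals(peaks[kept, , drop = FALSE])
  rownames(out) <- NULL
  out
}

peak_scores <- function(peaks) {
  if (!is.null(peaks$spm) && !anyNA(peaks$spm)) peaks$spm else peaks$score
}

#' Group-level reproducible peak templates
#'
#' Pools all fixed-width peaks of a group's samples with score per
#' million >= `spm_min`, collapses them into candidate templates by
#' [iterative_removal()] (template coordinates are those of the
#' highest-spm instance), counts per-template supporting samples (a
#' sample supports a template if it has >= 1 raw peak with spm >=
#' `spm_min` overlapping it by >= 1 bp), and retains templates supported
#' by at least `ceiling(N_pct/100 * group size)` samples.
#'
#' @param sample_peaks named list of per-sample fixed-width,
#'   spm-normalized peak data frames (the group's samples).
#' @param N_pct reproducibility threshold as a percentage.
#' @param spm_min minimum score per million, applied both when pooling
#'   and when counting support.
#' @return template data frame with a `support` column.
#' @export
group_reproducible <- function(sample_peaks, N_pct, spm_min = 5) {
  if (length(sample_peaks) == 0L) stop("empty group")
  filtered <- lapply(sample_peaks, function(p) p[p$spm >= spm_min, , drop = FALSE])
  pool <- do.call(rbind, filtered)
  rownames(pool) <- NULL
  if (nrow(pool) == 0L) {
    out <- empty_peaks()
    out$support <- integer(0)
    return(out)
  }
  templates <- iterative_removal(pool)
  support <- Reduce(`+`, lapply(filtered, function(p)
    as.integer(overlaps_any(templates, p))))
  templates$support <- support
  min_support <- ceiling(N_pct / 100 * length(sample_peaks))
  out <- templates[support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the final consensus peak set
#'
#' Concatenates the group-specific template lists, resolves overlaps
#' between groups with another [iterative_removal()] pass, and removes
#' templates overlapping the blacklist (>= 1 bp) or lying on excluded
#' chromosomes. The result is the non-overlapping, fixed-width
#' consensus peak list.
#'
#' @param group_lists list of group template data frames (e.g. case and
#'   control lists from [group_reproducible()]).
#' @param blacklist optional interval data frame of excluded regions.
#' @param excluded_chroms chromosomes removed outright.
#' @param chrom_sizes optional named vector; asserted against if given.
#' @return a `consensus_peaks` object: the peak data frame (with
#'   `peak_id`) plus attributes recording provenance.
#' @export
build_consensus <- function(group_lists, blacklist = NULL,
                            excluded_chroms = c("chrX", "chrY", "chrM"),
                            chrom_sizes = NULL) {
  stopifnot(length(group_lists) >= 1L)
  pooled <- do.call(rbind, lapply(group_lists, function(g) {
    g$support <- NULL
    g
  }))
  rownames(pooled) <- NULL
  cons <- iterative_removal(pooled)
  cons <- cons[!(cons$chrom %in% excluded_chroms), , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    cons <- cons[!overlaps_any(cons, blacklist), , drop = FALSE]
  }
  if (!is.null(chrom_sizes)) validate_intervals(cons, chrom_sizes, "consensus")
  cons <- sort_intervals(cons)
  cons$peak_id <- sprintf("peak_%05d", seq_len(nrow(cons)))
  rownames(cons) <- NULL
  structure(cons, class = c("consensus_peaks", "data.frame"))
}

#' Peak-presence occupancy matrix
#'
#' Zero-one matrix with rows = consensus peaks and columns = samples;
#' an entry is 1 iff the sample has at least one raw fixed-width peak
#' overlapping the consensus peak by >= 1 bp.
#'
#' @param consensus consensus peak data frame.
#' @param sample_peaks named list of per-sample peak data frames (all
#'   samples, both groups).
#' @return integer matrix (peaks x samples).
#' @export
occupancy <- function(consensus, sample_peaks) {
  stopifnot(!is.null(names(sample_peaks)))
  m <- vapply(sample_peaks, function(p)
    as.integer(overlaps_any(consensus, p)), integer(nrow(consensus)))
  if (nrow(consensus) == 1L) m <- matrix(m, nrow = 1L,
                                         dimnames = list(NULL, names(sample_peaks)))
  rownames(m) <- consensus$peak_id
  m
}

#' Per-peak Fisher tests on an occupancy matrix
#'
#' Two-sided Fisher's exact test of the 2x2 table presence/absence x
#' case/control for every consensus peak, with BH correction.
#' Identical tables share one test (memoised), which keeps the grid
#' search cheap.
#'
#' @param occ occupancy matrix from [occupancy()].
#' @param groups character vector ("case"/"control") along columns.
#' @return data frame `peak_id`, `n_case`, `n_control`, `p`, `q`.
#' @export
occupancy_fisher <- function(occ, groups) {
  stopifnot(ncol(occ) == length(groups))
  is_case <- groups == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("both groups must be present")
  a <- as.integer(occ[, is_case, drop = FALSE] %*% rep(1L, n1))
  c_ <- as.integer(occ[, !is_case, drop = FALSE] %*% rep(1L, n0))
  key <- paste(a, c_)
  uniq <- !duplicated(key)
  pu <- vapply(which(uniq), function(i) {
    fisher_exact_2x2(a[i], n1 - a[i], c_[i], n0 - c_[i])$p_value
  }, numeric(1))
  p <- pu[match(key, key[uniq])]
  data.frame(peak_id = rownames(occ), n_case = a, n_control = c_,
             p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
}

#' Choose the reproducibility threshold N over a grid
#'
#' For each candidate N, the caller supplies that N's occupancy matrix;
#' per-peak Fisher tests are run and the N giving the largest number of
#' peaks with BH-FDR below `fdr` is chosen (ties broken toward the
#' smaller N). The minimum p-value per N is also reported for audit.
#'
#' @param occ_by_N named list (names = N values) of occupancy matrices.
#' @param groups group labels along the columns of every matrix.
#' @param fdr FDR threshold defining a "significant" peak.
#' @return list with `chosen_N` and `summary` (per-N table: peak count,
#'   significant count, min p).
#' @export
select_N <- function(occ_by_N, groups, fdr = 0.05) {
  stopifnot(length(occ_by_N) >= 1L, !is.null(names(occ_by_N)))
  summ <- do.call(rbind, lapply(names(occ_by_N), function(nm) {
    ft <- occupancy_fisher(occ_by_N[[nm]], groups)
    data.frame(N = as.numeric(nm), n_peaks = nrow(ft),
               n_significant = sum(ft$q < fdr),
               min_p = if (nrow(ft)) min(ft$p) else NA_real_)
  }))
  ord <- order(-summ$n_significant, summ$N)
  list(chosen_N = summ$N[ord[1]], summary = summ)
}

#' Build per-sample fixed-width, spm-normalized peak lists
#'
#' Convenience wrapper applying [fix_width()] then [spm_normalize()] to
#' every sample's raw peak calls.
#'
#' @param raw_peaks named list of per-sample narrowPeak data frames.
#' @param chrom_sizes named chromosome length vector.
#' @param half_width see [fix_width()].
#' @return named list of processed peak data frames.
#' @export
prepare_sample_peaks <- function(raw_peaks, chrom_sizes, half_width = 100L) {
  lapply(raw_peaks, function(p) spm_normalize(fix_width(p, chrom_sizes, half_width)))
}

#' Full consensus construction for one N
#'
#' Runs [group_reproducible()] per group, [build_consensus()], and
#' [occupancy()] over all samples.
#'
#' @param sample_peaks named list of processed per-sample peaks.
#' @param groups named character vector (sample_id -> "case"/"control").
#' @param N_pct reproducibility threshold.
#' @param spm_min minimum score per million.
#' @param blacklist,excluded_chroms,chrom_sizes passed to
#'   [build_consensus()].
#' @return list with `consensus`, `occupancy`, `group_lists`.
#' @export
consensus_for_N <- function(sample_peaks, groups, N_pct, spm_min = 5,
                            blacklist = NULL,
                            excluded_chroms = c("chrX", "chrY", "chrM"),
                            chrom_sizes = NULL) {
  groups <- groups[names(sample_peaks)]
  gl <- lapply(split(names(sample_peaks), groups), function(ids)
    group_reproducible(sample_peaks[ids], N_pct, spm_min))
  cons <- build_consensus(gl, blacklist, excluded_chroms, chrom_sizes)
  list(consensus = cons, occupancy = occupancy(cons, sample_peaks),
       group_lists = gl)
}
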