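#' Count fragments overlapping each consensus peak
#'
#' A fragment is counted once for every peak it overlaps by >= 1 bp
#' (half-open abutment is zero overlap and does not count). Since
#' consensus peaks are disjoint, a fragment can hit two peaks only by
#' spanning the gap between them, in which case both count it.
#'
#' @param consensus consensus peak data frame.
#' @param fragments a `fragment_set` or a plain interval data frame.
#' @return integer vector of counts along consensus rows.
#' @export
count_fragments <- function(consensus, fragments) {
  frg <- if (inherits(fragments, "fragment_set")) fragments$fragments else fragments
  count_overlaps0(consensus, frg)
}

#' FPKM from counts
#'
#' Fragments per kilobase of region per million mapped fragments:
#' `count / ((length/1000) * (total_mapped/1e6))`.
#'
#' @param counts fragment counts (vector or matrix, regions x samples).
#' @param length_bp region lengths in bp (recycled along rows).
#' @param total_mapped per-sample library sizes (scalar or per-column).
#' @return FPKM on the same shape as `counts`.
#' @export
fpkm_from_counts <- function(counts, length_bp, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(length_bp <= 0)) stop("region length must be > 0")
  if (is.matrix(counts)) {
    counts / (length_bp / 1000) /
      rep(total_mapped / 1e6, each = nrow(counts))
  } else {
    counts / ((length_bp / 1000) * (total_mapped / 1e6))
  }
}

#' Build the peaks-by-samples FPKM signal matrix
#'
#' @param consensus consensus peak data frame.
#' @param fragment_sets named list of `fragment_set`s.
#' @param metadata sample metadata (must cover every fragment set).
#' @return a `signal_matrix`: list with `fpkm` (peaks x samples),
#'   `counts`, `metadata`, `peaks` and `peak_length`.
#' @export
signal_matrix <- function(consensus, fragment_sets, metadata) {
  missing_md <- setdiff(names(fragment_sets), metadata$sample_id)
  if (length(missing_md)) {
    stop("sample(s) missing from metadata: ", paste(missing_md, collapse = ", "))
  }
  counts <- vapply(fragment_sets, function(fs) count_fragments(consensus, fs),
                   integer(nrow(consensus)))
  if (nrow(consensus) == 1L) {
    counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, names(fragment_sets)))
  }
  rownames(counts) <- consensus$peak_id
  total <- vapply(fragment_sets, function(fs) fs$total_mapped, numeric(1))
  len <- consensus$end - consensus$start
  fpkm <- fpkm_from_counts(counts, len, total)
  md <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  structure(list(fpkm = fpkm, counts = counts, metadata = md,
                 peaks = consensus, peak_length = len),
            class = "signal_matrix")
}

#' Per-batch standardization of a signal matrix
#'
#' Plumbing knob for simulated batch effects (disabled by default in
#' the pipeline): per peak and per batch, values are centered and
#' scaled to unit sd (sd 0 leaves the batch centered), then the peak's
#' global mean and sd are restored so the output stays on the FPKM
#' scale. Singleton batches are passed through with a warning.
#'
#' @param mat FPKM matrix (peaks x samples).
#' @param batch per-column batch labels.
#' @return adjusted matrix of the same shape.
#' @export
batch_standardize <- function(mat, batch) {
  stopifnot(ncol(mat) == length(batch))
  g_mean <- rowMeans(mat)
  g_sd <- apply(mat, 1, stats::sd)
  out <- mat
  for (b in unique(batch)) {
    cols <- which(batch == b)
    if (length(cols) < 2L) {
      warning(sprintf("batch '%s' has a single sample; passed through", b))
      next
    }
    sub <- mat[, cols, drop = FALSE]
    b_mean <- rowMeans(sub)
    b_sd <- apply(sub, 1, stats::sd)
    z <- (sub - b_mean) / ifelse(b_sd > 0, b_sd, 1)
    out[, cols] <- z * g_sd + g_mean
  }
  out
}
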