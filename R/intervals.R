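#' @importFrom IRanges IRanges findOverlaps
#' @importFrom GenomicRanges GRanges countOverlaps intersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All coordinates in this package are 0-based half-open [start, end),
# matching BED/narrowPeak on disk. Conversion to the 1-based closed
# convention of IRanges/GRanges happens only inside these two helpers.

#' Convert a 0-based half-open interval data frame to GRanges
#'
#' @param df data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return a [GenomicRanges::GRanges] with identical overlap semantics
#'   (an overlap of >= 1 bp in half-open coordinates is an overlap of
#'   >= 1 bp between the converted ranges).
#' @keywords internal
as_granges0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Validate an interval data frame
#'
#' Checks the core invariants: 0 <= start < end, and (when a chromosome
#' size table is supplied) chrom present and end within the chromosome.
#' @param df interval data frame.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @param what label used in error messages.
#' @return `df`, invisibly.
#' @keywords internal
validate_intervals <- function(df, chrom_sizes = NULL, what = "interval") {
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s record %d invalid: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop(sprintf("%s uses chromosome(s) absent from size table: %s",
                   what, paste(unknown, collapse = ", ")))
    }
    over <- which(df$end > chrom_sizes[df$chrom])
    if (length(over)) {
      stop(sprintf("%s record %d extends beyond end of %s",
                   what, over[1], df$chrom[over[1]]))
    }
  }
  invisible(df)
}

#' Which query intervals overlap any subject interval by >= 1 bp
#' @param query,subject interval data frames (0-based half-open).
#' @return logical vector along rows of `query`.
#' @keywords internal
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L) return(rep(FALSE, nrow(query)))
  count_overlaps0(query, subject) > 0L
}

#' Count subject intervals overlapping each query interval by >= 1 bp
#'
#' Disjoint chromosome sets are a legitimate zero-overlap case, so the
#' "no sequence levels in common" notice is muffled.
#' @keywords internal
count_overlaps0 <- function(query, subject) {
  if (nrow(query) == 0L) return(integer(0))
  if (nrow(subject) == 0L) return(integer(nrow(query)))
  withCallingHandlers(
    GenomicRanges::countOverlaps(as_granges0(query), as_granges0(subject)),
    warning = function(w) {
      if (grepl("no sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Total overlapped base pairs between a set of intervals and a class
#'
#' @param peaks,class_iv interval data frames (0-based half-open).
#' @return total number of peak base pairs falling inside `class_iv`.
#' @keywords internal
overlap_bp <- function(peaks, class_iv) {
  if (nrow(peaks) == 0L || nrow(class_iv) == 0L) return(0)
  gi <- withCallingHandlers(
    GenomicRanges::intersect(as_granges0(peaks),
                             GenomicRanges::reduce(as_granges0(class_iv))),
    warning = function(w) {
      if (grepl("no sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  sum(as.numeric(GenomicRanges::width(gi)))
}

#' Sort an interval data frame by (chrom, start, end)
#' @keywords internal
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
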