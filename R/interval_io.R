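#' Read a two-column chromosome size table
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}

#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column narrowPeak format. The summit (column 10) is an
#' offset from `start`; it is stored as an absolute position. A summit
#' offset of -1 (caller did not report one) falls back to the interval
#' midpoint. Records on chromosomes absent from `chrom_sizes` are
#' rejected (dropped with a warning).
#'
#' @param path narrowPeak file.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @param sample_id sample identifier attached to every peak.
#' @return data frame of peaks: `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score` (upstream caller score, column 5),
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit` (absolute bp),
#'   `sample_id`. `spm` (score per million) is NA until
#'   [spm_normalize()] is applied.
#' @export
read_narrowpeak <- function(path, chrom_sizes = NULL, sample_id = NA_character_) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit_offset")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_peaks(sample_id))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    stop(sprintf("malformed narrowPeak line %d in %s: expected 10 fields, got %d",
                 which(nf != 10L)[1], path, nf[nf != 10L][1]))
  }
  m <- do.call(rbind, fields)
  df <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
                   end = as.numeric(m[, 3]), name = m[, 4],
                   score = as.numeric(m[, 5]), strand = m[, 6],
                   signal = as.numeric(m[, 7]), pvalue = as.numeric(m[, 8]),
                   qvalue = as.numeric(m[, 9]),
                   summit_offset = as.numeric(m[, 10]),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$score) |
                 is.na(df$summit_offset))
  if (length(bad)) stop(sprintf("malformed narrowPeak line %d in %s: non-numeric field",
                                bad[1], path))
  validate_intervals(df, what = sprintf("narrowPeak %s", path))
  if (any(df$score < 0)) stop("narrowPeak score must be nonnegative")
  df$summit <- ifelse(df$summit_offset >= 0,
                      df$start + df$summit_offset,
                      floor((df$start + df$end) / 2))
  out_of_peak <- which(df$summit < df$start | df$summit >= df$end)
  if (length(out_of_peak)) {
    stop(sprintf("narrowPeak record %d: summit %d outside interval [%d,%d)",
                 out_of_peak[1], df$summit[out_of_peak[1]],
                 df$start[out_of_peak[1]], df$end[out_of_peak[1]]))
  }
  if (!is.null(chrom_sizes)) {
    keep <- df$chrom %in% names(chrom_sizes)
    if (!all(keep)) {
      warning(sprintf("%d narrowPeak record(s) on chromosomes absent from size table rejected",
                      sum(!keep)))
      df <- df[keep, , drop = FALSE]
    }
  }
  df$summit_offset <- NULL
  df$spm <- NA_real_
  df$sample_id <- sample_id
  rownames(df) <- NULL
  df
}

empty_peaks <- function(sample_id = NA_character_) {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             signal = numeric(0), pvalue = numeric(0), qvalue = numeric(0),
             summit = numeric(0), spm = numeric(0),
             sample_id = character(0), stringsAsFactors = FALSE)
}

#' Write peaks as ENCODE narrowPeak
#'
#' Inverse of [read_narrowpeak()]: coordinates, scores and summit
#' offsets round-trip exactly.
#' @param peaks peak data frame (see [read_narrowpeak()]).
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(peaks$chrom, format_coord(peaks$start), format_coord(peaks$end),
                    peaks$name, peaks$score,
                    ifelse(is.na(peaks$strand), ".", peaks$strand),
                    peaks$signal, peaks$pvalue, peaks$qvalue,
                    format_coord(peaks$summit - peaks$start))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BED3+ fragment file into a fragment set
#'
#' @param path BED file of aligned fragment intervals (0-based half-open).
#' @param sample_id sample identifier.
#' @param total_mapped optional library-size override. When supplied it
#'   is used as the FPKM denominator regardless of how many records the
#'   file holds (so fragment files can be down-sampled without changing
#'   normalization); default is the record count.
#' @return a `fragment_set`: list with `sample_id`, `fragments`
#'   (data frame chrom/start/end) and `total_mapped`.
#' @export
read_fragments <- function(path, sample_id = NA_character_, total_mapped = NULL) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (nrow(df) == 0L) {
    frg <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  } else {
    frg <- data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
                      end = as.numeric(df[[3]]))
    validate_intervals(frg, what = sprintf("fragment BED %s", path))
  }
  fragment_set(frg, sample_id = sample_id, total_mapped = total_mapped)
}

#' Construct a fragment set
#' @param fragments data frame with chrom/start/end.
#' @param sample_id sample identifier.
#' @param total_mapped library size; defaults to `nrow(fragments)`.
#' @export
fragment_set <- function(fragments, sample_id = NA_character_, total_mapped = NULL) {
  if (is.null(total_mapped)) total_mapped <- nrow(fragments)
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  structure(list(sample_id = sample_id, fragments = fragments,
                 total_mapped = total_mapped),
            class = "fragment_set")
}

#' Write a fragment set as BED3
#' @param fs fragment set.
#' @param path output file.
#' @export
write_fragments <- function(fs, path) {
  data.table::fwrite(fs$fragments, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a spike-in read-count table
#'
#' @param path TSV with header `sample_id`, `unmod`, `mc`, `hmc`.
#' @return data frame of per-sample spike-in species counts.
#' @export
read_spikein <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Spike-in capture efficiency
#'
#' Fraction of spike-in reads aligned to one modification species out of
#' all spike-in reads, the QC measure of enrichment specificity.
#'
#' @param counts named vector or one-row data frame with species counts
#'   `unmod`, `mc`, `hmc`.
#' @param species one of `"unmod"`, `"mc"`, `"hmc"`.
#' @return fraction in \[0, 1\].
#' @export
capture_efficiency <- function(counts, species = c("mc", "hmc", "unmod")) {
  species <- match.arg(species)
  counts <- unlist(counts[c("unmod", "mc", "hmc")])
  if (any(counts < 0)) stop("spike-in counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stop("capture efficiency undefined: zero total spike-in count")
  unname(counts[species] / total)
}

#' Read a sample metadata table
#'
#' @param path TSV with header; requires columns `sample_id`, `group`
#'   (case/control), `channel`; optional `batch`, `stage`, `jaundice`,
#'   `resectable`.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "channel")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(md$group %in% c("case", "control"))) {
    stop("metadata group must be 'case' or 'control'")
  }
  md
}

#' Read a BED3/BED6 interval file
#' @param path BED file.
#' @return data frame chrom/start/end (plus name/score/strand when present).
#' @export
read_bed <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 6) names(df)[4:6] <- c("name", "score", "strand")
  df$chrom <- as.character(df$chrom)
  validate_intervals(df, what = sprintf("BED %s", path))
  df
}
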