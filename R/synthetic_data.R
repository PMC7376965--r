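#' Specify a synthetic cfDNA enrichment cohort
#'
#' Defines the generative model for a two-group (case/control) cohort of
#' enrichment-sequencing samples: a fixed template of non-overlapping
#' enriched regions, negative-binomial fragment counts per region with
#' per-sample library-size factors and optional batch factors, a subset
#' of regions carrying a true case/control log2 fold change, uniform
#' background fragments, and spike-in species counts. Defaults emulate a
#' mono-nucleosomal cfDNA library (fragment length ~167 bp) over a small
#' two-chromosome genome, with the reference study-condition values
#' used throughout the package's validation: 40 cases vs 40 controls,
#' 2,000 regions, 30 differential regions at |log2FC| = 1.5, mean
#' in-region count 50 with negative-binomial size 10.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param chroms named vector of chromosome lengths.
#' @param n_case,n_control group sizes.
#' @param n_regions number of template regions.
#' @param n_diff number of truly differential regions.
#' @param lfc magnitude(s) of the true log2 fold change; recycled to
#'   `n_diff`. Sign is set by `frac_hyper`.
#' @param frac_hyper fraction of differential regions elevated in cases.
#' @param mean_count mean fragment count per region in controls (before
#'   library-size scaling).
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param libsize_sdlog log-sd of the lognormal per-sample library-size
#'   factor (mean factor 1).
#' @param noise_rate expected background fragments per bp of genome at
#'   library factor 1.
#' @param batch_factors optional named vector of per-batch multiplicative
#'   factors; samples are assigned to batches round-robin, balanced
#'   across groups. NULL = single batch, factor 1.
#' @param channel_overlap fraction of regions shared between the 5mC and
#'   5hmC templates in [generate_paired_channels()].
#' @param region_width width of each template region in bp.
#' @param fraglen_mean,fraglen_sd fragment length distribution
#'   (truncated to \[50, 500\] bp).
#' @param spike_specificity fraction of spike-in reads on the
#'   channel-matched species.
#' @param channel modification channel label.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(seed = 1L,
                        chroms = c(chrS1 = 5e6, chrS2 = 5e6),
                        n_case = 40L, n_control = 40L,
                        n_regions = 2000L, n_diff = 30L,
                        lfc = 1.5, frac_hyper = 0.5,
                        mean_count = 50, dispersion = 10,
                        libsize_sdlog = 0.15,
                        noise_rate = 2e-3,
                        batch_factors = NULL,
                        channel_overlap = 0.3,
                        region_width = 300L,
                        fraglen_mean = 167, fraglen_sd = 30,
                        spike_specificity = 0.85,
                        channel = "5mC") {
  spec <- list(seed = as.integer(seed), chroms = chroms,
               n_case = as.integer(n_case), n_control = as.integer(n_control),
               n_regions = as.integer(n_regions), n_diff = as.integer(n_diff),
               lfc = lfc, frac_hyper = frac_hyper,
               mean_count = mean_count, dispersion = dispersion,
               libsize_sdlog = libsize_sdlog, noise_rate = noise_rate,
               batch_factors = batch_factors,
               channel_overlap = channel_overlap,
               region_width = as.integer(region_width),
               fraglen_mean = fraglen_mean, fraglen_sd = fraglen_sd,
               spike_specificity = spike_specificity,
               channel = channel)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_diff <= spec$n_regions,
            all(is.finite(spec$lfc)),
            spec$mean_count > 0, spec$dispersion > 0,
            spec$noise_rate >= 0,
            spec$channel_overlap >= 0, spec$channel_overlap <= 1,
            spec$frac_hyper >= 0, spec$frac_hyper <= 1,
            spec$n_case >= 1, spec$n_control >= 1)
  # regions must fit with >= 500 bp separation
  need <- spec$n_regions * (spec$region_width + 500)
  if (need > sum(spec$chroms)) {
    stop("chromosomes too short to place regions >= 500 bp apart")
  }
  invisible(spec)
}

# Place n non-overlapping regions >= 500 bp apart, uniformly over slots.
place_regions <- function(chroms, n, width) {
  pitch <- width + 500L
  slots_per_chrom <- floor((chroms - 500) / pitch)
  total_slots <- sum(slots_per_chrom)
  stopifnot(total_slots >= n)
  take <- sort(sample.int(total_slots, n))
  chrom_idx <- findInterval(take - 1L, cumsum(c(0, slots_per_chrom)),
                            rightmost.closed = FALSE)
  offset_in_chrom <- take - c(0, cumsum(slots_per_chrom))[chrom_idx] - 1L
  start <- 250L + offset_in_chrom * pitch
  data.frame(region_id = sprintf("r%04d", seq_len(n)),
             chrom = names(chroms)[chrom_idx],
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# Assign differential flags / signed lfc to a region template.
assign_truth <- function(regions, n_diff, lfc, frac_hyper) {
  n <- nrow(regions)
  diff_idx <- if (n_diff > 0) sort(sample.int(n, n_diff)) else integer(0)
  regions$differential <- FALSE
  regions$differential[diff_idx] <- TRUE
  regions$lfc <- 0
  if (n_diff > 0) {
    mags <- rep_len(abs(lfc), n_diff)
    n_hyper <- round(frac_hyper * n_diff)
    signs <- sample(c(rep(1, n_hyper), rep(-1, n_diff - n_hyper)))
    regions$lfc[diff_idx] <- mags * signs
  }
  regions$direction <- ifelse(!regions$differential, NA_character_,
                              ifelse(regions$lfc > 0, "hyper_case", "hypo_case"))
  regions
}

# Sample metadata frame for a spec (group order: cases then controls).
cohort_metadata <- function(spec) {
  n <- spec$n_case + spec$n_control
  md <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    group = c(rep("case", spec$n_case), rep("control", spec$n_control)),
    channel = spec$channel,
    stringsAsFactors = FALSE)
  if (is.null(spec$batch_factors)) {
    md$batch <- "b1"
  } else {
    nb <- length(spec$batch_factors)
    # round-robin within group keeps batches balanced across groups
    md$batch <- names(spec$batch_factors)[
      c(rep_len(seq_len(nb), spec$n_case), rep_len(seq_len(nb), spec$n_control))]
  }
  md
}

#' Simulate the per-region count model of a cohort
#'
#' The statistical core shared by [generate_cohort()]: draws the
#' region-by-sample negative-binomial fragment counts (with library-size
#' factors, batch factors and true fold changes applied) without
#' scattering fragments. Useful for calibration studies where only the
#' count/FPKM matrix matters.
#'
#' @param spec a [cohort_spec()].
#' @return list with `counts` (regions x samples), `regions` (template
#'   with truth columns), `metadata`, `lib_factor`, `total_mapped`
#'   (in-region counts plus expected background) and `fpkm` (regions x
#'   samples FPKM matrix).
#' @export
simulate_signal_matrix <- function(spec) {
  withr::with_seed(spec$seed, simulate_signal_matrix_impl(spec))
}

simulate_signal_matrix_impl <- function(spec, template = NULL) {
  regions <- if (is.null(template)) {
    place_regions(spec$chroms, spec$n_regions, spec$region_width)
  } else {
    template[, c("region_id", "chrom", "start", "end",
                 intersect("shared", names(template)))]
  }
  regions <- assign_truth(regions, spec$n_diff, spec$lfc, spec$frac_hyper)
  md <- cohort_metadata(spec)
  n <- nrow(md)
  lib <- stats::rlnorm(n, meanlog = -spec$libsize_sdlog^2 / 2,
                       sdlog = spec$libsize_sdlog)
  batch_f <- if (is.null(spec$batch_factors)) rep(1, n) else
    unname(spec$batch_factors[md$batch])
  # per-region baseline means vary around mean_count
  base_mu <- spec$mean_count * stats::rlnorm(spec$n_regions, -0.08, 0.4)
  fc <- outer(regions$lfc, as.numeric(md$group == "case"),
              function(l, g) 2^(l * g))
  mu <- (base_mu * fc) * rep(lib * batch_f, each = spec$n_regions)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = spec$dispersion),
                   nrow = spec$n_regions,
                   dimnames = list(regions$region_id, md$sample_id))
  # The batch factor models enrichment-efficiency bias: it scales
  # in-region signal but not sequencing depth, so it survives FPKM
  # normalization (and is what batch_standardize is meant to remove).
  expected_bg <- spec$noise_rate * sum(spec$chroms) * lib
  total_mapped <- round(colSums(counts) / batch_f) + round(expected_bg)
  fpkm <- fpkm_from_counts(counts, rep(spec$region_width, spec$n_regions),
                           total_mapped)
  list(counts = counts, regions = regions, metadata = md,
       lib_factor = lib, batch_factor = batch_f, base_mu = base_mu,
       total_mapped = total_mapped, fpkm = fpkm)
}

#' Generate a synthetic cfDNA cohort
#'
#' Draws the count model of [simulate_signal_matrix()] and scatters
#' fragments: per region, `count` fragments with centers jittered
#' around the region center and lengths ~ Normal(`fraglen_mean`,
#' `fraglen_sd`) truncated to \[50, 500\] bp; plus uniform background
#' fragments at `noise_rate` per bp. Per sample it also emits a
#' narrowPeak call for every region whose count exceeds a Poisson
#' background threshold (score = round(-10 log10 p)), a spike-in count
#' row, and the shared metadata and ground-truth tables. Fully
#' reproducible from `spec$seed`; with `outdir` set, two runs produce
#' byte-identical files.
#'
#' @param spec a [cohort_spec()].
#' @param outdir optional directory; when given, writes
#'   `fragments/<sample>.bed`, `peaks/<sample>.narrowPeak`,
#'   `metadata.tsv`, `spikein.tsv`, `truth.tsv`, `chrom.sizes`.
#' @param peak_p Poisson p-value threshold for emitting a sample peak.
#' @return list with `truth` (region table), `metadata`, `chrom_sizes`,
#'   `fragments` (named list of fragment sets), `peaks` (named list of
#'   narrowPeak data frames), `spikein`, `counts`, `total_mapped`.
#' @export
generate_cohort <- function(spec, outdir = NULL, peak_p = 1e-4) {
  sim <- withr::with_seed(spec$seed, generate_cohort_impl(spec, peak_p))
  if (!is.null(outdir)) write_cohort(sim, outdir)
  sim
}

generate_cohort_impl <- function(spec, peak_p, template = NULL) {
  core <- simulate_signal_matrix_impl(spec, template = template)
  md <- core$metadata
  regions <- core$regions
  n <- nrow(md)
  genome_len <- sum(spec$chroms)
  chrom_cum <- cumsum(c(0, spec$chroms))
  centers <- (regions$start + regions$end) / 2

  fragments <- vector("list", n)
  peaks <- vector("list", n)
  for (j in seq_len(n)) {
    k <- core$counts[, j]
    ridx <- rep.int(seq_len(nrow(regions)), k)
    ctr <- stats::rnorm(length(ridx), centers[ridx], spec$region_width / 6)
    ctr <- pmin(pmax(ctr, regions$start[ridx] + 1), regions$end[ridx] - 1)
    len <- pmin(pmax(stats::rnorm(length(ridx), spec$fraglen_mean,
                                  spec$fraglen_sd), 50), 500)
    fstart <- round(ctr - len / 2)
    fend <- fstart + round(len)
    fchrom <- regions$chrom[ridx]
    # background fragments uniform over the genome
    n_bg <- stats::rpois(1, spec$noise_rate * genome_len * core$lib_factor[j])
    bpos <- stats::runif(n_bg, 0, genome_len)
    bci <- findInterval(bpos, chrom_cum, rightmost.closed = TRUE)
    blen <- pmin(pmax(stats::rnorm(n_bg, spec$fraglen_mean, spec$fraglen_sd),
                      50), 500)
    bstart <- round(bpos - chrom_cum[bci])
    frg <- data.frame(
      chrom = c(fchrom, names(spec$chroms)[bci]),
      start = c(fstart, bstart),
      end = c(fend, bstart + round(blen)))
    frg$start <- pmax(frg$start, 0)
    frg$end <- pmin(frg$end, unname(spec$chroms[frg$chrom]))
    frg <- frg[frg$end > frg$start, , drop = FALSE]
    frg <- sort_intervals(frg)
    rownames(frg) <- NULL
    fragments[[j]] <- fragment_set(frg, sample_id = md$sample_id[j])

    # sample-level peak calls: Poisson test of region count vs background
    lambda_bg <- spec$noise_rate * core$lib_factor[j] * core$batch_factor[j] *
      spec$region_width
    pval <- stats::ppois(k - 1, lambda_bg, lower.tail = FALSE)
    called <- which(pval < peak_p & k > 0)
    jit <- round(stats::runif(length(called), -20, 20))
    pk <- data.frame(
      chrom = regions$chrom[called],
      start = regions$start[called], end = regions$end[called],
      name = sprintf("%s_pk%04d", md$sample_id[j], seq_along(called)),
      score = round(-10 * log10(pmax(pval[called], 1e-300))),
      strand = ".",
      signal = k[called],
      pvalue = round(-log10(pmax(pval[called], 1e-300)), 4),
      qvalue = -1,
      summit = pmin(pmax(round(centers[called]) + jit,
                         regions$start[called]),
                    regions$end[called] - 1),
      spm = NA_real_,
      sample_id = md$sample_id[j],
      stringsAsFactors = FALSE)
    peaks[[j]] <- sort_intervals(pk)
    rownames(peaks[[j]]) <- NULL
  }
  names(fragments) <- names(peaks) <- md$sample_id

  spike_total <- round(5e4 * core$lib_factor)
  on_target <- stats::rbinom(n, spike_total, spec$spike_specificity)
  off <- spike_total - on_target
  off_a <- stats::rbinom(n, off, 0.5)
  target_col <- if (spec$channel == "5hmC") "hmc" else "mc"
  spike <- data.frame(sample_id = md$sample_id, unmod = off_a,
                      mc = 0L, hmc = 0L, stringsAsFactors = FALSE)
  other_col <- setdiff(c("mc", "hmc"), target_col)
  spike[[target_col]] <- on_target
  spike[[other_col]] <- off - off_a

  list(truth = regions, metadata = md, chrom_sizes = spec$chroms,
       fragments = fragments, peaks = peaks, spikein = spike,
       counts = core$counts, total_mapped = core$total_mapped,
       fpkm = core$fpkm, spec = spec)
}

write_cohort <- function(sim, outdir) {
  dir.create(file.path(outdir, "fragments"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  for (sid in sim$metadata$sample_id) {
    write_fragments(sim$fragments[[sid]],
                    file.path(outdir, "fragments", paste0(sid, ".bed")))
    write_narrowpeak(sim$peaks[[sid]],
                     file.path(outdir, "peaks", paste0(sid, ".narrowPeak")))
  }
  utils::write.table(sim$metadata, file.path(outdir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$spikein, file.path(outdir, "spikein.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(names(sim$chrom_sizes), format_coord(sim$chrom_sizes)),
    file.path(outdir, "chrom.sizes"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(outdir)
}

#' Generate paired 5mC / 5hmC cohorts with partially shared templates
#'
#' Builds two region templates sharing exactly
#' `round(channel_overlap * n_regions)` regions (identical coordinates
#' in both channels; the remainder disjoint), then simulates one cohort
#' per channel over the same samples. Differential regions are drawn
#' independently per channel, so signal can be complementary across
#' channels.
#'
#' @param spec a [cohort_spec()]; `spec$channel_overlap` controls
#'   sharing.
#' @param outdir optional; writes each channel under
#'   `<outdir>/5mC`, `<outdir>/5hmC`.
#' @param n_diff_mc,n_diff_hmc optional per-channel differential region
#'   counts (default `spec$n_diff` each).
#' @return list with elements `5mC` and `5hmC`, each as returned by
#'   [generate_cohort()].
#' @export
generate_paired_channels <- function(spec, outdir = NULL,
                                     n_diff_mc = spec$n_diff,
                                     n_diff_hmc = spec$n_diff) {
  res <- withr::with_seed(spec$seed, {
    n_shared <- round(spec$channel_overlap * spec$n_regions)
    pool <- place_regions(spec$chroms, 2L * spec$n_regions - n_shared,
                          spec$region_width)
    idx <- sample.int(nrow(pool))
    n_own <- spec$n_regions - n_shared
    shared <- idx[seq_len(n_shared)]
    own_a <- idx[n_shared + seq_len(n_own)]
    own_b <- idx[n_shared + n_own + seq_len(n_own)]
    tmpl_mc <- sort_intervals(pool[sort(c(shared, own_a)), ])
    tmpl_hmc <- sort_intervals(pool[sort(c(shared, own_b)), ])
    tmpl_mc$region_id <- sprintf("r%04d", seq_len(nrow(tmpl_mc)))
    tmpl_hmc$region_id <- sprintf("r%04d", seq_len(nrow(tmpl_hmc)))
    tmpl_mc$shared <- paste(tmpl_mc$chrom, tmpl_mc$start) %in%
      paste(pool$chrom[shared], pool$start[shared])
    tmpl_hmc$shared <- paste(tmpl_hmc$chrom, tmpl_hmc$start) %in%
      paste(pool$chrom[shared], pool$start[shared])
    list(tmpl_mc = tmpl_mc, tmpl_hmc = tmpl_hmc,
         seed_mc = sample.int(2^31 - 1, 1), seed_hmc = sample.int(2^31 - 1, 1))
  })
  spec_mc <- spec; spec_mc$seed <- res$seed_mc; spec_mc$channel <- "5mC"
  spec_mc$n_diff <- as.integer(n_diff_mc)
  spec_hmc <- spec; spec_hmc$seed <- res$seed_hmc; spec_hmc$channel <- "5hmC"
  spec_hmc$n_diff <- as.integer(n_diff_hmc)
  co_mc <- generate_cohort_with_template(spec_mc, res$tmpl_mc,
                                         if (is.null(outdir)) NULL else file.path(outdir, "5mC"))
  co_hmc <- generate_cohort_with_template(spec_hmc, res$tmpl_hmc,
                                          if (is.null(outdir)) NULL else file.path(outdir, "5hmC"))
  list("5mC" = co_mc, "5hmC" = co_hmc)
}

# generate_cohort but on a fixed region template (used for paired channels)
generate_cohort_with_template <- function(spec, template, outdir = NULL,
                                          peak_p = 1e-4) {
  sim <- withr::with_seed(spec$seed,
                          generate_cohort_impl(spec, peak_p, template = template))
  if (!is.null(outdir)) write_cohort(sim, outdir)
  sim
}
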