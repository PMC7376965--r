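#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults equal to the
#' method's canonical values: 100 bp summit extension (201 bp peaks),
#' score-per-million floor 5, reproducibility grid N = 10..90 step 10,
#' |log2FC| threshold 0.8, selection frequency 0.95, 3 rounds
#' retention, 100 elastic-net repeats, alpha grid 0.1..0.9.
#'
#' @param seed master seed; every stage derives its own stream via
#'   [stage_seed()].
#' @param half_width,spm_min,N_grid,N_fixed,occupancy_fdr consensus
#'   parameters; `N_fixed` (when non-NULL) skips the grid search.
#' @param diff_p,diff_use_fdr,diff_lfc,log2_transform differential
#'   parameters.
#' @param frac_case,frac_control split fractions.
#' @param R,K,B,alpha,freq_min,rounds_min,retention stability-selection
#'   parameters.
#' @param prob_threshold classification cut-off.
#' @param excluded_chroms chromosomes excluded from the consensus.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            half_width = 100L, spm_min = 5,
                            N_grid = seq(10, 90, by = 10), N_fixed = NULL,
                            occupancy_fdr = 0.05,
                            diff_p = 0.01, diff_use_fdr = TRUE, diff_lfc = 0.8,
                            log2_transform = FALSE,
                            frac_case = 0.75, frac_control = 0.75,
                            R = 5L, K = 5L, B = 100L, alpha = 0.2,
                            freq_min = 0.95, rounds_min = 3L,
                            retention = "rounds",
                            prob_threshold = 0.5,
                            excluded_chroms = c("chrX", "chrY", "chrM")) {
  cfg <- as.list(environment())
  if (length(cfg$N_grid) == 0L || any(cfg$N_grid <= 0 | cfg$N_grid > 100)) {
    stop("invalid N grid")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Consensus construction (with N chosen on the occupancy grid unless
#' `N_fixed` is set) -> FPKM quantification -> differential calling ->
#' stratified split -> stability selection -> final elastic-net fit ->
#' evaluation on training and validation sets. Operates on an
#' in-memory cohort (as from [generate_cohort()]) or on a directory of
#' files written by it.
#'
#' @param cohort list with `peaks`, `fragments`, `metadata`,
#'   `chrom_sizes` (see [generate_cohort()]), or a directory path.
#' @param config a [pipeline_config()].
#' @param blacklist optional blacklist interval data frame.
#' @param outdir optional directory for result tables and the manifest.
#' @return list with `consensus`, `chosen_N`, `N_summary`, `signal`,
#'   `differential`, `split`, `panel`, `model`, `train_eval`,
#'   `val_eval`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         blacklist = NULL, outdir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  md <- cohort$metadata
  groups <- stats::setNames(md$group, md$sample_id)

  prepped <- prepare_sample_peaks(cohort$peaks, cohort$chrom_sizes,
                                  config$half_width)
  if (is.null(config$N_fixed)) {
    occ_by_N <- lapply(stats::setNames(config$N_grid, config$N_grid),
                       function(N) consensus_for_N(
                         prepped, groups, N, config$spm_min, blacklist,
                         config$excluded_chroms, cohort$chrom_sizes)$occupancy)
    sel <- select_N(occ_by_N, groups[names(prepped)], config$occupancy_fdr)
    chosen_N <- sel$chosen_N
    N_summary <- sel$summary
  } else {
    chosen_N <- config$N_fixed
    N_summary <- NULL
  }
  built <- consensus_for_N(prepped, groups, chosen_N, config$spm_min,
                           blacklist, config$excluded_chroms,
                           cohort$chrom_sizes)
  if (nrow(built$consensus) == 0L) stop("stage consensus failed: empty peak set")

  sig <- signal_matrix(built$consensus, cohort$fragments, md)
  dt <- call_differential(sig, p_threshold = config$diff_p,
                          use_fdr = config$diff_use_fdr,
                          lfc_threshold = config$diff_lfc,
                          log2_transform = config$log2_transform)

  split <- make_split(md, config$frac_case, config$frac_control,
                      seed = stage_seed(config$seed, "split"))
  tr <- split$train; va <- split$validation
  panel <- stability_select(sig$fpkm[, tr, drop = FALSE], groups[tr],
                            R = config$R, K = config$K, B = config$B,
                            alpha = config$alpha,
                            candidate_p = config$diff_p,
                            use_fdr = config$diff_use_fdr,
                            candidate_lfc = config$diff_lfc,
                            freq_min = config$freq_min,
                            rounds_min = config$rounds_min,
                            retention = config$retention,
                            seed = stage_seed(config$seed, "stability"))
  if (length(panel$markers) == 0L) stop("stage stability_select failed: empty panel")
  model <- fit_final(sig$fpkm[, tr, drop = FALSE], groups[tr], panel$markers,
                     alpha = config$alpha,
                     seed = stage_seed(config$seed, "fit"))
  res <- list(consensus = built$consensus, chosen_N = chosen_N,
              N_summary = N_summary, signal = sig, differential = dt,
              split = split, panel = panel, model = model,
              train_eval = evaluate(model, sig$fpkm[, tr, drop = FALSE],
                                    groups[tr], config$prob_threshold),
              val_eval = evaluate(model, sig$fpkm[, va, drop = FALSE],
                                  groups[va], config$prob_threshold),
              config = config)
  if (!is.null(outdir)) write_pipeline_results(res, outdir)
  res
}

read_cohort_dir <- function(dir) {
  chrom_sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  peaks <- lapply(stats::setNames(md$sample_id, md$sample_id), function(sid)
    read_narrowpeak(file.path(dir, "peaks", paste0(sid, ".narrowPeak")),
                    chrom_sizes, sample_id = sid))
  fragments <- lapply(stats::setNames(md$sample_id, md$sample_id), function(sid)
    read_fragments(file.path(dir, "fragments", paste0(sid, ".bed")),
                   sample_id = sid))
  list(peaks = peaks, fragments = fragments, metadata = md,
       chrom_sizes = chrom_sizes)
}

write_pipeline_results <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(as.data.frame(res$consensus), "consensus_peaks.tsv")
  tsv(data.frame(peak_id = rownames(res$signal$fpkm),
                 round(res$signal$fpkm, 6), check.names = FALSE),
      "fpkm_matrix.tsv")
  tsv(res$differential, "differential.tsv")
  if (!is.null(res$N_summary)) tsv(res$N_summary, "N_selection.tsv")
  tsv(res$val_eval$scores, "validation_scores.tsv")
  model_json <- list(markers = res$model$markers,
                     coef = as.list(res$model$coef),
                     intercept = res$model$intercept,
                     alpha = res$model$alpha, lambda = res$model$lambda)
  jsonlite::write_json(model_json, file.path(outdir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = res$config$seed, chosen_N = res$chosen_N,
                   params = res$config[setdiff(names(res$config), "N_grid")],
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  manifest$params$N_grid <- res$config$N_grid
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
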