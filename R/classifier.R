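#' Derive a stage-specific seed from a master seed
#'
#' Stable polynomial hash of the stage name mixed with the master seed,
#' kept below 2^31. Adding a stage never shifts another stage's
#' randomness.
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483563
  as.integer((as.numeric(master) %% 2147483563 * 48271 + h) %% 2147483563 + 1)
}

#' Stratified train/validation split
#'
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param frac_case,frac_control training fractions per group; the
#'   training count is `floor(frac * n)`.
#' @param seed split seed.
#' @return a `split_plan`: list with `train`, `validation` (sample id
#'   vectors), fractions and seed.
#' @export
make_split <- function(metadata, frac_case = 0.75, frac_control = 0.75,
                       seed = 1L) {
  stopifnot(frac_case > 0, frac_case < 1, frac_control > 0, frac_control < 1)
  withr::with_seed(seed, {
    pick <- function(ids, frac) {
      n_train <- floor(frac * length(ids))
      if (n_train < 1L || n_train >= length(ids)) {
        stop("group too small to split at this fraction")
      }
      sample(ids, n_train)
    }
    tr_case <- pick(metadata$sample_id[metadata$group == "case"], frac_case)
    tr_ctrl <- pick(metadata$sample_id[metadata$group == "control"], frac_control)
    train <- c(tr_case, tr_ctrl)
    structure(list(train = train,
                   validation = setdiff(metadata$sample_id, train),
                   frac_case = frac_case, frac_control = frac_control,
                   seed = seed),
              class = "split_plan")
  })
}

# Stratified fold ids (1..K) over a label vector; every fold gets both
# classes when feasible.
stratified_folds <- function(is_case, K) {
  fold <- integer(length(is_case))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_case == cls)
    fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  fold
}

#' Stability selection of marker peaks by repeated elastic-net fits
#'
#' R rounds of K-fold cross-validation over the training set. In each
#' round the training samples are split into K stratified folds; each
#' of the K training subsets (all samples except one fold) is processed
#' independently: (1) a differential filter (`candidate_p` / `use_fdr`
#' / `candidate_lfc`, via [call_differential()]) applied to the subset
#' only defines the candidate peaks; (2) B elastic-net logistic fits at
#' fixed `alpha` are run, each with re-randomized internal
#' cross-validation folds for the penalty `lambda`; (3) the subset
#' panel keeps candidates with a nonzero coefficient in at least
#' `freq_min` of the B fits. A marker is present in a round if it
#' enters any subset panel of that round; the final panel keeps markers
#' present in at least `rounds_min` rounds (or, with
#' `retention = "subsets"`, in at least `rounds_min` of the R*K subset
#' panels). All randomness derives from `seed`.
#'
#' @param mat FPKM matrix (peaks x samples), training samples only.
#' @param groups "case"/"control" along columns.
#' @param R rounds.
#' @param K folds per round.
#' @param B elastic-net repeats per training subset.
#' @param alpha elastic-net mixing parameter.
#' @param candidate_p,use_fdr,candidate_lfc differential filter
#'   parameters for the candidate rule.
#' @param freq_min minimum selection frequency within a subset.
#' @param rounds_min minimum rounds (or subsets) a marker must appear in.
#' @param retention count presence over `"rounds"` (default) or
#'   `"subsets"`.
#' @param nfolds_inner folds of the internal lambda cross-validation.
#' @param seed master seed.
#' @return a `marker_panel`: list with `markers`, `rounds_present`
#'   (named counts), `subsets_present`, `freq` (per subset x candidate
#'   selection frequencies, long data frame) and the parameters.
#' @export
stability_select <- function(mat, groups, R = 5L, K = 5L, B = 100L,
                             alpha = 0.2, candidate_p = 0.01, use_fdr = TRUE,
                             candidate_lfc = 0.8, freq_min = 0.95,
                             rounds_min = 3L,
                             retention = c("rounds", "subsets"),
                             nfolds_inner = 5L, seed = 1L) {
  retention <- match.arg(retention)
  is_case <- groups == "case"
  stopifnot(ncol(mat) == length(groups), sum(is_case) >= K, sum(!is_case) >= K)
  y <- factor(ifelse(is_case, "case", "control"), levels = c("control", "case"))
  round_panels <- vector("list", R)
  subset_panels <- list()
  freq_rows <- list()
  for (r in seq_len(R)) {
    fold <- withr::with_seed(stage_seed(seed, sprintf("round%02d", r)),
                             stratified_folds(is_case, K))
    panels_r <- vector("list", K)
    for (k in seq_len(K)) {
      sub <- which(fold != k)
      cand <- tryCatch({
        dt <- call_differential(mat[, sub, drop = FALSE], groups[sub],
                                p_threshold = candidate_p, use_fdr = use_fdr,
                                lfc_threshold = candidate_lfc)
        dt$peak_id[dt$passes]
      }, error = function(e) character(0))
      if (length(cand) < 1L) next
      nz <- withr::with_seed(
        stage_seed(seed, sprintf("round%02d_subset%02d", r, k)),
        selection_frequencies(mat[cand, sub, drop = FALSE], y[sub],
                              alpha, B, nfolds_inner))
      panel <- cand[nz >= freq_min]
      panels_r[[k]] <- panel
      subset_panels[[length(subset_panels) + 1L]] <- panel
      freq_rows[[length(freq_rows) + 1L]] <-
        data.frame(round = r, subset = k, peak_id = cand, freq = nz,
                   stringsAsFactors = FALSE)
    }
    round_panels[[r]] <- unique(unlist(panels_r))
  }
  all_markers <- unique(unlist(c(round_panels, subset_panels)))
  if (length(all_markers) == 0L) {
    warning("no candidates survived the filter in any subset; empty panel")
  }
  rounds_present <- vapply(all_markers, function(m)
    sum(vapply(round_panels, function(p) m %in% p, logical(1))), integer(1))
  subsets_present <- vapply(all_markers, function(m)
    sum(vapply(subset_panels, function(p) m %in% p, logical(1))), integer(1))
  presence <- if (retention == "rounds") rounds_present else subsets_present
  markers <- all_markers[presence >= rounds_min]
  structure(list(markers = markers,
                 rounds_present = rounds_present,
                 subsets_present = subsets_present,
                 freq = if (length(freq_rows)) do.call(rbind, freq_rows) else NULL,
                 params = list(R = R, K = K, B = B, alpha = alpha,
                               candidate_p = candidate_p, use_fdr = use_fdr,
                               candidate_lfc = candidate_lfc,
                               freq_min = freq_min, rounds_min = rounds_min,
                               retention = retention, seed = seed)),
            class = "marker_panel")
}

# Fraction of B cv.glmnet fits (re-randomized inner folds) in which each
# feature has a nonzero coefficient at lambda.min.
selection_frequencies <- function(sub_mat, y, alpha, B, nfolds_inner) {
  x <- pad_design(t(sub_mat))
  p <- nrow(sub_mat)
  nz_count <- numeric(p)
  for (b in seq_len(B)) {
    foldid <- stratified_folds(y == "case", nfolds_inner)
    cv <- quiet_cv_glmnet(x, y, family = "binomial", alpha = alpha,
                          foldid = foldid, standardize = TRUE)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[1 + seq_len(p)]
    nz_count <- nz_count + (beta != 0)
  }
  stats::setNames(nz_count / B, rownames(sub_mat))
}

# cv.glmnet warns about folds with < 8 members of a class; routine at
# the fold sizes used here and not actionable, so keep it quiet.
quiet_cv_glmnet <- function(...) {
  withCallingHandlers(
    glmnet::cv.glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8|grouped=FALSE", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# glmnet requires >= 2 columns; a constant zero column (which always
# takes coefficient 0) pads single-feature designs.
pad_design <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, `.pad` = 0)
}

#' Fit the final elastic-net logistic model on a marker panel
#'
#' Penalized logistic regression at fixed `alpha`; `lambda` chosen by
#' internal stratified cross-validation minimizing binomial deviance.
#' Features are standardized inside the fit; the returned coefficients
#' are on the input FPKM scale.
#'
#' @param mat FPKM matrix restricted to training samples (all peaks or
#'   panel peaks; rows are subset to `markers`).
#' @param groups "case"/"control" along columns.
#' @param markers panel peak ids (rows of `mat`).
#' @param alpha elastic-net mixing parameter.
#' @param seed seed for the internal fold assignment.
#' @param nfolds internal cross-validation folds.
#' @return an `elastic_net_model`: `markers`, `coef` (named),
#'   `intercept`, `alpha`, `lambda`.
#' @export
fit_final <- function(mat, groups, markers, alpha = 0.2, seed = 1L,
                      nfolds = 5L) {
  if (length(markers) == 0L) stop("empty marker panel")
  missing_m <- setdiff(markers, rownames(mat))
  if (length(missing_m)) stop("markers absent from matrix: ",
                              paste(missing_m, collapse = ", "))
  y <- factor(ifelse(groups == "case", "case", "control"),
              levels = c("control", "case"))
  x <- pad_design(t(mat[markers, , drop = FALSE]))
  fit <- withr::with_seed(stage_seed(seed, "fit_final"), {
    foldid <- stratified_folds(y == "case", nfolds)
    quiet_cv_glmnet(x, y, family = "binomial", alpha = alpha,
                    foldid = foldid, standardize = TRUE)
  })
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
  structure(list(markers = markers,
                 coef = stats::setNames(beta[1 + seq_along(markers)], markers),
                 intercept = beta[1], alpha = alpha,
                 lambda = fit$lambda.min, seed = seed),
            class = "elastic_net_model")
}

#' Select the elastic-net mixing parameter on the validation set
#'
#' For each alpha in the grid, fits the final model for that alpha's
#' panel on the training samples and measures classification accuracy
#' (at probability 0.5) on the validation samples; returns the alpha
#' with maximal accuracy, ties going to the smaller alpha. Selecting a
#' tuning parameter against the validation set leaks validation
#' information into the model choice; the published procedure does
#' exactly this, and the report flags it.
#'
#' @param panels named list (names = alpha values) of marker id
#'   vectors, or a single vector used for every alpha.
#' @param train_mat,train_groups training FPKM matrix and labels.
#' @param val_mat,val_groups validation FPKM matrix and labels.
#' @param grid alpha grid.
#' @param seed seed for the per-alpha final fits.
#' @return list `alpha`, `accuracy` (per-alpha table), `leakage_note`.
#' @export
select_alpha <- function(panels, train_mat, train_groups, val_mat, val_groups,
                         grid = seq(0.1, 0.9, by = 0.1), seed = 1L) {
  acc <- vapply(grid, function(a) {
    panel <- if (is.list(panels)) panels[[as.character(a)]] else panels
    if (is.null(panel) || length(panel) == 0L) return(NA_real_)
    m <- fit_final(train_mat, train_groups, panel, alpha = a, seed = seed)
    ev <- evaluate(m, val_mat, val_groups)
    mean(ev$scores$predicted == val_groups)
  }, numeric(1))
  ok <- which(!is.na(acc))
  if (!length(ok)) stop("no alpha yielded a usable panel")
  best <- ok[order(-acc[ok], grid[ok])][1]
  list(alpha = grid[best],
       accuracy = data.frame(alpha = grid, accuracy = acc),
       leakage_note = "alpha chosen on the validation set (published procedure); validation metrics are optimistic")
}

#' Weighted diagnosis score
#'
#' `wd = sum_k coef(k) * FPKM(k)` over the model's markers; the
#' intercept is excluded.
#'
#' @param model an `elastic_net_model`.
#' @param fpkm named vector of marker FPKM values, or a matrix
#'   (peaks x samples) containing all marker rows.
#' @return numeric score (or per-sample vector for a matrix).
#' @export
wd_score <- function(model, fpkm) {
  if (is.matrix(fpkm)) {
    missing_m <- setdiff(model$markers, rownames(fpkm))
    if (length(missing_m)) stop("missing marker value(s): ",
                                paste(missing_m, collapse = ", "))
    return(as.numeric(model$coef %*% fpkm[model$markers, , drop = FALSE]))
  }
  missing_m <- setdiff(model$markers, names(fpkm))
  if (length(missing_m)) stop("missing marker value(s): ",
                              paste(missing_m, collapse = ", "))
  sum(model$coef * fpkm[model$markers])
}

#' Evaluate a fitted model on a labeled set
#'
#' Predicted probabilities come from the logistic model (intercept
#' included); AUC from [roc_auc()] on the probabilities; sensitivity
#' and specificity at `prob_threshold` with positives = cases.
#' Per-sample wd-scores are attached.
#'
#' @param model an `elastic_net_model`.
#' @param mat FPKM matrix containing the model's marker rows.
#' @param groups "case"/"control" along columns.
#' @param prob_threshold classification cut-off on the probability.
#' @return a `score_report`: list with `auc`, `sensitivity`,
#'   `specificity`, and `scores` (per-sample data frame: `sample_id`,
#'   `wd_score`, `probability`, `predicted`, `group`).
#' @export
evaluate <- function(model, mat, groups, prob_threshold = 0.5) {
  if (!any(groups == "case") || !any(groups == "control")) {
    stop("both classes must be present")
  }
  wd <- wd_score(model, mat)
  prob <- stats::plogis(model$intercept + wd)
  predicted <- ifelse(prob >= prob_threshold, "case", "control")
  roc <- roc_auc(prob, groups, threshold = prob_threshold)
  structure(list(auc = roc$auc,
                 sensitivity = mean(predicted[groups == "case"] == "case"),
                 specificity = mean(predicted[groups == "control"] == "control"),
                 scores = data.frame(
                   sample_id = colnames(mat), wd_score = wd,
                   probability = prob, predicted = predicted, group = groups,
                   stringsAsFactors = FALSE, row.names = NULL)),
            class = "score_report")
}

#' Combine two channels' panels into one feature matrix
#'
#' Feature space = disjoint union of the two panels with channel-tagged
#' ids (a locus shared by both channels contributes two features).
#' Samples present in only one channel are dropped with a warning.
#'
#' @param panel_mc,panel_hmc marker id vectors for the 5mC and 5hmC
#'   panels (either may be empty).
#' @param mat_mc,mat_hmc FPKM matrices (peaks x samples) per channel;
#'   columns are sample ids shared across channels.
#' @return list `mat` (combined features x paired samples), `features`
#'   (data frame id/channel/peak_id).
#' @export
integrate_channels <- function(panel_mc, panel_hmc, mat_mc, mat_hmc) {
  common <- intersect(colnames(mat_mc), colnames(mat_hmc))
  dropped <- length(union(colnames(mat_mc), colnames(mat_hmc))) - length(common)
  if (dropped > 0) warning(sprintf("%d unpaired sample(s) dropped", dropped))
  if (!length(common)) stop("no paired samples")
  blocks <- list()
  feats <- list()
  if (length(panel_mc)) {
    b <- mat_mc[panel_mc, common, drop = FALSE]
    rownames(b) <- paste0("5mC:", panel_mc)
    blocks$mc <- b
    feats$mc <- data.frame(id = rownames(b), channel = "5mC",
                           peak_id = panel_mc, stringsAsFactors = FALSE)
  }
  if (length(panel_hmc)) {
    b <- mat_hmc[panel_hmc, common, drop = FALSE]
    rownames(b) <- paste0("5hmC:", panel_hmc)
    blocks$hmc <- b
    feats$hmc <- data.frame(id = rownames(b), channel = "5hmC",
                            peak_id = panel_hmc, stringsAsFactors = FALSE)
  }
  if (!length(blocks)) stop("both panels empty")
  list(mat = do.call(rbind, blocks), features = do.call(rbind, feats),
       samples = common)
}

#' Compare wd-scores across clinical groups
#'
#' Two levels: Wilcoxon rank-sum (default) or t-test; more than two
#' levels: one-way ANOVA.
#'
#' @param scores numeric wd-scores.
#' @param grouping factor-like grouping with >= 2 non-empty levels.
#' @param two_group_test "wilcoxon" or "t".
#' @return an `assoc_test`.
#' @export
compare_wd_groups <- function(scores, grouping,
                              two_group_test = c("wilcoxon", "t")) {
  two_group_test <- match.arg(two_group_test)
  grouping <- factor(grouping)
  grouping <- droplevels(grouping)
  if (nlevels(grouping) < 2L) stop("need >= 2 non-empty groups")
  parts <- split(scores, grouping)
  if (nlevels(grouping) == 2L) {
    if (two_group_test == "wilcoxon") {
      wilcoxon_rank_sum(parts[[1]], parts[[2]])
    } else {
      t_test(parts[[1]], parts[[2]])
    }
  } else {
    anova_oneway(parts)
  }
}
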