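#' Pseudocount-stabilized log2 fold change of group means
#'
#' @param mean_case,mean_control nonnegative group means (vectorized).
#' @param eps pseudocount guarding against zero means.
#' @return `log2((mean_case + eps) / (mean_control + eps))`.
#' @export
log2fc <- function(mean_case, mean_control, eps = 0.01) {
  log2((mean_case + eps) / (mean_control + eps))
}

# Vectorized two-sample Welch t-test over matrix rows. Written in-house
# because no installed package offers row-wise t-tests; verified against
# stats::t.test row by row in the test suite.
row_welch <- function(mat, is_case) {
  x <- mat[, is_case, drop = FALSE]
  y <- mat[, !is_case, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) stop("each group needs >= 2 samples")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # constant identical rows: 0/0 -> no evidence of difference
  degen <- se2 == 0
  stat[degen] <- 0; p[degen] <- 1; df[degen] <- nx + ny - 2
  list(statistic = stat, df = df, p = p, mean_case = mx, mean_control = my)
}

#' Call differentially (hydroxy)methylated peaks
#'
#' Per-peak Welch t-test of case vs control FPKM with a fold-change
#' filter. BH q-values are always computed; the pass rule uses either
#' the raw p-value or the q-value depending on `use_fdr`.
#'
#' @param mat FPKM matrix (peaks x samples) or a `signal_matrix`.
#' @param groups "case"/"control" along columns (taken from metadata
#'   when `mat` is a `signal_matrix`).
#' @param p_threshold raw p (or q when `use_fdr`) cut-off.
#' @param use_fdr threshold on BH q-values instead of raw p.
#' @param lfc_threshold minimum |log2FC|.
#' @param log2_transform run the t-test on log2(FPKM + 1) (fold changes
#'   are always computed on the untransformed means).
#' @param eps pseudocount for [log2fc()].
#' @return data frame (one row per peak): `peak_id`, `mean_case`,
#'   `mean_control`, `log2fc`, `statistic`, `p`, `q`, `passes`,
#'   `direction` ("hyper_case"/"hypo_case").
#' @export
call_differential <- function(mat, groups = NULL, p_threshold = 0.01,
                              use_fdr = FALSE, lfc_threshold = 0.8,
                              log2_transform = FALSE, eps = 0.01) {
  if (inherits(mat, "signal_matrix")) {
    groups <- mat$metadata$group
    mat <- mat$fpkm
  }
  stopifnot(!is.null(groups), ncol(mat) == length(groups))
  is_case <- groups == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) stop("each group needs >= 2 samples")
  test_mat <- if (log2_transform) log2(mat + 1) else mat
  tt <- row_welch(test_mat, is_case)
  mc <- rowMeans(mat[, is_case, drop = FALSE])
  mh <- rowMeans(mat[, !is_case, drop = FALSE])
  lfc <- log2fc(mc, mh, eps)
  q <- bh_fdr(tt$p)
  crit <- if (use_fdr) q else tt$p
  passes <- crit < p_threshold & abs(lfc) > lfc_threshold
  data.frame(peak_id = if (is.null(rownames(mat))) seq_len(nrow(mat)) else rownames(mat),
             mean_case = mc, mean_control = mh, log2fc = lfc,
             statistic = tt$statistic, p = tt$p, q = q, passes = passes,
             direction = ifelse(lfc > 0, "hyper_case", "hypo_case"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a differential table
#' @param dt output of [call_differential()].
#' @return list: `n_pass`, `n_hyper`, `n_hypo`.
#' @export
differential_counts <- function(dt) {
  list(n_pass = sum(dt$passes),
       n_hyper = sum(dt$passes & dt$direction == "hyper_case"),
       n_hypo = sum(dt$passes & dt$direction == "hypo_case"))
}
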