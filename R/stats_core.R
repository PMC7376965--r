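#' @name stats_core
#' @title Statistical primitives
#' @description Thin, uniform wrappers over the classical tests the
#'   pipeline uses (chi-squared, Fisher, t, Wilcoxon-Mann-Whitney,
#'   one-way ANOVA, BH correction, ROC/AUC). Each returns an
#'   `assoc_test` list: `statistic`, `p_value`, `df` (or `exact` flag),
#'   `method`, optional `estimate`.
NULL

assoc_test <- function(statistic, p_value, method, df = NA_real_,
                       exact = FALSE, estimate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = unname(statistic),
                 p_value = min(unname(p_value), 1),
                 df = unname(df), exact = exact, method = method,
                 estimate = estimate),
            class = "assoc_test")
}

#' Pearson chi-squared test of a 2x2 table
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome
#'   (table `rbind(c(a, b), c(c, d))`).
#' @param correction apply Yates continuity correction (off by default;
#'   the uncorrected Pearson statistic is the conventional headline
#'   value for cohort characteristics tables).
#' @return an `assoc_test`.
#' @export
chi2_2x2 <- function(a, b, c, d, correction = FALSE) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("cell counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared undefined: zero margin")
  }
  ht <- stats::chisq.test(tab, correct = correction)
  assoc_test(ht$statistic, ht$p.value, df = ht$parameter,
             method = if (correction) "chi-squared (Yates)" else "chi-squared")
}

#' Fisher's exact test of a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' tables no more probable than the observed one. A zero margin gives
#' p = 1 by convention (flagged in the method string).
#'
#' @param a,b,c,d cell counts as in [chi2_2x2()].
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return an `assoc_test` with the conditional odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("cell counts must be nonnegative")
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  ht <- stats::fisher.test(tab, alternative = alternative)
  assoc_test(NA_real_, ht$p.value, exact = TRUE,
             method = if (degenerate) "fisher exact (zero margin)" else "fisher exact",
             estimate = unname(ht$estimate))
}

#' Welch (default) or pooled two-sample t-test
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param welch use Welch degrees of freedom (default, matching R's
#'   `t.test` default).
#' @return an `assoc_test` with the mean difference as estimate.
#' @export
t_test <- function(x, y, welch = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(assoc_test(0, 1, df = length(x) + length(y) - 2,
                      method = "t-test (degenerate: identical constants)",
                      estimate = 0))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  assoc_test(ht$statistic, ht$p.value, df = ht$parameter,
             method = if (welch) "Welch t-test" else "Student t-test",
             estimate = unname(diff(rev(ht$estimate))))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact for small samples without ties, normal approximation with tie
#' correction otherwise (R's `wilcox.test` policy).
#'
#' @param x,y numeric samples.
#' @return an `assoc_test`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  assoc_test(ht$statistic, ht$p.value,
             exact = is.null(ht$parameter), method = "Wilcoxon rank-sum")
}

#' One-way ANOVA
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   each >= 2 values).
#' @return an `assoc_test` with the F statistic.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("ANOVA undefined: zero within-group variance")
  }
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  assoc_test(ht$statistic, ht$p.value, df = unname(ht$parameter[1]),
             method = "one-way ANOVA")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values (monotone step-up adjustment, capped at 1),
#'   order-preserving with the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' ROC AUC and operating point by the rank formulation
#'
#' AUC equals the Mann-Whitney concordance probability, computed with
#' midranks so tied scores contribute 1/2. Positives are cases
#' (`labels == 1` or `"case"`).
#'
#' @param scores numeric classification scores (higher = more
#'   case-like).
#' @param labels 0/1, logical, or "case"/"control".
#' @param threshold optional score cut-off; when given, sensitivity
#'   (TP/(TP+FN)) and specificity (TN/(TN+FP)) at `scores >= threshold`
#'   are reported.
#' @return list `auc`, and with a threshold also `sensitivity`,
#'   `specificity`.
#' @export
roc_auc <- function(scores, labels, threshold = NULL) {
  pos <- normalize_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  out <- list(auc = auc)
  if (!is.null(threshold)) {
    call_pos <- scores >= threshold
    out$sensitivity <- sum(call_pos & pos) / n1
    out$specificity <- sum(!call_pos & !pos) / n0
  }
  out
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "case"
  } else {
    as.logical(labels)
  }
}
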