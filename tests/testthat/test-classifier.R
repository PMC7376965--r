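md_for_split <- data.frame(
  sample_id = sprintf("s%03d", 1:140),
  group = rep(c("case", "control"), c(40, 100)),
  channel = "5mC", stringsAsFactors = FALSE)

test_that("stratified splits use floor on training counts and are seed-reproducible", {
  sp <- make_split(md_for_split, frac_case = 0.75, frac_control = 0.75, seed = 2)
  expect_equal(sum(sp$train %in% md_for_split$sample_id[1:40]), 30)   # floor(.75*40)
  expect_equal(sum(sp$train %in% md_for_split$sample_id[41:140]), 75) # floor(.75*100)
  expect_setequal(c(sp$train, sp$validation), md_for_split$sample_id)
  expect_length(intersect(sp$train, sp$validation), 0)
  sp2 <- make_split(md_for_split, 0.75, 0.75, seed = 2)
  expect_identical(sp$train, sp2$train)
  tiny <- md_for_split[c(1, 41), ]
  expect_error(make_split(tiny, 0.5, 0.5, seed = 1), "too small")
})

test_that("wd-score is the interceptless coefficient-weighted FPKM sum", {
  model <- structure(list(markers = c("A", "B"),
                          coef = c(A = 2, B = -1), intercept = 5,
                          alpha = 0.2, lambda = 0.1),
                     class = "elastic_net_model")
  expect_equal(wd_score(model, c(A = 3, B = 4)), 2)
  zero <- model; zero$coef[] <- 0
  expect_equal(wd_score(zero, c(A = 3, B = 4)), 0)
  ext <- structure(list(markers = c("A", "B", "C"),
                        coef = c(A = 2, B = -1, C = 0), intercept = 5),
                   class = "elastic_net_model")
  expect_equal(wd_score(ext, c(A = 3, B = 4, C = 99)), 2)
  expect_error(wd_score(model, c(A = 3)), "missing marker")
})

test_that("AUC on wd-scores equals AUC on probabilities (monotone invariance)", {
  withr::with_seed(101, {
    model <- structure(list(markers = sprintf("m%d", 1:4),
                            coef = stats::setNames(rnorm(4), sprintf("m%d", 1:4)),
                            intercept = -0.3),
                       class = "elastic_net_model")
    mat <- matrix(rexp(4 * 30), nrow = 4,
                  dimnames = list(sprintf("m%d", 1:4), sprintf("s%d", 1:30)))
    groups <- sample(c("case", "control"), 30, replace = TRUE)
    groups[1:2] <- c("case", "control")
    ev <- evaluate(model, mat, groups)
    expect_equal(roc_auc(ev$scores$wd_score, groups)$auc, ev$auc, tolerance = 1e-12)
  })
})

test_that("evaluation reports perfect metrics for a separating model", {
  mat <- matrix(c(rep(10, 5), rep(0, 5)), nrow = 1,
                dimnames = list("m1", sprintf("s%d", 1:10)))
  groups <- rep(c("case", "control"), each = 5)
  model <- structure(list(markers = "m1", coef = c(m1 = 3), intercept = -15),
                     class = "elastic_net_model")
  ev <- evaluate(model, mat, groups)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  # constant probability on balanced labels gives midrank AUC 0.5
  flat <- structure(list(markers = "m1", coef = c(m1 = 0), intercept = 0),
                    class = "elastic_net_model")
  expect_equal(evaluate(flat, mat, groups)$auc, 0.5)
})

test_that("final fit is deterministic, sign-consistent, and sparser at higher alpha", {
  withr::with_seed(102, {
    n <- 60
    groups <- rep(c("case", "control"), each = n / 2)
    mat <- matrix(rnorm(20 * n, 5), nrow = 20,
                  dimnames = list(sprintf("m%d", 1:20), sprintf("s%d", 1:n)))
    mat["m1", groups == "case"] <- mat["m1", groups == "case"] + 4
    fit1 <- fit_final(mat, groups, rownames(mat), alpha = 0.5, seed = 9)
    fit2 <- fit_final(mat, groups, rownames(mat), alpha = 0.5, seed = 9)
    expect_identical(fit1$coef, fit2$coef)
    expect_gt(fit1$coef["m1"], 0)  # elevated in cases -> positive weight

    nnz <- sapply(c(0.1, 0.5, 1.0), function(a)
      sum(fit_final(mat, groups, rownames(mat), alpha = a, seed = 9)$coef != 0))
    expect_true(nnz[3] <= nnz[1])
  })
})

test_that("stability selection recovers planted markers and stays quiet on null data", {
  sim <- simulate_signal_matrix(cohort_spec(seed = 401, n_case = 24, n_control = 24,
                                            n_regions = 300, n_diff = 12, lfc = 2))
  panel <- stability_select(sim$fpkm, sim$metadata$group, R = 3, K = 4, B = 8,
                            alpha = 0.2, seed = 11)
  truth_ids <- sim$regions$region_id[sim$regions$differential]
  expect_gte(length(intersect(panel$markers, truth_ids)),
             ceiling(0.7 * length(truth_ids)))
  expect_lte(length(setdiff(panel$markers, truth_ids)), 3)
  # identical call, identical result (all randomness from the seed)
  panel2 <- stability_select(sim$fpkm, sim$metadata$group, R = 3, K = 4, B = 8,
                             alpha = 0.2, seed = 11)
  expect_identical(panel$markers, panel2$markers)

  null_sim <- simulate_signal_matrix(cohort_spec(seed = 402, n_case = 24,
                                                 n_control = 24, n_regions = 300,
                                                 n_diff = 0))
  null_panel <- suppressWarnings(
    stability_select(null_sim$fpkm, null_sim$metadata$group,
                     R = 3, K = 4, B = 8, alpha = 0.2, seed = 12))
  expect_lte(length(null_panel$markers), 1)
})

test_that("a perfectly separating marker is selected in every subset of every round", {
  withr::with_seed(103, {
    n <- 40
    groups <- rep(c("case", "control"), each = n / 2)
    mat <- matrix(rnorm(30 * n, 10), nrow = 30,
                  dimnames = list(sprintf("m%d", 1:30), sprintf("s%d", 1:n)))
    mat["m1", ] <- ifelse(groups == "case", 30, 1) + rnorm(n, sd = 0.1)
    panel <- stability_select(mat, groups, R = 3, K = 4, B = 6, alpha = 0.5,
                              candidate_p = 0.05, use_fdr = FALSE, seed = 13)
    expect_true("m1" %in% panel$markers)
    expect_equal(unname(panel$rounds_present["m1"]), 3L)
    m1 <- panel$freq[panel$freq$peak_id == "m1", ]
    expect_true(all(m1$freq == 1))
  })
})

test_that("alpha selection maximizes validation accuracy with ties to the smaller alpha", {
  withr::with_seed(104, {
    n <- 60
    groups <- rep(c("case", "control"), each = n / 2)
    mat <- matrix(rnorm(10 * n, 5), nrow = 10,
                  dimnames = list(sprintf("m%d", 1:10), sprintf("s%d", 1:n)))
    mat["m1", groups == "case"] <- mat["m1", groups == "case"] + 5
    vmat <- matrix(rnorm(10 * 20, 5), nrow = 10,
                   dimnames = list(sprintf("m%d", 1:10), sprintf("v%d", 1:20)))
    vgroups <- rep(c("case", "control"), each = 10)
    vmat["m1", vgroups == "case"] <- vmat["m1", vgroups == "case"] + 5
    res <- select_alpha(rownames(mat), mat, groups, vmat, vgroups,
                        grid = c(0.2, 0.5), seed = 7)
    expect_true(res$alpha %in% c(0.2, 0.5))
    # strong single marker: both alphas classify perfectly -> tie -> smaller
    expect_equal(res$alpha, 0.2)
    single <- select_alpha(rownames(mat), mat, groups, vmat, vgroups,
                           grid = 0.4, seed = 7)
    expect_equal(single$alpha, 0.4)
    expect_match(res$leakage_note, "validation")
  })
})

test_that("channel integration concatenates channel-tagged panels over paired samples", {
  mat_mc <- matrix(1:12, nrow = 3, dimnames = list(c("a", "b", "c"),
                                                   c("s1", "s2", "s3", "s4")))
  mat_hmc <- matrix(13:21, nrow = 3, dimnames = list(c("a", "x", "y"),
                                                     c("s2", "s3", "s4")))
  expect_warning(comb <- integrate_channels(c("a", "b"), c("x"), mat_mc, mat_hmc),
                 "unpaired")
  expect_equal(rownames(comb$mat), c("5mC:a", "5mC:b", "5hmC:x"))
  expect_equal(comb$samples, c("s2", "s3", "s4"))
  # a shared locus contributes one feature per channel
  expect_warning(both <- integrate_channels("a", "a", mat_mc, mat_hmc))
  expect_equal(rownames(both$mat), c("5mC:a", "5hmC:a"))
  # degenerate union: empty second panel reduces to the first channel
  expect_warning(only_mc <- integrate_channels(c("a", "b"), character(0),
                                               mat_mc, mat_hmc))
  expect_equal(rownames(only_mc$mat), c("5mC:a", "5mC:b"))
})

test_that("wd-score group comparisons route to the right test", {
  expect_equal(compare_wd_groups(c(1, 2, 3, 1, 2, 3),
                                 rep(c("a", "b"), each = 3))$p_value, 1)
  withr::with_seed(105, {
    shifted <- c(rnorm(30), rnorm(30, 2))
    res <- compare_wd_groups(shifted, rep(c("a", "b"), each = 30))
    expect_lt(res$p_value, 0.01)
    staged <- c(rnorm(15, 0), rnorm(15, 1), rnorm(15, 2))
    a <- compare_wd_groups(staged, rep(c("I", "II", "III"), each = 15))
    expect_match(a$method, "ANOVA")
    expect_lt(a$p_value, 0.01)
  })
  expect_error(compare_wd_groups(1:3, rep("a", 3)), ">= 2")
})
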