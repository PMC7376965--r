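test_that("fixed-width reduction yields 201 bp summit-centered peaks and drops edge cases", {
  pk <- make_peaks("chr1", c(400, 0, 9850), c(600, 100, 9999),
                   score = c(5, 5, 5), summit = c(500, 50, 9950))
  out <- fix_width(pk, c(chr1 = 10000), half_width = 100)
  expect_equal(nrow(out), 1L)       # summit 50 and summit 9950 both cross ends
  expect_equal(out$start, 400)
  expect_equal(out$end, 601)
  expect_equal(out$end - out$start, 201)
  expect_error(fix_width(pk, c(chr2 = 1e4)), "missing")
})

test_that("score-per-million normalization sums to 1e6 and preserves proportions", {
  pk <- make_peaks("chr1", c(0, 300), c(201, 501), score = c(3, 1))
  out <- spm_normalize(pk)
  expect_equal(out$spm, c(750000, 250000))
  one <- spm_normalize(make_peaks("chr1", 0, 201, score = 42))
  expect_equal(one$spm, 1e6)
  four <- spm_normalize(make_peaks("chr1", c(0, 300, 600, 900),
                                   c(201, 501, 801, 1101), score = rep(1, 4)))
  expect_equal(four$spm, rep(250000, 4))
  expect_error(spm_normalize(make_peaks("chr1", 0, 201, score = 0)), "zero")
})

test_that("iterative removal keeps the best peak of each overlapping cluster", {
  pk <- make_peaks("chr1", c(0, 100, 300), c(201, 301, 501), score = c(5, 4, 3))
  out <- iterative_removal(pk)
  expect_equal(out$start, c(0, 300))  # B overlaps A and dies; C survives

  disjoint <- make_peaks("chr1", c(0, 300, 600), c(201, 501, 801),
                         score = c(1, 2, 3))
  expect_equal(iterative_removal(disjoint)$start, disjoint$start)

  tie <- make_peaks("chr1", c(100, 0), c(301, 201), score = c(7, 7))
  expect_equal(iterative_removal(tie)$start, 0)  # leftmost wins ties
})

test_that("iterative removal matches the brute-force greedy oracle on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      for (i in 1:100) {
        pk <- random_peak_instance(sample(2:20, 1))
        got <- iterative_removal(pk)
        want <- greedy_removal_oracle(pk)
        expect_equal(got[c("chrom", "start", "end", "score")],
                     want[c("chrom", "start", "end", "score")])
      }
    })
  }
})

test_that("group reproducibility uses a ceil(N% of group) support threshold", {
  # ten samples with the identical single peak: retained at N=50
  samples <- lapply(1:10, function(i)
    spm_normalize(make_peaks("chr1", 1000, 1201, score = 10,
                             sample_id = sprintf("s%d", i))))
  names(samples) <- sprintf("s%d", 1:10)
  tpl <- group_reproducible(samples, N_pct = 50)
  expect_equal(nrow(tpl), 1L)
  expect_equal(tpl$support, 10L)

  # peak present in only 2 of 10 samples dies at N=30 (ceil(3) > 2)
  sparse <- samples
  for (i in 3:10) sparse[[i]] <- spm_normalize(
    make_peaks("chr1", 5000, 5201, score = 10, sample_id = sprintf("s%d", i)))
  tpl2 <- group_reproducible(sparse, N_pct = 30)
  expect_false(any(tpl2$start == 1000))
  expect_true(any(tpl2$start == 5000))

  # template coordinates come from the highest-spm instance of a cluster
  shifted <- list(
    a = spm_normalize(make_peaks("chr1", c(100, 1000), c(301, 1201),
                                 score = c(9, 1), sample_id = "a")),
    b = spm_normalize(make_peaks("chr1", c(150, 1000), c(351, 1201),
                                 score = c(1, 9), sample_id = "b")))
  tpl3 <- group_reproducible(shifted, N_pct = 50)
  expect_true(100 %in% tpl3$start)  # sample a's instance has higher spm
  expect_false(150 %in% tpl3$start)
})

test_that("consensus building filters blacklist overlap and excluded chromosomes", {
  grp1 <- spm_normalize(make_peaks("chr1", c(0, 1000), c(201, 1201), score = c(5, 5)))
  grp2 <- spm_normalize(make_peaks(c("chr1", "chrX"), c(2000, 100), c(2201, 301),
                                   score = c(5, 5)))
  bl <- data.frame(chrom = "chr1", start = 1200, end = 1300)  # 1 bp overlap
  cons <- build_consensus(list(grp1, grp2), blacklist = bl)
  expect_equal(cons$start, c(0, 2000))
  expect_false(any(cons$chrom == "chrX"))
  expect_true(all(diff(cons$start) > 0))

  # overlapping case/control templates: higher-spm template survives
  a <- spm_normalize(make_peaks("chr1", 0, 201, score = 10))
  b <- spm_normalize(make_peaks("chr1", 100, 301, score = 3))
  b$spm <- 5e5  # pooled comparison is on spm
  a$spm <- 1e6
  cons2 <- build_consensus(list(a, b))
  expect_equal(cons2$start, 0)
})

test_that("consensus output is invariant to sample and peak ordering", {
  withr::with_seed(42, {
    samples <- lapply(1:6, function(i) {
      pk <- random_peak_instance(12)
      pk$sample_id <- sprintf("s%d", i)
      spm_normalize(pk)
    })
    names(samples) <- sprintf("s%d", 1:6)
    groups <- stats::setNames(rep(c("case", "control"), each = 3), names(samples))
    ref <- consensus_for_N(samples, groups, N_pct = 30, spm_min = 0)
    shuffled <- lapply(rev(samples), function(p) p[sample(nrow(p)), , drop = FALSE])
    alt <- consensus_for_N(shuffled, groups[names(shuffled)], N_pct = 30, spm_min = 0)
    expect_equal(ref$consensus$start, alt$consensus$start)
    expect_equal(ref$consensus$chrom, alt$consensus$chrom)
  })
})

test_that("occupancy is a 0/1 overlap-at-least-1bp matrix", {
  cons <- build_consensus(list(spm_normalize(
    make_peaks("chr1", c(0, 1000), c(201, 1201), score = c(5, 5)))))
  samples <- list(
    hit = make_peaks("chr1", 200, 401, score = 1),    # 1 bp overlap with [0,201)
    abut = make_peaks("chr1", 201, 402, score = 1),   # abutting: no overlap
    none = make_peaks("chr2", 0, 201, score = 1))
  occ <- occupancy(cons, samples)
  expect_equal(unname(occ[, "hit"]), c(1L, 0L))
  expect_equal(unname(occ[, "abut"]), c(0L, 0L))
  expect_equal(unname(occ[, "none"]), c(0L, 0L))
})

test_that("N selection counts FDR-significant Fisher peaks, ties to the smaller N", {
  # a peak present in all cases and no controls is maximally significant
  occ <- rbind(peakA = c(rep(1L, 10), rep(0L, 10)),
               peakB = rep(1L, 20))
  groups <- rep(c("case", "control"), each = 10)
  ft <- occupancy_fisher(occ, groups)
  expect_equal(ft$p[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(ft$p[2], 1)

  # no group difference at any N: zero significant, smallest N wins
  occ_null <- matrix(1L, nrow = 5, ncol = 20,
                     dimnames = list(sprintf("p%d", 1:5), NULL))
  sel <- select_N(list("10" = occ_null, "30" = occ_null, "50" = occ_null), groups)
  expect_equal(sel$summary$n_significant, c(0L, 0L, 0L))
  expect_equal(sel$chosen_N, 10)
})

test_that("planted group-specific peaks drive N selection to a low threshold", {
  # group-specific peaks present in ~35% of cases only: visible in the
  # occupancy at N<=30 but absent from templates at high N
  withr::with_seed(5, {
    n <- 20
    groups <- stats::setNames(rep(c("case", "control"), each = n),
                              sprintf("s%02d", 1:(2 * n)))
    chrom_sizes <- c(chr1 = 1e6)
    shared_pos <- seq(1000, 40000, by = 2000)
    specific_pos <- seq(100000, 139000, by = 2000)
    samples <- lapply(names(groups), function(sid) {
      pos <- shared_pos
      if (groups[sid] == "case" && stats::runif(1) < 0.35) {
        pos <- c(pos, specific_pos)
      }
      spm_normalize(make_peaks("chr1", pos, pos + 201,
                               score = rep(10, length(pos)), sample_id = sid))
    })
    names(samples) <- names(groups)
    occ_by_N <- lapply(stats::setNames(c(10, 30, 50, 70, 90), c(10, 30, 50, 70, 90)),
                       function(N) consensus_for_N(samples, groups, N,
                                                   spm_min = 0)$occupancy)
    sel <- select_N(occ_by_N, groups)
    expect_lte(sel$chosen_N, 30)
  })
})
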