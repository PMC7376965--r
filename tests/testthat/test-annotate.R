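test_that("element overlap percentages and odds ratios behave at the boundaries", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 3000), end = c(1201, 3201))
  genome <- 1e6
  inside <- list(promoter = data.frame(chrom = "chr1", start = 0, end = 1e5))
  res <- element_overlap(peaks, inside, genome)
  expect_equal(res$percent, 100)
  expect_gt(res$odds_ratio, 1)  # all peak bp inside a 10% class
  none <- element_overlap(peaks,
                          list(exon = data.frame(chrom = "chr2", start = 0, end = 100)),
                          genome)
  expect_equal(none$percent, 0)
  expect_error(element_overlap(peaks[0, ], inside, genome), "empty")
})

test_that("element odds ratio is ~1 for uniformly placed peaks and ordering-invariant", {
  withr::with_seed(111, {
    genome <- 5e6
    start <- sort(sample.int(genome - 300, 5000))
    peaks <- data.frame(chrom = "chr1", start = start, end = start + 201)
    cls <- data.frame(chrom = "chr1", start = 0, end = 0.1 * genome)
    res <- element_overlap(peaks, list(cls = cls), genome)
    expect_lt(abs(res$odds_ratio - 1), 0.15)
    # invariant to peak order and to splitting the class into pieces
    shuf <- peaks[sample(nrow(peaks)), ]
    split_cls <- data.frame(chrom = "chr1",
                            start = seq(0, 0.1 * genome - 1e4, by = 1e4),
                            end = seq(1e4, 0.1 * genome, by = 1e4))
    res2 <- element_overlap(shuf, list(cls = split_cls), genome)
    expect_equal(res$percent, res2$percent)
    expect_equal(res$odds_ratio, res2$odds_ratio, tolerance = 1e-9)
  })
})

test_that("region-set enrichment is centered at zero for shuffled-equivalent peaks", {
  withr::with_seed(112, {
    chrom_sizes <- c(chr1 = 5e6)
    start <- sort(sample.int(5e6 - 300, 5000))
    sample_peaks <- list(s1 = data.frame(chrom = "chr1", start = start,
                                         end = start + 201))
    regions <- data.frame(chrom = "chr1", start = seq(0, 4.9e6, by = 5e5),
                          end = seq(0, 4.9e6, by = 5e5) + 1e5)
    res <- regionset_stats(sample_peaks, regions, chrom_sizes, seed = 5)
    expect_lt(abs(res$per_sample$log2_or), 0.2)
    # seeded shuffle is reproducible
    res2 <- regionset_stats(sample_peaks, regions, chrom_sizes, seed = 5)
    expect_equal(res$per_sample$log2_or, res2$per_sample$log2_or)
    expect_error(regionset_stats(sample_peaks, regions[0, ], chrom_sizes), "empty")
  })
})

test_that("case-enriched fragments in a region set are detected by the Wilcoxon comparison", {
  withr::with_seed(113, {
    chrom_sizes <- c(chr1 = 1e6)
    regions <- data.frame(chrom = "chr1", start = 1e5, end = 2e5)
    groups <- stats::setNames(rep(c("case", "control"), each = 12),
                              sprintf("s%02d", 1:24))
    fsets <- lapply(names(groups), function(sid) {
      n_in <- if (groups[sid] == "case") rpois(1, 400) else rpois(1, 200)
      n_out <- rpois(1, 2000)
      st <- c(runif(n_in, 1e5, 2e5 - 170), runif(n_out, 0, 1e6 - 170))
      fragment_set(data.frame(chrom = "chr1", start = floor(st),
                              end = floor(st) + 167), sid)
    })
    names(fsets) <- names(groups)
    peaks <- lapply(names(groups), function(sid)
      data.frame(chrom = "chr1", start = seq(1000, 9e5, by = 5e4),
                 end = seq(1000, 9e5, by = 5e4) + 201))
    names(peaks) <- names(groups)
    res <- regionset_stats(peaks, regions, chrom_sizes, fsets, groups, seed = 3)
    expect_lt(res$fpkm_test$p_value, 0.01)
  })
})

test_that("metagene profile is flat at 1 under uniform coverage", {
  genes <- data.frame(chrom = "chr1", start = 10000, end = 20000, strand = "+")
  tile <- seq(0, 40000 - 100, by = 100)
  frg <- data.frame(chrom = "chr1", start = tile, end = tile + 100)
  prof <- metagene_profile(frg, genes, flank = 3000, body_bins = 100,
                           flank_bins = 30)
  expect_equal(prof$profile, rep(1, 160), tolerance = 1e-9)
  expect_equal(prof$n_genes, 1)
})

test_that("body-only coverage elevates body bins and strand is respected", {
  genes <- data.frame(chrom = "chr1", start = 10000, end = 20000, strand = "+")
  body <- seq(10000, 20000 - 100, by = 100)
  frg <- data.frame(chrom = "chr1", start = body, end = body + 100)
  prof <- metagene_profile(frg, genes)$profile
  expect_gt(mean(prof[31:130]), mean(prof[c(1:30, 131:160)]))

  # 5'-biased signal on a minus-strand gene appears at the TSS end (left)
  gene_m <- data.frame(chrom = "chr1", start = 10000, end = 20000, strand = "-")
  five_prime <- seq(18000, 20000 - 100, by = 100)  # 5' end of a minus gene
  frg_m <- data.frame(chrom = "chr1", start = five_prime, end = five_prime + 100)
  prof_m <- metagene_profile(frg_m, gene_m)$profile
  left_body <- mean(prof_m[31:50]); right_body <- mean(prof_m[111:130])
  expect_gt(left_body, right_body)

  short <- data.frame(chrom = "chr1", start = 0, end = 150, strand = "+")
  expect_error(metagene_profile(frg, short), "no usable genes")
})
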