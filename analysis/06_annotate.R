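#!/usr/bin/env Rscript
# Annotation of the consensus peaks against a synthetic genome
# annotation: genomic-element percentages and base-pair odds ratios,
# per-sample enrichment in a region set (shuffled-peak background),
# and a TSS->TES metagene profile.

suppressPackageStartupMessages(library(cfpeakpanel))
dir.create("results", showWarnings = FALSE)

sim <- generate_cohort(cohort_spec(seed = 1, n_case = 12, n_control = 12,
                                   n_regions = 400))
groups <- setNames(sim$metadata$group, sim$metadata$sample_id)
prepped <- prepare_sample_peaks(sim$peaks, sim$chrom_sizes)
built <- consensus_for_N(prepped, groups, 30, chrom_sizes = sim$chrom_sizes)
genome_size <- sum(sim$chrom_sizes)

# synthetic annotation: gene bodies tiled over the genome with
# promoters (TSS +/- 2 kb), exons at gene starts, intergenic remainder
set.seed(7)
gene_start <- seq(50000, 4.5e6, by = 100000)
genes <- data.frame(chrom = rep(names(sim$chrom_sizes), each = length(gene_start)),
                    start = gene_start, end = gene_start + 30000,
                    strand = rep(c("+", "-"), length.out = 2 * length(gene_start)))
elements <- list(
  promoter = data.frame(chrom = genes$chrom,
                        start = ifelse(genes$strand == "+", genes$start - 2000,
                                       genes$end - 2000),
                        end = ifelse(genes$strand == "+", genes$start + 2000,
                                     genes$end + 2000)),
  exon = data.frame(chrom = genes$chrom, start = genes$start,
                    end = genes$start + 2000),
  gene_body = genes[, c("chrom", "start", "end")])

el <- element_overlap(built$consensus, elements, genome_size)
write.table(el, "results/element_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

regions <- data.frame(chrom = genes$chrom, start = genes$start,
                      end = genes$start + 10000)  # H3K36me3-like domains
rs <- regionset_stats(prepped, regions, sim$chrom_sizes,
                      fragment_sets = sim$fragments, groups = groups, seed = 7)
write.table(rs$per_sample, "results/regionset_per_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

prof <- metagene_profile(sim$fragments$s001, genes)
write.table(data.frame(bin = seq_along(prof$profile), coverage = prof$profile),
            "results/metagene_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("element enrichment (percent of peaks overlapping, log2 OR):")
for (i in seq_len(nrow(el))) {
  message(sprintf("  %-10s %5.1f%%  log2OR %+0.2f", el$class[i],
                  el$percent[i], el$log2_or[i]))
}
message(sprintf("region-set FPKM case vs control: Wilcoxon p = %.3g",
                rs$fpkm_test$p_value))
message(sprintf("metagene profile over %d genes (%d skipped)",
                prof$n_genes, prof$n_skipped))
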