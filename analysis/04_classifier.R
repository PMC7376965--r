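#!/usr/bin/env Rscript
# Marker panel and prediction model: stratified 75/25 split, stability
# selection (3 rounds x 5 folds x 25 elastic-net repeats at alpha=0.2,
# selection frequency >= 0.95, markers kept if present in >= 3 rounds),
# final penalized logistic fit, wd-scores and held-out evaluation.

suppressPackageStartupMessages(library(cfpeakpanel))
dir.create("results", showWarnings = FALSE)

sim <- generate_cohort(cohort_spec(seed = 1))
cfg <- pipeline_config(seed = 1, N_fixed = 30, R = 3, K = 5, B = 25)
res <- run_pipeline(sim, cfg, outdir = "results/pipeline")

metrics <- data.frame(
  set = c("training", "validation"),
  auc = c(res$train_eval$auc, res$val_eval$auc),
  sensitivity = c(res$train_eval$sensitivity, res$val_eval$sensitivity),
  specificity = c(res$train_eval$specificity, res$val_eval$specificity))
write.table(metrics, "results/classifier_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# wd-score separation between groups on the validation set
sc <- res$val_eval$scores
wd_cmp <- compare_wd_groups(sc$wd_score, sc$group)

message(sprintf("panel: %d markers (of %d consensus peaks)",
                length(res$panel$markers), nrow(res$consensus)))
message(sprintf("training  AUC %.3f  sens %.3f  spec %.3f",
                res$train_eval$auc, res$train_eval$sensitivity,
                res$train_eval$specificity))
message(sprintf("validation AUC %.3f  sens %.3f  spec %.3f",
                res$val_eval$auc, res$val_eval$sensitivity,
                res$val_eval$specificity))
message(sprintf("validation wd-score case vs control: %s p = %.3g",
                wd_cmp$method, wd_cmp$p_value))
message("model, scores and matrices under results/pipeline/")
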