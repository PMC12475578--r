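#!/usr/bin/env Rscript
# Methylation-accessibility integration: Kendall correlation classes of
# peak accessibility vs peak methylation, per-sample subsampled
# correlations, and the srDMR/srDAR overlap panel with its three
# per-sample metrics and their within-sample Pearson correlations.

library(stageomics)

coh <- simulate_cohort(cohort_config(seed = 20260924))
sheet <- coh$sheet
res <- run_cohort_pipeline(coh, classifier_seed = 1)

dir.create("results", showWarnings = FALSE)

# peak-level correlation classes across all samples
sf <- size_factors(coh$peak_counts)
acc_norm <- log2(sweep(coh$peak_counts, 2, sf, "/") + 1)
meth_in_peak <- region_methylation(coh$meth, coh$peaks)
rownames(meth_in_peak) <- rownames(acc_norm)
cls <- classify_peak_correlations(acc_norm, meth_in_peak)
write.table(cls, "results/peak_meth_acc_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("peak correlation classes: %d positive, %d negative, %d none\n",
            sum(cls$class == "positive"), sum(cls$class == "negative"),
            sum(cls$class == "none")))

# per-sample subsampled correlation (mean +- SD), one line per sample
sub <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(j) {
  r <- sample_level_correlation(acc_norm[, j], meth_in_peak[, j],
                                n_subsample = 200, n_repeats = 50,
                                seed = 1000 + j)
  data.frame(sample = sheet$sample_id[j], stage = as.character(sheet$stage[j]),
             mean_tau = r$mean, sd_tau = r$sd)
}))
write.table(sub, "results/sample_level_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("per-sample tau, cohort mean: %.3f\n", mean(sub$mean_tau)))

# panel and metric correlations
panel_tab <- cbind(res$panel_pairs$pairs,
                   srdmr_meth_mean = rowMeans(res$panel_pairs$srdmr_meth,
                                              na.rm = TRUE),
                   srdar_meth_mean = rowMeans(res$panel_pairs$srdar_meth,
                                              na.rm = TRUE),
                   srdar_acc_mean = rowMeans(res$panel_pairs$srdar_acc,
                                             na.rm = TRUE))
write.table(panel_tab, "results/panel_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$metric_correlations, "results/panel_metric_correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("panel: %d srDMR/srDAR pairs (%d srDARs deduplicated)\n",
            nrow(res$panel_pairs$pairs), nrow(res$panel$pairs)))
cat(sprintf("per-sample metric correlations (means): meth-meth %.2f, srDAR meth-acc %.2f\n",
            mean(res$metric_correlations$r_mm, na.rm = TRUE),
            mean(res$metric_correlations$r_da, na.rm = TRUE)))
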