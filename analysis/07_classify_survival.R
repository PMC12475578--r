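#!/usr/bin/env Rscript
# Panel-based classification and prognosis: random-forest cancer-vs-control
# and four-stage classifiers on the panel's srDAR methylation levels
# (train/test ROC AUC), Ward clustering of samples, and median-split
# log-rank survival stratification by mean panel methylation.

library(stageomics)

coh <- simulate_cohort(cohort_config(seed = 20260924))
res <- run_cohort_pipeline(coh, classifier_seed = 1)

dir.create("results", showWarnings = FALSE)

b <- res$binary_report; m <- res$multiclass_report
report <- data.frame(
  model = c("binary", rep("multiclass", length(m$auc_test))),
  class = c("cancer", names(m$auc_test)),
  auc_train = c(b$auc_train[["cancer"]], unname(m$auc_train)),
  auc_test = c(b$auc_test[["cancer"]], unname(m$auc_test)))
write.table(report, "results/classifier_auc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
roc <- do.call(rbind, lapply(names(m$roc_test), function(cl)
  cbind(class = cl, m$roc_test[[cl]])))
write.table(roc, "results/multiclass_roc_test.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("binary test AUC: %.3f; multiclass macro test AUC: %.3f\n",
            b$auc_test[["cancer"]], m$macro_auc_test))
print(round(m$auc_test, 3))

feat <- res$panel$srdar_meth
rownames(feat) <- sprintf("panel_%03d", seq_len(nrow(feat)))
cl <- hierarchical_cluster_samples(feat, k = 2)
write.table(data.frame(sample = names(cl$labels), cluster = cl$labels,
                       stage = coh$sheet$stage[match(names(cl$labels),
                                                     coh$sheet$sample_id)]),
            "results/sample_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sv <- res$survival
write.table(sv$km, "results/km_curves.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("survival: log-rank chisq %.3f, p %.3g; worse group: %s (events low/high %d/%d)\n",
            sv$chisq, sv$p_value, sv$worse_group,
            sv$n_events["low"], sv$n_events["high"]))
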