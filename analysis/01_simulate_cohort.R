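#!/usr/bin/env Rscript
# Build the synthetic four-stage cohort used throughout the analysis and
# write its inputs (sample sheet, count matrices, locus/peak coordinates)
# under results/cohort/. All later steps re-derive the same cohort from the
# same configuration, so every table downstream is reproducible from this
# seed.

library(stageomics)

cfg <- cohort_config(seed = 20260924)
coh <- simulate_cohort(cfg)

outdir <- "results/cohort"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

write_sample_sheet(coh$sheet, file.path(outdir, "sample_sheet.tsv"))
write_count_matrix(coh$peak_counts, file.path(outdir, "peak_counts.tsv"))
write_count_matrix(coh$gene_counts, file.path(outdir, "gene_counts.tsv"))
write_intervals(coh$loci, file.path(outdir, "loci.bed"))
write_intervals(coh$peaks, file.path(outdir, "peaks.bed"))
for (tf in names(coh$tf_sites))
  write_intervals(coh$tf_sites[[tf]],
                  file.path(outdir, sprintf("sites_%s.bed", tf)))

truth <- rbind(
  data.frame(kind = "methylation", id = coh$truth$meth_effects$locus,
             onset = coh$truth$meth_effects$onset,
             direction = coh$truth$meth_effects$direction),
  data.frame(kind = "accessibility", id = coh$truth$acc_effects$peak_id,
             onset = coh$truth$acc_effects$onset,
             direction = coh$truth$acc_effects$direction),
  data.frame(kind = "expression", id = coh$truth$gene_effects$gene,
             onset = coh$truth$gene_effects$onset,
             direction = coh$truth$gene_effects$direction))
write.table(truth, file.path(outdir, "planted_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d samples (%s), %d CpGs, %d peaks, %d genes\n",
            nrow(coh$sheet),
            paste(table(coh$sheet$stage), collapse = "/"),
            nrow(coh$meth$sites), nrow(coh$peak_counts),
            nrow(coh$gene_counts)))
cat(sprintf("planted: %d methylation, %d accessibility, %d expression effects; %d panel loci\n",
            nrow(coh$truth$meth_effects), nrow(coh$truth$acc_effects),
            nrow(coh$truth$gene_effects), length(coh$truth$panel_loci)))
cat(sprintf("mean CpG coverage: %.1f\n", mean(coh$meth$total)))
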