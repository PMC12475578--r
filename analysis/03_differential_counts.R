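#!/usr/bin/env Rscript
# Stage-wise NB differential testing: accessibility peaks (DARs at
# |log2FC| > 2, raw p < 0.001) and genes (DEGs at |log2FC| > 0.58,
# BH q < 0.05), each case stage against control.

library(stageomics)

coh <- simulate_cohort(cohort_config(seed = 20260924))
sheet <- coh$sheet
ctl <- sheet$sample_id[sheet$stage == "CTL"]

dir.create("results", showWarnings = FALSE)
for (st in c("AIS", "MIA", "IAC")) {
  cs <- sheet$sample_id[sheet$stage == st]
  res_pk <- nb_test(coh$peak_counts, cs, ctl)
  res_gn <- nb_test(coh$gene_counts, cs, ctl)
  dars <- call_dars(res_pk)
  degs <- call_degs(res_gn)
  write.table(dars, sprintf("results/dar_%s_vs_CTL.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(degs, sprintf("results/deg_%s_vs_CTL.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s vs CTL: %d DARs, %d DEGs\n", st, nrow(dars), nrow(degs)))
}
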