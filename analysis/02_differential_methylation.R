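#!/usr/bin/env Rscript
# Stage-wise DMC calling with the beta-binomial credible difference
# (threshold 0.20) and merging into DMRs (>= 3 DMCs, gap <= 200 bp), per
# case stage against control.

library(stageomics)

coh <- simulate_cohort(cohort_config(seed = 20260924))
sheet <- coh$sheet
ctl <- sheet$sample_id[sheet$stage == "CTL"]

dir.create("results", showWarnings = FALSE)
for (st in c("AIS", "MIA", "IAC")) {
  dmcs <- call_dmcs(coh$meth, sheet$sample_id[sheet$stage == st], ctl)
  dmrs <- merge_dmcs_to_dmrs(dmcs[order(dmcs$chrom, dmcs$start),
                                  c("chrom", "start", "direction")])
  write.table(dmcs, sprintf("results/dmc_%s_vs_CTL.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dmrs, sprintf("results/dmr_%s_vs_CTL.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s vs CTL: %d DMCs (%d hyper / %d hypo), %d DMRs\n",
              st, nrow(dmcs), sum(dmcs$direction == "hyper"),
              sum(dmcs$direction == "hypo"), nrow(dmrs)))
}
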