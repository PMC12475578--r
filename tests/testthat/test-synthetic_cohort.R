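test_that("cohort simulation is deterministic and truth ids are unique", {
  cfg <- cohort_config(seed = 42, n_loci = 120L, n_genes = 200L,
                       n_panel_per_cat = 2L, n_meth_only_per_cat = 1L,
                       n_acc_only_per_cat = 1L, n_deg_per_cat = 2L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$meth$meth, b$meth$meth)
  expect_identical(a$peak_counts, b$peak_counts)
  expect_identical(a$gene_counts, b$gene_counts)
  expect_identical(a$sheet, b$sheet)
  expect_identical(lapply(a$tf_sites, `[[`, "start"),
                   lapply(b$tf_sites, `[[`, "start"))

  # every planted feature appears in exactly one category registry
  expect_false(anyDuplicated(a$truth$meth_effects$locus) > 0)
  expect_false(anyDuplicated(a$truth$acc_effects$locus) > 0)
  expect_false(anyDuplicated(a$truth$gene_effects$gene) > 0)
})

test_that("methylation counts hit the configured coverage and planted deltas", {
  cfg <- cohort_config(seed = 8, n_loci = 2000L,
                       n_panel_per_cat = 0L, n_meth_only_per_cat = 25L,
                       n_acc_only_per_cat = 0L, n_deg_per_cat = 0L)
  sim <- simulate_methylation(cfg)
  # mean total reads within 2% of 25.8 over 10^4 sites
  expect_lt(abs(mean(sim$meth$total) - 25.8) / 25.8, 0.02)

  sheet <- sim$sheet
  iac <- sheet$sample_id[sheet$stage == "IAC"]
  ctl <- sheet$sample_id[sheet$stage == "CTL"]
  lvl <- sim$meth$meth / sim$meth$total
  eff <- sim$truth$meth_effects
  hypo_iac <- eff$locus[eff$onset == "IAC" & eff$direction == "hypo"]
  layout <- cohort_layout(cfg)
  in_eff <- layout$cpgs$locus %in% hypo_iac
  # empirical IAC - CTL difference within +-0.05 of the planted -0.4
  d <- mean(lvl[in_eff, iac]) - mean(lvl[in_eff, ctl])
  expect_lt(abs(d - (-0.4)), 0.05)
  # null sites: group means differ only by sampling noise
  d0 <- mean(lvl[!in_eff, iac]) - mean(lvl[!in_eff, ctl])
  expect_lt(abs(d0), 0.05)
})

test_that("count simulation reproduces planted fold changes and the Poisson limit", {
  cfg <- cohort_config(seed = 5, n_loci = 600L, nb_mean = 100,
                       nb_mean_spread = 0, acc_lfc = 3,
                       n_panel_per_cat = 0L, n_meth_only_per_cat = 0L,
                       n_acc_only_per_cat = 30L, n_deg_per_cat = 0L,
                       n_per_stage = c(CTL = 25L, AIS = 5L, MIA = 5L, IAC = 25L))
  pk <- simulate_counts(cfg, "peaks")
  norm <- sweep(pk$counts, 2, pk$size_factors, "/")
  sheet <- pk$sheet
  eff <- cohort_layout(cfg)$truth$acc_effects
  hyper_iac <- eff$peak_id[eff$onset == "IAC" & eff$direction == "hyper"]
  ratio <- rowMeans(norm[hyper_iac, sheet$stage == "IAC"]) /
    rowMeans(norm[hyper_iac, sheet$stage == "CTL"])
  expect_lt(abs(mean(ratio) - 8) / 8, 0.15)
  # null features: group ratio ~ 1
  null_ids <- setdiff(rownames(norm), eff$peak_id)
  r0 <- mean(rowMeans(norm[null_ids, sheet$stage == "IAC"]) /
               rowMeans(norm[null_ids, sheet$stage == "CTL"]))
  expect_lt(abs(r0 - 1), 0.1)
  expect_equal(unname(exp(mean(log(pk$size_factors)))), 1)

  # dispersion -> 0 approaches the Poisson variance/mean limit
  cfg0 <- cohort_config(seed = 5, n_loci = 2000L, nb_mean = 100,
                        nb_mean_spread = 0, nb_dispersion = 1e-6,
                        size_factor_sd = 0,
                        n_panel_per_cat = 0L, n_meth_only_per_cat = 0L,
                        n_acc_only_per_cat = 0L, n_deg_per_cat = 0L)
  pk0 <- simulate_counts(cfg0, "peaks")
  vm <- apply(pk0$counts, 1, var) / rowMeans(pk0$counts)
  expect_lt(abs(mean(vm) - 1), 0.05)
})

test_that("TF site sets hit the configured sharing structure", {
  # within-cluster fraction 1 -> identical site sets; between 0 -> disjoint
  cfg1 <- cohort_config(seed = 2, tf_within_jaccard = 1,
                        tf_between_jaccard = 0,
                        tf_clusters = list(c1 = c("A", "B"), c2 = c("C", "D")))
  s1 <- simulate_sites(cfg1)
  key <- function(x) paste(x$chrom, x$start)
  expect_identical(key(s1$sites$A), key(s1$sites$B))
  expect_length(intersect(key(s1$sites$A), key(s1$sites$C)), 0)

  # configured within-cluster Jaccard ~ 0.6 at locus occupancy level
  cfg2 <- cohort_config(seed = 3, tf_within_jaccard = 0.6, n_loci = 800L,
                        n_panel_per_cat = 20L, n_acc_only_per_cat = 20L)
  coh <- simulate_cohort(cfg2)
  dar_iv <- coh$peaks[coh$peaks$locus %in% coh$truth$acc_effects$locus,
                      c("chrom", "start", "end")]
  cm <- coloc_matrix(coh$tf_sites, dar_iv)
  lab <- coh$truth$tf_cluster_labels[rownames(cm)]
  within <- outer(lab, lab, "==") & !diag(TRUE, nrow(cm))
  expect_lt(abs(mean(cm[within]) - 0.6), 0.1)
})

test_that("survival coupling has the planted sign and the null is flat", {
  meth <- stats::setNames(seq(0.3, 0.7, length.out = 40),
                          sprintf("S%02d", 1:40))
  # strong positive link: low methylation accumulates more events
  cfg <- cohort_config(seed = 10, survival_hazard_link = 8,
                       baseline_hazard = 0.5)
  n_low <- n_high <- 0
  for (s in 1:30) {
    cfg$seed <- 10 + s
    sv <- simulate_survival(cfg, meth)
    low <- names(meth)[meth <= median(meth)]
    n_low <- n_low + sum(sv$event[sv$sample_id %in% low])
    n_high <- n_high + sum(sv$event[!sv$sample_id %in% low])
  }
  expect_gt(n_low, n_high * 1.5)

  # zero link: event counts balance
  cfg0 <- cohort_config(seed = 20, survival_hazard_link = 0,
                        baseline_hazard = 0.05)
  n_low <- n_high <- 0
  for (s in 1:30) {
    cfg0$seed <- 20 + s
    sv <- simulate_survival(cfg0, meth)
    low <- names(meth)[meth <= median(meth)]
    n_low <- n_low + sum(sv$event[sv$sample_id %in% low])
    n_high <- n_high + sum(sv$event[!sv$sample_id %in% low])
  }
  expect_lt(abs(n_low - n_high) / (n_low + n_high), 0.2)
})
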