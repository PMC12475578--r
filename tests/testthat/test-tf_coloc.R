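mk_regions <- function(n, width = 100, gap = 1000) {
  start <- (seq_len(n) - 1) * gap
  iv <- intervals(rep("chr1", n), start, start + width)
  iv
}

sites_in <- function(regions, idx) {
  intervals(regions$chrom[idx], regions$start[idx] + 10,
            regions$start[idx] + 20)
}

test_that("site enrichment equals the exact hypergeometric tail", {
  bg <- mk_regions(100)
  targets <- bg[1:20, ]
  # sites hitting all targets and half the background
  sites <- sites_in(bg, c(1:20, 21:50))
  e <- site_enrichment(sites, targets, bg)
  expect_equal(e$fold, (20 / 20) / (50 / 100))
  expect_equal(e$p_value, brute_hyper_upper(20, 50, 100, 20))

  # no target hits
  e0 <- site_enrichment(sites_in(bg, 30:40), targets, bg)
  expect_equal(e0$fold, 0)
  # targets = background: fold 1
  e1 <- site_enrichment(sites_in(bg, 1:30), bg, bg)
  expect_equal(e1$fold, 1)
  # randomized agreement
  set.seed(17)
  for (rep in 1:10) {
    hit <- sample.int(100, sample(5:60, 1))
    e <- site_enrichment(sites_in(bg, hit), targets, bg)
    k_t <- sum(hit <= 20)
    expect_equal(e$p_value, brute_hyper_upper(k_t, length(hit), 100, 20))
  }
})

test_that("epi TF identification requires enrichment in both region classes", {
  bg <- mk_regions(200)
  srdmr_targets <- list(cat1 = bg[1:30, ])
  srdar_targets <- list(cat1 = bg[31:60, ])
  tf_sites <- list(
    both = sites_in(bg, c(1:25, 31:55)),   # enriched in both
    dmr_only = sites_in(bg, 1:25),         # only srDMRs
    neither = sites_in(bg, 100:120))
  e_dmr <- enrichment_table(tf_sites, srdmr_targets, bg)
  e_dar <- enrichment_table(tf_sites, srdar_targets, bg)
  expect_equal(identify_epi_tfs(e_dmr, e_dar, alpha = 0.05), "both")
  empty <- enrichment_table(tf_sites, list(), bg)
  expect_equal(identify_epi_tfs(empty, empty), character(0))
})

test_that("evidence filtering is an intersection and is monotone", {
  set.seed(18)
  sites <- mk_regions(50, width = 10, gap = 100)
  ev_all <- intervals("chr1", 0, 1e6)
  expect_equal(filter_sites_by_evidence(sites, list(ev_all)), sites,
               ignore_attr = TRUE)

  ev_a <- intervals("chr1", 0, 2000)
  ev_b <- intervals("chr1", 3000, 5000)
  expect_equal(nrow(filter_sites_by_evidence(sites, list(ev_a, ev_b))), 0)
  expect_warning(
    none <- filter_sites_by_evidence(sites, list(intervals(character(),
                                                           numeric(),
                                                           numeric()))),
    "removes all")
  expect_equal(nrow(none), 0)

  # sequential set-algebra oracle + monotonicity
  evs <- lapply(1:3, function(i) {
    s <- sort(sample.int(4900, 8)); intervals(rep("chr1", 8), s, s + 150)
  })
  kept_prev <- nrow(sites)
  for (k in 1:3) {
    got <- filter_sites_by_evidence(sites, evs[1:k])
    want <- sites
    for (e in evs[1:k]) {
      hit <- brute_intersect(want, e)
      want <- want[sort(unique(hit$a_idx)), , drop = FALSE]
    }
    expect_equal(got$start, want$start)
    expect_lte(nrow(got), kept_prev)
    kept_prev <- nrow(got)
  }
})

test_that("co-localization matrices are symmetric with unit diagonal and match enumeration", {
  regions <- mk_regions(40)
  tfs <- list(A = sites_in(regions, 1:20), B = sites_in(regions, 11:30),
              C = sites_in(regions, 35:40))
  cm <- coloc_matrix(tfs, regions)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), c(1, 1, 1))
  expect_equal(cm["A", "B"], 10 / 30)   # direct set enumeration
  expect_equal(cm["A", "C"], 0)
  expect_equal(coloc_matrix(list(A = tfs$A, A2 = tfs$A), regions)["A", "A2"],
               1)
  # TF with no sites in context: flagged absent
  cm2 <- coloc_matrix(c(tfs, list(D = sites_in(regions, 1)[0, ])), regions)
  expect_true(all(is.na(cm2["D", ])))

  rc <- ratio_change(cm, cm)
  expect_true(all(rc[is.finite(rc)] == 1))
  expect_equal(ratio_change(matrix(0.6, 1, 1, dimnames = list("A", "A")),
                            matrix(0.3, 1, 1, dimnames = list("A", "A")))[1, 1],
               2)
})

test_that("block-structured sites cluster back to the planted groups", {
  cfg <- cohort_config(seed = 19, tf_within_jaccard = 0.8,
                       tf_between_jaccard = 0.1)
  coh <- simulate_cohort(cfg)
  dar_iv <- coh$peaks[coh$peaks$locus %in% coh$truth$acc_effects$locus,
                      c("chrom", "start", "end")]
  cm <- coloc_matrix(coh$tf_sites, dar_iv)
  labels <- cluster_tfs(cm, k = 3)
  truth <- coh$truth$tf_cluster_labels[names(labels)]
  expect_equal(adjusted_rand(labels, truth), 1)

  # permuting the TF input order leaves the partition unchanged
  perm <- sample(length(coh$tf_sites))
  labels2 <- cluster_tfs(coloc_matrix(coh$tf_sites[perm], dar_iv), k = 3)
  expect_equal(adjusted_rand(labels2[names(labels)], labels), 1)

  expect_equal(as.integer(sort(table(cluster_tfs(cm, k = nrow(cm))))),
               rep(1L, nrow(cm)))
  expect_error(cluster_tfs(cm, k = 50), "exceeds")
})
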