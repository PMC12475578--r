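test_that("credible difference matches the Monte Carlo posterior oracle", {
  # identical groups: interval spans zero
  expect_equal(credible_difference(c(5, 10), c(5, 10)), 0)

  # saturated vs unmethylated: compare with 10^6-draw posterior sampling
  v <- credible_difference(c(30, 30), c(0, 30))
  set.seed(1)
  draws <- rbeta(1e6, 30.5, 0.5) - rbeta(1e6, 0.5, 30.5)
  mc <- unname(quantile(draws, 0.025))
  expect_gt(v, 0.20)
  expect_lt(abs(v - mc), 0.002)

  # a moderate case, against the same oracle
  v2 <- credible_difference(c(40, 60), c(20, 60))
  set.seed(2)
  draws2 <- rbeta(1e6, 40.5, 20.5) - rbeta(1e6, 20.5, 40.5)
  expect_lt(abs(v2 - unname(quantile(draws2, 0.025))), 0.003)
})

test_that("credible difference is antisymmetric, bounded by the raw difference, and consistent at depth", {
  set.seed(7)
  for (i in 1:25) {
    t1 <- sample(5:200, 1); t2 <- sample(5:200, 1)
    m1 <- rbinom(1, t1, runif(1)); m2 <- rbinom(1, t2, runif(1))
    v <- credible_difference(c(m1, t1), c(m2, t2))
    expect_identical(v, -credible_difference(c(m2, t2), c(m1, t1)))
    raw <- m1 / t1 - m2 / t2
    expect_lte(abs(v), abs(raw) + 1e-12)
  }
  # convergence to the raw difference at pooled depth 1e5
  deep <- credible_difference(c(65000, 1e5), c(35000, 1e5))
  expect_lt(abs(deep - 0.3), 0.01)
})

test_that("DMC calling respects the strict threshold and skips uncovered sites", {
  # two sites: one strong effect, one moderate below threshold after
  # credible shrinkage
  tracks <- list(
    case = data.frame(chrom = "chr1", start = c(100, 200), end = c(101, 201),
                      methylated = c(95, 30), total = c(100, 100)),
    ctl = data.frame(chrom = "chr1", start = c(100, 200), end = c(101, 201),
                     methylated = c(5, 8), total = c(100, 100)))
  mm <- meth_matrix(tracks)
  d <- call_dmcs(mm, "case", "ctl")
  expect_equal(d$start, 100)
  expect_equal(d$direction, "hyper")
  expect_gte(abs(d$cdif), 0.20)

  # sub-threshold credible difference is not emitted even if raw passes
  raw2 <- 30 / 100 - 8 / 100
  expect_gt(raw2, 0.20)
  expect_lt(abs(credible_difference(c(30, 100), c(8, 100))), 0.20)

  # zero coverage in one group: site skipped
  tracks$ctl$total[1] <- 0; tracks$ctl$methylated[1] <- 0
  mm2 <- meth_matrix(tracks)
  expect_false(100 %in% call_dmcs(mm2, "case", "ctl")$start)
})

test_that("DMR merging reproduces the spec geometry and the run-scan oracle", {
  dmcs <- data.frame(chrom = "chr1", start = c(100, 250, 400),
                     direction = "hyper", stringsAsFactors = FALSE)
  d <- merge_dmcs_to_dmrs(dmcs)
  expect_equal(d$start, 100)
  expect_equal(d$end, 401)
  expect_equal(d$n_dmcs, 3L)

  expect_equal(nrow(merge_dmcs_to_dmrs(dmcs[1:2, ])), 0)
  expect_error(merge_dmcs_to_dmrs(dmcs[c(2, 1, 3), ]), "sorted")

  for (seed in 1:6) {
    set.seed(seed)
    n <- 500
    dm <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(20000, n),
      direction = sample(c("hyper", "hypo"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    dm <- dm[!duplicated(dm[c("chrom", "start")]), ]
    dm <- dm[order(dm$chrom, dm$start), ]
    got <- merge_dmcs_to_dmrs(dm)
    want <- brute_dmrs(dm)
    expect_equal(got[, c("chrom", "start", "end", "n_dmcs", "direction")],
                 want, ignore_attr = TRUE)
    # DMRs of one direction never overlap each other
    for (dir in c("hyper", "hypo")) {
      g <- got[got$direction == dir, ]
      if (nrow(g) > 1) {
        hit <- intersect_intervals(g, g)
        expect_true(all(hit$a_idx == hit$b_idx))
      }
    }
  }
})

test_that("region methylation is read-weighted with absent values for empty regions", {
  tracks <- list(s1 = data.frame(chrom = "chr1", start = c(10, 20),
                                 end = c(11, 21),
                                 methylated = c(5, 0), total = c(10, 10)))
  mm <- meth_matrix(tracks)
  regions <- intervals(c("chr1", "chr1", "chr2"), c(0, 15, 0),
                       c(30, 30, 50))
  lvl <- region_methylation(mm, regions)
  expect_equal(unname(lvl[1, 1]), 5 / 20)  # pooled reads, not mean of ratios
  expect_equal(unname(lvl[2, 1]), 0)
  expect_true(is.na(lvl[3, 1]))

  # random fixture vs direct summation
  mm2 <- toy_meth(n_sites = 60, samples = c("a", "b", "c"), seed = 9)
  set.seed(10)
  regs <- random_intervals(25, chroms = "chr1", span = 9000, max_width = 800)
  got <- region_methylation(mm2, regs)
  for (i in seq_len(nrow(regs))) {
    inr <- mm2$sites$start >= regs$start[i] & mm2$sites$start < regs$end[i]
    for (s in 1:3) {
      tot <- sum(mm2$total[inr, s])
      want <- if (tot > 0) sum(mm2$meth[inr, s]) / tot else NA_real_
      expect_equal(unname(got[i, s]), want)
    }
  }
})

test_that("anchored profiles are flat under uniform methylation and mirror under strand flip", {
  start <- seq(0, 9999, by = 37)
  tracks <- list(s = data.frame(chrom = "chr1", start = start,
                                end = start + 1,
                                methylated = 8, total = 10))
  mm <- meth_matrix(tracks)
  anchors <- intervals("chr1", 5000, 5001, strand = "+")
  prof <- anchored_profile(mm, anchors, flank = 2000, bin_width = 200)
  expect_true(all(abs(prof$level - 0.8) < 1e-12, na.rm = TRUE))

  # asymmetric fixture: minus-strand anchor mirrors the plus-strand profile
  tracks2 <- list(s = data.frame(
    chrom = "chr1", start = c(4850, 5650), end = c(4851, 5651),
    methylated = c(1, 9), total = c(10, 10)))
  mm2 <- meth_matrix(tracks2)
  plus <- anchored_profile(mm2, intervals("chr1", 5000, 5001, strand = "+"),
                           flank = 1000, bin_width = 100)
  minus <- anchored_profile(mm2, intervals("chr1", 5000, 5001, strand = "-"),
                            flank = 1000, bin_width = 100)
  expect_equal(plus$level, rev(minus$level))
})
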