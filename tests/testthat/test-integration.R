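test_that("Kendall tau matches the all-pairs counting oracle, with ties", {
  x <- 1:6
  expect_equal(kendall_tau(x, x)$tau, 1)
  expect_equal(kendall_tau(x, rev(x))$tau, -1)
  expect_equal(kendall_tau(x, rep(1, 6))$tau, NA_real_)
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:5, n, TRUE)  # heavy ties
    y <- sample(1:5, n, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_tau(x, y)$tau, brute_kendall_tau_b(x, y),
                 tolerance = 1e-12)
  }
  # invariant under strictly monotone transforms
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(kendall_tau(exp(x), y^3 + 5 * y)$tau,
               kendall_tau(x, y)$tau)
})

test_that("Pearson r matches the covariance-formula oracle", {
  expect_equal(pearson_r(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))$r, 1)
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(pearson_r(x, y)$r, brute_pearson(x, y), tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(pearson_r(2 * x + 3, x)$r, 1)
})

test_that("peak correlation classes recover planted coupling and stay nominal under the null", {
  sim <- simulate_coupled_peaks(300, 20, coupling = -1, noise_sd = 0.05,
                                seed = 6)
  cls <- classify_peak_correlations(sim$acc, sim$meth)
  expect_gte(mean(cls$class == "negative"), 0.95)

  null <- simulate_coupled_peaks(800, 20, coupling = 0, noise_sd = 1,
                                 seed = 7)
  cls0 <- classify_peak_correlations(null$acc, null$meth)
  expect_gt(mean(cls0$class == "none"), 0.92)
  expect_lt(mean(cls0$class == "none"), 0.98)

  # constant accessibility is never classified
  acc <- matrix(1, 2, 10); meth <- matrix(runif(20), 2, 10)
  rownames(acc) <- rownames(meth) <- c("p1", "p2")
  expect_true(all(classify_peak_correlations(acc, meth)$class == "none"))
})

test_that("sample-level subsampled correlation behaves like a sampling estimator", {
  sim <- simulate_coupled_peaks(400, 1, coupling = -1, noise_sd = 0.1,
                                seed = 8)
  acc <- sim$acc[, 1]; meth <- sim$meth[, 1]
  # subsampling everything leaves no sampling variability
  all_in <- sample_level_correlation(acc, meth, n_subsample = 400,
                                     n_repeats = 10, seed = 1)
  expect_equal(all_in$sd, 0)
  expect_lt(all_in$mean, -0.8)

  r1 <- sample_level_correlation(acc, meth, n_subsample = 100,
                                 n_repeats = 50, seed = 1)
  r2 <- sample_level_correlation(acc, meth, n_subsample = 100,
                                 n_repeats = 50, seed = 2)
  expect_lt(abs(r1$mean - r2$mean), 3 * r1$sd / sqrt(50) + 3 * r2$sd / sqrt(50))
  expect_error(sample_level_correlation(acc[1:2], meth[1:2]), "3 usable")
})

test_that("panel construction equals the interval-intersection oracle", {
  mm <- toy_meth(n_sites = 80, samples = c("a", "b", "c", "d"), seed = 12)
  set.seed(12)
  srdmrs <- random_intervals(30, chroms = "chr1", span = 9000,
                             max_width = 400)
  srdmrs$category <- sample(stage_categories(), 30, TRUE)
  srdars <- random_intervals(25, chroms = "chr1", span = 9000,
                             max_width = 400)
  srdars$category <- sample(stage_categories(), 25, TRUE)
  srdars$peak_id <- sprintf("pk%02d", seq_len(25))
  acc <- matrix(rpois(25 * 4, 60) + 1L, 25, 4,
                dimnames = list(srdars$peak_id, c("a", "b", "c", "d")))
  panel <- suppressWarnings(build_panel(srdmrs, srdars, mm, acc))
  want <- brute_intersect(srdmrs, srdars)
  expect_equal(nrow(panel$pairs), nrow(want))
  expect_equal(paste(panel$pairs$srdmr_start, panel$pairs$srdar_start),
               paste(srdmrs$start[want$a_idx], srdars$start[want$b_idx]))

  # disjoint sets give an empty panel with a warning
  far <- srdars; far$start <- far$start + 1e6; far$end <- far$end + 1e6
  expect_warning(p0 <- build_panel(srdmrs, far, mm, acc), "empty panel")
  expect_equal(nrow(p0$pairs), 0)
})

test_that("panel metric correlations are exact on constructed fixtures", {
  mm <- toy_meth(n_sites = 60, samples = c("a", "b", "c"), seed = 14)
  set.seed(14)
  # disjoint regions so each srDMR pairs only with its own srDAR
  starts <- seq(0, by = 500, length.out = 20)
  srdmrs <- intervals(rep("chr1", 20), starts, starts + 300)
  srdmrs$category <- "hyper-IAC"
  srdars <- srdmrs  # identical regions: srDMR and srDAR methylation equal
  srdars$peak_id <- sprintf("pk%02d", 1:20)
  acc <- matrix(rpois(60, 50) + 1L, 20, 3,
                dimnames = list(srdars$peak_id, c("a", "b", "c")))
  panel <- build_panel(srdmrs, srdars, mm, acc)
  mc <- metric_correlations(panel)
  expect_true(all(abs(mc$r_mm - 1) < 1e-12))
  # r_da equals a direct Pearson on the metric columns
  for (i in seq_len(nrow(mc))) {
    s <- mc$sample[i]
    ok <- is.finite(panel$srdar_meth[, s]) & is.finite(panel$srdar_acc[, s])
    expect_equal(mc$r_da[i],
                 brute_pearson(panel$srdar_meth[ok, s],
                               panel$srdar_acc[ok, s]))
  }
})

test_that("co-expression classes follow the sign of r at p < 0.05", {
  set.seed(15)
  tf <- matrix(rnorm(2 * 12), 2, 12, dimnames = list(c("TFa", "TFb"), NULL))
  genes <- rbind(g1 = tf["TFa", ],                      # identical: positive
                 g2 = -tf["TFa", ] + rnorm(12, 0, 0.1), # inverted: negative
                 g3 = rnorm(12))                        # independent
  colnames(genes) <- colnames(tf) <- paste0("s", 1:12)
  cx <- coexpression(tf, genes)
  expect_equal(cx$class[cx$tf == "TFa" & cx$gene == "g1"], "positive")
  expect_equal(cx$r[cx$tf == "TFa" & cx$gene == "g1"], 1)
  expect_equal(cx$class[cx$tf == "TFa" & cx$gene == "g2"], "negative")
  const <- matrix(1, 1, 12, dimnames = list("gc", paste0("s", 1:12)))
  expect_equal(coexpression(tf, const)$class, c("none", "none"))
})
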