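#' Methylation-accessibility integration and co-expression
#'
#' Kendall correlation of peak accessibility with peak methylation across
#' samples, per-sample correlations estimated by repeated subsampling of
#' peaks, the overlapping srDMR/srDAR region panel with its three
#' per-sample metrics (srDMR methylation, srDAR methylation, srDAR
#' accessibility), and Pearson co-expression of TF-gene pairs.
#'
#' @name integration
NULL

#' Kendall rank correlation (tau-b) with p-value
#'
#' Tie-corrected tau-b; p-value from [stats::cor.test()] (exact enumeration
#' for small untied samples, normal approximation otherwise).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(tau, p_value); tau is NA (and p 1) for constant input.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(tau = NA_real_, p_value = 1))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Pearson correlation with p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(r, p_value); r is NA (and p 1) for constant input.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = 1))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

correlation_class <- function(stat, p, p_threshold) {
  if (is.na(stat) || p >= p_threshold) "none"
  else if (stat > 0) "positive" else "negative"
}

#' Classify peak methylation-accessibility correlations
#'
#' Per peak, Kendall tau across samples between normalized accessibility and
#' peak methylation; classes by the sign of tau at p below the threshold.
#'
#' @param acc peak x sample normalized accessibility matrix.
#' @param meth_in_peak peak x sample methylation level matrix (same
#'   dimensions and order).
#' @param p_threshold two-sided significance cutoff (default 0.05).
#' @return data.frame: feature, tau, p_value, class
#'   (positive/negative/none). Peaks without usable methylation (all NA or
#'   constant) are class "none" with tau NA.
#' @export
classify_peak_correlations <- function(acc, meth_in_peak, p_threshold = 0.05) {
  stopifnot(identical(dim(acc), dim(meth_in_peak)))
  res <- lapply(seq_len(nrow(acc)), function(i) {
    usable <- sum(is.finite(acc[i, ]) & is.finite(meth_in_peak[i, ]))
    if (usable < 3) return(list(tau = NA_real_, p_value = 1))
    kendall_tau(acc[i, ], meth_in_peak[i, ])
  })
  tau <- vapply(res, `[[`, numeric(1), "tau")
  p <- vapply(res, `[[`, numeric(1), "p_value")
  data.frame(feature = rownames(acc), tau = tau, p_value = p,
             class = mapply(correlation_class, tau, p,
                            MoreArgs = list(p_threshold = p_threshold)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Within-sample methylation-accessibility correlation by subsampling
#'
#' Repeatedly draws peaks without replacement and computes Kendall tau
#' across peaks between one sample's accessibility and methylation values;
#' reports the mean and SD over repeats.
#'
#' @param acc_sample,meth_sample numeric vectors over peaks for one sample.
#' @param n_subsample peaks per draw (default 2000, capped at the usable
#'   peak count).
#' @param n_repeats number of draws (default 100).
#' @param seed RNG seed.
#' @return list(mean, sd, n_usable).
#' @export
sample_level_correlation <- function(acc_sample, meth_sample,
                                     n_subsample = 2000, n_repeats = 100,
                                     seed = 1L) {
  ok <- which(is.finite(acc_sample) & is.finite(meth_sample))
  if (length(ok) < 3) stop("fewer than 3 usable peaks")
  n_subsample <- min(n_subsample, length(ok))
  set.seed(seed)
  taus <- vapply(seq_len(n_repeats), function(r) {
    idx <- sample(ok, n_subsample)
    stats::cor(acc_sample[idx], meth_sample[idx], method = "kendall")
  }, numeric(1))
  list(mean = mean(taus), sd = stats::sd(taus), n_usable = length(ok))
}

#' Build the srDMR/srDAR overlap panel
#'
#' One record per overlapping (srDMR, srDAR) pair, each carrying three
#' per-sample metric vectors: srDMR methylation, srDAR methylation and
#' size-factor-normalized srDAR accessibility. An srDAR overlapping several
#' srDMRs yields several records; `dedup_by_srdar` collapses to one record
#' per srDAR (first overlapping srDMR kept) for per-srDAR views.
#'
#' @param srdmrs srDMR data.frame (chrom, start, end, category).
#' @param srdars srDAR data.frame (chrom, start, end, category, peak_id
#'   matching `acc` row names).
#' @param meth a [meth_matrix()].
#' @param acc peak x sample raw count matrix.
#' @param sf optional size factors for `acc` (computed when NULL).
#' @param dedup_by_srdar collapse to one record per srDAR.
#' @return list: `pairs` (data.frame of overlapping pair coordinates and
#'   categories), `srdmr_meth`, `srdar_meth`, `srdar_acc` (pair x sample
#'   metric matrices; accessibility is log2(normalized count + 1)).
#' @export
build_panel <- function(srdmrs, srdars, meth, acc, sf = NULL,
                        dedup_by_srdar = FALSE) {
  hits <- intersect_intervals(srdmrs, srdars)
  if (nrow(hits) == 0) {
    warning("no srDMR/srDAR overlaps; empty panel")
    return(list(pairs = data.frame(), srdmr_meth = NULL,
                srdar_meth = NULL, srdar_acc = NULL))
  }
  if (dedup_by_srdar) hits <- hits[!duplicated(hits$b_idx), , drop = FALSE]
  pairs <- data.frame(
    srdmr_chrom = srdmrs$chrom[hits$a_idx], srdmr_start = srdmrs$start[hits$a_idx],
    srdmr_end = srdmrs$end[hits$a_idx],
    srdmr_category = srdmrs$category[hits$a_idx],
    srdar_chrom = srdars$chrom[hits$b_idx], srdar_start = srdars$start[hits$b_idx],
    srdar_end = srdars$end[hits$b_idx],
    srdar_category = srdars$category[hits$b_idx],
    peak_id = srdars$peak_id[hits$b_idx],
    stringsAsFactors = FALSE)
  if (is.null(sf)) sf <- size_factors(acc)
  norm <- sweep(acc, 2, sf, "/")
  srdmr_meth <- region_methylation(meth, srdmrs[hits$a_idx, , drop = FALSE])
  srdar_meth <- region_methylation(meth, srdars[hits$b_idx, , drop = FALSE])
  srdar_acc <- log2(norm[pairs$peak_id, , drop = FALSE] + 1)
  rownames(srdmr_meth) <- rownames(srdar_meth) <- rownames(srdar_acc) <- NULL
  list(pairs = pairs, srdmr_meth = srdmr_meth, srdar_meth = srdar_meth,
       srdar_acc = srdar_acc)
}

#' Per-sample correlations among the three panel metrics
#'
#' For each sample, Pearson r (and p) across panel records for the three
#' metric pairs: srDMR methylation vs srDAR methylation, srDMR methylation
#' vs srDAR accessibility, srDAR methylation vs srDAR accessibility.
#'
#' @param panel result of [build_panel()].
#' @return data.frame, one row per sample: sample, then r and p for
#'   `mm` (meth-meth), `ma` (srDMR meth vs acc), `da` (srDAR meth vs acc).
#' @export
metric_correlations <- function(panel) {
  samples <- colnames(panel$srdmr_meth)
  one <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(list(r = NA_real_, p_value = NA_real_))
    pearson_r(x[ok], y[ok])
  }
  rows <- lapply(samples, function(s) {
    mm <- one(panel$srdmr_meth[, s], panel$srdar_meth[, s])
    ma <- one(panel$srdmr_meth[, s], panel$srdar_acc[, s])
    da <- one(panel$srdar_meth[, s], panel$srdar_acc[, s])
    data.frame(sample = s, r_mm = mm$r, p_mm = mm$p_value,
               r_ma = ma$r, p_ma = ma$p_value,
               r_da = da$r, p_da = da$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' TF-gene co-expression classification
#'
#' Pearson r for every (TF, gene) pair across shared samples; a pair is
#' co-expressed when p < `p_threshold`, classed by the sign of r.
#'
#' @param tf_expr TF x sample expression matrix.
#' @param gene_expr gene x sample expression matrix (same samples).
#' @param p_threshold co-expression cutoff (default 0.05).
#' @return data.frame: tf, gene, r, p_value, class.
#' @export
coexpression <- function(tf_expr, gene_expr, p_threshold = 0.05) {
  stopifnot(ncol(tf_expr) == ncol(gene_expr), ncol(tf_expr) >= 3)
  grid <- expand.grid(tf = rownames(tf_expr), gene = rownames(gene_expr),
                      stringsAsFactors = FALSE)
  res <- mapply(function(tf, g) {
    pr <- pearson_r(tf_expr[tf, ], gene_expr[g, ])
    c(pr$r, pr$p_value)
  }, grid$tf, grid$gene)
  grid$r <- res[1, ]
  grid$p_value <- res[2, ]
  grid$class <- mapply(correlation_class, grid$r, grid$p_value,
                       MoreArgs = list(p_threshold = p_threshold))
  grid
}
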