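#' Negative-binomial differential testing for peaks and genes
#'
#' One NB engine serves both differential accessibility (DAR) and
#' differential expression (DEG) calling: median-of-ratios size factors,
#' per-feature method-of-moments dispersion shrunk toward a log-linear
#' mean-dispersion trend, log2 fold changes of normalized group means with a
#' 0.5 pseudocount, and a Wald p-value from the NB variance model. DARs are
#' declared at |log2FC| > 2 and raw p < 0.001; DEGs at |log2FC| > 0.58 and
#' Benjamini-Hochberg adjusted p < 0.05 (all strict inequalities).
#'
#' @name diffcount
NULL

#' Median-of-ratios size factors
#'
#' Per-sample factor = median over features (nonzero in every sample) of the
#' ratio of the sample's count to the feature's geometric mean; factors are
#' rescaled to geometric mean 1. Falls back to total-count ratios (with a
#' warning) when no feature is nonzero in all samples.
#'
#' @param counts feature x sample count matrix.
#' @return named positive numeric vector, geometric mean 1.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  allnz <- rowSums(counts == 0) == 0
  if (!any(allnz)) {
    warning("no feature nonzero in all samples; using total-count ratios")
    sf <- colSums(counts)
  } else {
    sub <- counts[allnz, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sub / geo, 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# method-of-moments NB dispersion, shrunk 50/50 (log scale) toward a
# log-linear mean-dispersion trend; floor 1e-8
estimate_dispersion <- function(norm_counts, groups) {
  floor_disp <- 1e-8
  mu_overall <- rowMeans(norm_counts)
  within_var <- rep(0, nrow(norm_counts))
  dof <- 0
  for (g in unique(groups)) {
    sub <- norm_counts[, groups == g, drop = FALSE]
    ng <- ncol(sub)
    within_var <- within_var + apply(sub, 1, stats::var) * (ng - 1)
    dof <- dof + (ng - 1)
  }
  within_var <- within_var / dof
  raw <- pmax((within_var - mu_overall) / mu_overall^2, 0)
  use <- mu_overall > 0 & raw > 0 & is.finite(raw)
  if (sum(use) >= 10) {
    df <- data.frame(x = log(mu_overall[use]), y = log(raw[use]))
    fit <- stats::lm(y ~ x, data = df)
    trend <- exp(stats::predict(
      fit, newdata = data.frame(x = log(pmax(mu_overall, 1e-8)))))
  } else if (any(use)) {
    trend <- rep(exp(mean(log(raw[use]))), length(raw))
  } else {
    trend <- rep(floor_disp, length(raw))
  }
  disp <- 0.5 * raw + 0.5 * trend
  pmax(ifelse(is.finite(disp), disp, floor_disp), floor_disp)
}

#' NB Wald test between two sample groups
#'
#' @param counts feature x sample count matrix.
#' @param case_samples,ctl_samples sample id vectors (>= 2 each).
#' @param sf optional precomputed size factors (all samples of `counts`);
#'   computed by [size_factors()] when NULL.
#' @return data.frame per feature: feature, base_mean_case, base_mean_ctl
#'   (normalized means), log2fc (case vs control, pseudocount 0.5), p_value,
#'   q_value (BH), direction ("hyper"/up when log2fc > 0). All-zero features
#'   get log2fc 0, p 1 and are flagged in `all_zero`.
#' @export
nb_test <- function(counts, case_samples, ctl_samples, sf = NULL) {
  stopifnot(length(case_samples) >= 2, length(ctl_samples) >= 2)
  used <- c(case_samples, ctl_samples)
  if (!all(used %in% colnames(counts))) stop("unknown sample id")
  counts <- counts[, used, drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts) else sf <- sf[used]
  norm <- sweep(counts, 2, sf, "/")
  groups <- rep(c("case", "ctl"), c(length(case_samples), length(ctl_samples)))
  disp <- estimate_dispersion(norm, groups)

  cs <- norm[, groups == "case", drop = FALSE]
  ct <- norm[, groups == "ctl", drop = FALSE]
  m_case <- rowMeans(cs); m_ctl <- rowMeans(ct)
  log2fc <- log2((m_case + 0.5) / (m_ctl + 0.5))

  # delta-method variance of log2 group means under Var(K/s) = mu/s + a mu^2
  var_mean <- function(mu, cols) {
    s <- sf[cols]
    vapply(seq_along(mu), function(i)
      sum(mu[i] / s + disp[i] * mu[i]^2) / length(s)^2, numeric(1))
  }
  v_case <- var_mean(m_case + 0.5, which(groups == "case"))
  v_ctl <- var_mean(m_ctl + 0.5, which(groups == "ctl"))
  se_log2 <- sqrt(v_case / (m_case + 0.5)^2 + v_ctl / (m_ctl + 0.5)^2) / log(2)
  z <- log2fc / se_log2
  # moderated t reference: the dispersion entering the variance is
  # estimated (a normal reference is anticonservative at small n), but the
  # 50/50 shrinkage toward the trend contributes prior information worth
  # about the residual df again, so the reference df is doubled
  df_resid <- length(case_samples) + length(ctl_samples) - 2
  p <- 2 * stats::pt(-abs(z), df = 2 * df_resid)

  all_zero <- rowSums(counts) == 0
  log2fc[all_zero] <- 0
  p[all_zero] <- 1
  data.frame(feature = rownames(counts),
             base_mean_case = m_case, base_mean_ctl = m_ctl,
             log2fc = log2fc, p_value = p,
             q_value = bh_adjust(p),
             direction = ifelse(log2fc > 0, "hyper", "hypo"),
             all_zero = all_zero,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p p-value vector in `[0, 1]`.
#' @return BH step-up q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold a differential table into significant calls
#'
#' DAR mode uses raw p-values (|log2FC| > 2, p < 0.001); DEG mode uses BH
#' q-values (|log2FC| > 0.58, q < 0.05). Both comparisons are strict.
#'
#' @param results data.frame from [nb_test()].
#' @param lfc_threshold |log2FC| cutoff (strict >).
#' @param p_mode `"raw"` or `"adjusted"`.
#' @param p_threshold p (or q) cutoff (strict <).
#' @return subset of `results` rows that pass, with `direction` retained.
#' @export
call_differential <- function(results, lfc_threshold = 2,
                              p_mode = c("raw", "adjusted"),
                              p_threshold = 0.001) {
  p_mode <- match.arg(p_mode)
  stopifnot(lfc_threshold > 0, p_threshold > 0)
  pv <- if (p_mode == "raw") results$p_value else results$q_value
  keep <- abs(results$log2fc) > lfc_threshold & pv < p_threshold
  out <- results[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DAR calling thresholds
#' @param results [nb_test()] output for peaks.
#' @return significant differentially accessible peaks.
#' @export
call_dars <- function(results)
  call_differential(results, lfc_threshold = 2, p_mode = "raw",
                    p_threshold = 0.001)

#' DEG calling thresholds
#' @param results [nb_test()] output for genes.
#' @return significant differentially expressed genes.
#' @export
call_degs <- function(results)
  call_differential(results, lfc_threshold = 0.58, p_mode = "adjusted",
                    p_threshold = 0.05)
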