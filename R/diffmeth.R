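#' Credible-difference differential methylation
#'
#' DMCs are called from pooled per-group methylated/total read counts with a
#' beta-binomial (Beta posterior) model: each group's methylation level gets
#' a Beta(methylated + 0.5, unmethylated + 0.5) posterior (Jeffreys prior)
#' and the credible difference is the bound of the central credible interval
#' of (case - control) nearest zero — 0 when the interval spans zero. Sites
#' whose |credible difference| reaches the threshold (default 0.20) are DMCs;
#' runs of at least 3 same-direction DMCs with consecutive gaps of at most
#' 200 bp merge into DMRs.
#'
#' @name diffmeth
NULL

# P(X - Y <= d) for X ~ Beta(a1, b1), Y ~ Beta(a2, b2), by adaptive
# quadrature over the Y posterior. pbeta saturates outside [0, 1].
pdiff_beta <- function(d, a1, b1, a2, b2, rel.tol = 1e-7) {
  stats::integrate(function(y) stats::pbeta(y + d, a1, b1) *
                     stats::dbeta(y, a2, b2),
                   lower = 0, upper = 1, rel.tol = rel.tol,
                   stop.on.error = FALSE)$value
}

qdiff_beta <- function(p, a1, b1, a2, b2, tol = 1e-5) {
  stats::uniroot(function(d) pdiff_beta(d, a1, b1, a2, b2) - p,
                 lower = -1, upper = 1, tol = tol)$root
}

#' Signed credible methylation difference between two pooled groups
#'
#' @param case_counts,ctl_counts length-2 numeric vectors
#'   `(methylated, total)` of pooled within-group read counts; totals must
#'   be positive.
#' @param cred_level central credible level (default 0.95).
#' @return signed value in `[-1, 1]`: the bound of the central
#'   `cred_level` interval of (case level - control level) nearest zero, or
#'   0 when the interval spans zero. Antisymmetric under argument swap; its
#'   magnitude never exceeds the raw pooled level difference.
#' @export
credible_difference <- function(case_counts, ctl_counts, cred_level = 0.95) {
  stopifnot(length(case_counts) == 2, length(ctl_counts) == 2)
  if (case_counts[2] <= 0 || ctl_counts[2] <= 0)
    stop("credible_difference undefined: zero pooled total in a group")
  if (case_counts[1] < 0 || case_counts[1] > case_counts[2] ||
      ctl_counts[1] < 0 || ctl_counts[1] > ctl_counts[2])
    stop("methylated count outside [0, total]")
  raw <- case_counts[1] / case_counts[2] - ctl_counts[1] / ctl_counts[2]
  # compute in raw-positive orientation so antisymmetry is exact
  if (raw < 0) return(-credible_difference(ctl_counts, case_counts, cred_level))
  a1 <- case_counts[1] + 0.5; b1 <- case_counts[2] - case_counts[1] + 0.5
  a2 <- ctl_counts[1] + 0.5; b2 <- ctl_counts[2] - ctl_counts[1] + 0.5
  alpha <- (1 - cred_level) / 2
  lo <- qdiff_beta(alpha, a1, b1, a2, b2)
  if (lo > 0) return(min(lo, raw))
  hi <- qdiff_beta(1 - alpha, a1, b1, a2, b2)
  if (hi < 0) return(max(hi, -raw)) # only reachable by numeric noise at raw ~ 0
  0
}

pool_counts <- function(meth, samples) {
  cols <- match(samples, colnames(meth$meth))
  if (anyNA(cols)) stop("unknown sample id in group")
  list(meth = rowSums(meth$meth[, cols, drop = FALSE]),
       total = rowSums(meth$total[, cols, drop = FALSE]))
}

#' Call differentially methylated CpGs (DMCs)
#'
#' Reads are pooled across samples within each group before the Beta
#' posterior. Sites with zero pooled coverage in either group are skipped.
#' Because |credible difference| is bounded by the raw pooled difference,
#' sites with raw |difference| below the threshold are screened out without
#' quadrature.
#'
#' @param meth a [meth_matrix()].
#' @param case_samples,ctl_samples sample id vectors.
#' @param min_credible_dif DMC threshold on |credible difference|
#'   (default 0.20).
#' @param cred_level credible level (default 0.95).
#' @return data.frame of DMCs: chrom, start, end, cdif, direction
#'   (hyper iff cdif > 0), case_level, ctl_level; sorted by (chrom, start).
#' @export
call_dmcs <- function(meth, case_samples, ctl_samples,
                      min_credible_dif = 0.20, cred_level = 0.95) {
  case <- pool_counts(meth, case_samples)
  ctl <- pool_counts(meth, ctl_samples)
  usable <- case$total > 0 & ctl$total > 0
  if (!any(usable)) {
    warning("no sites with coverage in both groups")
    return(empty_dmcs())
  }
  case_lvl <- case$meth / case$total
  ctl_lvl <- ctl$meth / ctl$total
  raw <- case_lvl - ctl_lvl
  cand <- which(usable & abs(raw) >= min_credible_dif)
  if (length(cand) == 0) return(empty_dmcs())
  cdif <- vapply(cand, function(i)
    credible_difference(c(case$meth[i], case$total[i]),
                        c(ctl$meth[i], ctl$total[i]), cred_level),
    numeric(1))
  keep <- abs(cdif) >= min_credible_dif
  idx <- cand[keep]
  out <- data.frame(
    chrom = meth$sites$chrom[idx], start = meth$sites$start[idx],
    end = meth$sites$end[idx], cdif = cdif[keep],
    direction = ifelse(cdif[keep] > 0, "hyper", "hypo"),
    case_level = case_lvl[idx], ctl_level = ctl_lvl[idx],
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

empty_dmcs <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             cdif = numeric(), direction = character(),
             case_level = numeric(), ctl_level = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge DMCs into DMRs
#'
#' Per chromosome and per direction (hyper runs never merge with hypo runs),
#' maximal runs of DMCs whose consecutive start-coordinate gaps are at most
#' `max_gap` become candidate regions; candidates with at least `min_dmcs`
#' members are emitted. The DMR span is
#' `[first member start, last member start + 1)`.
#'
#' @param dmcs DMC data.frame (chrom, start, direction, ...), sorted by
#'   (chrom, start); unsorted input is an error, never silently sorted.
#' @param min_dmcs minimum member DMCs (default 3).
#' @param max_gap maximum distance between consecutive member DMC starts in
#'   bp (default 200).
#' @return data.frame of DMRs: chrom, start, end, n_dmcs, direction,
#'   member_starts (comma-separated).
#' @export
merge_dmcs_to_dmrs <- function(dmcs, min_dmcs = 3, max_gap = 200) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_dmcs = integer(), direction = character(),
                      member_starts = character(), stringsAsFactors = FALSE)
  if (nrow(dmcs) == 0) return(empty)
  if (is.unsorted(order(dmcs$chrom, dmcs$start)) ||
      any(diff(order(dmcs$chrom, dmcs$start)) != 1))
    stop("DMCs must be sorted by (chrom, start)")
  out <- empty
  for (grp in split(dmcs, list(dmcs$chrom, dmcs$direction), drop = TRUE)) {
    pos <- grp$start
    run_break <- c(TRUE, diff(pos) > max_gap)
    run_id <- cumsum(run_break)
    for (run in split(pos, run_id)) {
      if (length(run) >= min_dmcs)
        out <- rbind(out, data.frame(
          chrom = grp$chrom[1], start = run[1], end = run[length(run)] + 1,
          n_dmcs = length(run), direction = grp$direction[1],
          member_starts = paste(run, collapse = ","),
          stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Region-level methylation across samples
#'
#' Level(region, sample) = sum(methylated) / sum(total) over the region's
#' member CpGs (read-weighted, not a mean of ratios). Regions with no CpGs,
#' or zero total coverage for a sample, yield NA (absent), never 0.
#'
#' @param meth a [meth_matrix()].
#' @param regions interval data.frame.
#' @return region x sample numeric matrix of levels in `[0, 1]`; row names
#'   are `chrom:start-end`.
#' @export
region_methylation <- function(meth, regions) {
  hits <- intersect_intervals(regions, meth$sites)
  n_samp <- ncol(meth$meth)
  msum <- matrix(0, nrow(regions), n_samp)
  tsum <- matrix(0, nrow(regions), n_samp)
  if (nrow(hits) > 0) {
    by_region_m <- rowsum(meth$meth[hits$b_idx, , drop = FALSE], hits$a_idx)
    by_region_t <- rowsum(meth$total[hits$b_idx, , drop = FALSE], hits$a_idx)
    rows <- as.integer(rownames(by_region_m))
    msum[rows, ] <- by_region_m
    tsum[rows, ] <- by_region_t
  }
  lvl <- ifelse(tsum > 0, msum / tsum, NA_real_)
  dimnames(lvl) <- list(sprintf("%s:%d-%d", regions$chrom, regions$start,
                                regions$end),
                        colnames(meth$meth))
  lvl
}

#' Anchored methylation profile
#'
#' Mean methylation level in signed-distance bins around anchor reference
#' points (the anchor interval start; mirrored for minus-strand anchors),
#' pooled over all anchors and the selected samples. Bins with no covered
#' CpG are NA.
#'
#' @param meth a [meth_matrix()].
#' @param anchors interval data.frame (strand used to orient distances).
#' @param flank half-window in bp (default 5000).
#' @param bin_width bin width in bp (default 100).
#' @param samples sample ids to pool (default all).
#' @return data.frame: bin_mid (signed distance), level.
#' @export
anchored_profile <- function(meth, anchors, flank = 5000, bin_width = 100,
                             samples = colnames(meth$meth)) {
  cols <- match(samples, colnames(meth$meth))
  breaks <- seq(-flank, flank, by = bin_width)
  acc_m <- numeric(length(breaks) - 1)
  acc_t <- numeric(length(breaks) - 1)
  for (i in seq_len(nrow(anchors))) {
    same <- meth$sites$chrom == anchors$chrom[i]
    if (!any(same)) next
    d <- meth$sites$start[same] - anchors$start[i]
    if (!is.null(anchors$strand) && anchors$strand[i] == "-") d <- -d
    inw <- d >= -flank & d < flank
    if (!any(inw)) next
    bin <- findInterval(d[inw], breaks, rightmost.closed = FALSE)
    m <- rowSums(meth$meth[which(same)[inw], cols, drop = FALSE])
    t <- rowSums(meth$total[which(same)[inw], cols, drop = FALSE])
    bm <- tapply(m, factor(bin, levels = seq_along(acc_m)), sum)
    bt <- tapply(t, factor(bin, levels = seq_along(acc_t)), sum)
    acc_m <- acc_m + ifelse(is.na(bm), 0, bm)
    acc_t <- acc_t + ifelse(is.na(bt), 0, bt)
  }
  data.frame(bin_mid = breaks[-length(breaks)] + bin_width / 2,
             level = ifelse(acc_t > 0, acc_m / acc_t, NA_real_))
}
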