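# Independent brute-force oracles. Each recomputes a quantity by the most
# direct route available (all-pairs scans, hand tabulation, Monte Carlo) so
# the package implementation is checked against a second derivation.

brute_intersect <- function(a, b) {
  out <- data.frame(a_idx = integer(), b_idx = integer(), overlap = integer())
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1)
      out <- rbind(out, data.frame(a_idx = i, b_idx = j,
                                   overlap = as.integer(ov)))
  }
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

# all maximal contiguous windows of same-direction DMCs with every
# consecutive gap <= max_gap and >= min_dmcs members
brute_dmrs <- function(dmcs, min_dmcs = 3, max_gap = 200) {
  out <- NULL
  for (ch in unique(dmcs$chrom)) for (dir in unique(dmcs$direction)) {
    pos <- sort(dmcs$start[dmcs$chrom == ch & dmcs$direction == dir])
    n <- length(pos)
    for (i in seq_len(n)) for (j in i:n) {
      if (j - i + 1 < min_dmcs) next
      gaps_ok <- all(diff(pos[i:j]) <= max_gap)
      left_max <- i == 1 || pos[i] - pos[i - 1] > max_gap
      right_max <- j == n || pos[j + 1] - pos[j] > max_gap
      if (gaps_ok && left_max && right_max)
        out <- rbind(out, data.frame(chrom = ch, start = pos[i],
                                     end = pos[j] + 1,
                                     n_dmcs = j - i + 1L, direction = dir,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

brute_kendall_tau_b <- function(x, y) {
  n <- length(x); conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

brute_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

brute_bh <- function(p) {
  m <- length(p); ord <- order(p)
  q <- numeric(m)
  q[ord[m]] <- p[ord[m]]
  for (k in (m - 1):1)
    q[ord[k]] <- min(p[ord[k]] * m / k, q[ord[k + 1]])
  pmin(q, 1)
}

brute_hyper_upper <- function(k, K, N, n) {
  # P(X >= k), X ~ Hypergeom(K successes in N, n drawn)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

brute_logrank <- function(time, event, group) {
  lv <- levels(factor(group))
  o1 <- e1 <- v1 <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lv[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v1
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small deterministic meth_matrix fixture built in code
toy_meth <- function(n_sites = 10, samples = c("a", "b"), seed = 1,
                     coverage = 20, level = 0.5) {
  set.seed(seed)
  start <- sort(sample.int(10000, n_sites))
  tracks <- lapply(samples, function(s) {
    total <- pmax(rpois(n_sites, coverage), 1)
    data.frame(chrom = "chr1", start = start, end = start + 1,
               methylated = rbinom(n_sites, total, level), total = total)
  })
  names(tracks) <- samples
  meth_matrix(tracks)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 5000,
                             max_width = 120) {
  start <- sample.int(span, n, replace = TRUE)
  intervals(sample(chroms, n, replace = TRUE), start,
            start + sample.int(max_width, n, replace = TRUE))
}
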