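#' TF binding-site enrichment and co-localization clustering
#'
#' Epigenetics-related TFs (epi TFs) are those whose motif sites are
#' enriched in both srDMRs and srDARs (hypergeometric region-containment
#' test, BH-corrected). Pairwise co-localization is the Jaccard of the
#' region sets each TF occupies, computed both inside srDARs and
#' genome-wide; average-linkage hierarchical clustering on 1 - proportion
#' groups the TFs into co-binding clusters (default k = 6).
#'
#' @name tf_coloc
NULL

regions_hit <- function(sites, regions) {
  hits <- intersect_intervals(regions, sites)
  unique(hits$a_idx)
}

#' Hypergeometric site enrichment of a TF in target regions
#'
#' Upper-tail hypergeometric p for the number of target regions containing
#' at least one site, drawing from the background region universe; fold =
#' target hit rate / background hit rate.
#'
#' @param sites TF site interval data.frame.
#' @param targets target region set (a subset of the background universe).
#' @param background background region universe.
#' @return list(fold, p_value, k_target, n_target, k_background,
#'   n_background). Zero background hits give fold Inf (or 0 with no target
#'   hits) and p 1.
#' @export
site_enrichment <- function(sites, targets, background) {
  n_t <- nrow(targets); n_b <- nrow(background)
  k_t <- length(regions_hit(sites, targets))
  k_b <- length(regions_hit(sites, background))
  if (k_b == 0) {
    return(list(fold = if (k_t == 0) 0 else Inf, p_value = 1,
                k_target = k_t, n_target = n_t,
                k_background = k_b, n_background = n_b))
  }
  fold <- (k_t / n_t) / (k_b / n_b)
  # P(X >= k_t), X ~ Hypergeom(hits k_b, misses n_b - k_b, drawn n_t)
  p <- stats::phyper(k_t - 1, k_b, n_b - k_b, n_t, lower.tail = FALSE)
  list(fold = fold, p_value = p, k_target = k_t, n_target = n_t,
       k_background = k_b, n_background = n_b)
}

#' Enrichment table for many TFs against per-category targets
#'
#' @param tf_sites named list of TF site interval data.frames.
#' @param target_sets named list of target region data.frames (e.g. the six
#'   srDMR categories).
#' @param background background region universe.
#' @return data.frame: tf, target_set, fold, p_value, q_value (BH within
#'   the whole table).
#' @export
enrichment_table <- function(tf_sites, target_sets, background) {
  rows <- list()
  for (tf in names(tf_sites)) {
    for (ts in names(target_sets)) {
      if (nrow(target_sets[[ts]]) == 0) next
      e <- site_enrichment(tf_sites[[tf]], target_sets[[ts]], background)
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf, target_set = ts, fold = e$fold, p_value = e$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(tf = character(),
                                      target_set = character(),
                                      fold = numeric(), p_value = numeric(),
                                      q_value = numeric()))
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Identify epi TFs
#'
#' TFs significantly enriched (BH q < alpha, fold > 1) in at least one
#' srDMR category AND at least one srDAR category.
#'
#' @param enrich_srdmrs,enrich_srdars [enrichment_table()] outputs over the
#'   same TF list.
#' @param alpha q-value cutoff (default 0.05).
#' @return sorted character vector of TF names.
#' @export
identify_epi_tfs <- function(enrich_srdmrs, enrich_srdars, alpha = 0.05) {
  sig <- function(tab)
    unique(tab$tf[tab$q_value < alpha & tab$fold > 1])
  sort(intersect(sig(enrich_srdmrs), sig(enrich_srdars)))
}

#' Filter sites by intersection of evidence tracks
#'
#' Keeps sites overlapping at least one interval in EVERY evidence list
#' (e.g. JUN ChIP and FOS ChIP and H3K27ac). Monotone: adding an evidence
#' track never adds sites; an empty evidence track removes everything
#' (with a warning).
#'
#' @param sites TF site interval data.frame.
#' @param evidence list of interval data.frames.
#' @return filtered site data.frame (row order preserved).
#' @export
filter_sites_by_evidence <- function(sites, evidence) {
  keep <- rep(TRUE, nrow(sites))
  for (ev in evidence) {
    if (nrow(ev) == 0) {
      warning("empty evidence track removes all sites")
      return(sites[integer(), , drop = FALSE])
    }
    hit <- intersect_intervals(sites, ev)
    keep <- keep & seq_len(nrow(sites)) %in% hit$a_idx
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise TF co-localization matrix
#'
#' Entry (i, j) is the Jaccard index of the sets of context regions that
#' contain at least one site of TF i and TF j respectively. Diagonal is 1
#' for TFs with any site in context; TFs with no site in context get NA
#' rows/columns.
#'
#' @param tf_sites named list of TF site interval data.frames (>= 2 TFs).
#' @param regions context region set (e.g. srDARs, or genome-wide bins).
#' @return symmetric TF x TF matrix of proportions in `[0, 1]`.
#' @export
coloc_matrix <- function(tf_sites, regions) {
  stopifnot(length(tf_sites) >= 2)
  tfs <- names(tf_sites)
  occ <- lapply(tf_sites, regions_hit, regions = regions)
  n <- length(tfs)
  m <- matrix(NA_real_, n, n, dimnames = list(tfs, tfs))
  for (i in seq_len(n)) {
    if (length(occ[[i]]) == 0) next
    for (j in seq_len(n)) {
      if (length(occ[[j]]) == 0) next
      m[i, j] <- length(intersect(occ[[i]], occ[[j]])) /
        length(union(occ[[i]], occ[[j]]))
    }
  }
  m
}

#' Ratio change of co-localization in srDARs vs genome-wide
#'
#' @param coloc_in_srdars,coloc_genomewide matched [coloc_matrix()] outputs.
#' @return elementwise ratio matrix; NA where the genome-wide proportion
#'   is 0 or undefined.
#' @export
ratio_change <- function(coloc_in_srdars, coloc_genomewide) {
  stopifnot(identical(dimnames(coloc_in_srdars), dimnames(coloc_genomewide)))
  out <- coloc_in_srdars / coloc_genomewide
  out[!is.finite(out)] <- NA_real_
  out
}

#' Cluster TFs by co-localization
#'
#' Average-linkage hierarchical clustering on distance 1 - proportion, cut
#' into k groups. TFs are ordered lexicographically before clustering so
#' the partition is invariant to input order.
#'
#' @param coloc symmetric [coloc_matrix()] with complete rows.
#' @param k number of clusters (default 6).
#' @param linkage hclust method (default "average").
#' @return named integer vector of cluster labels per TF.
#' @export
cluster_tfs <- function(coloc, k = 6, linkage = "average") {
  if (k > nrow(coloc)) stop("k exceeds number of TFs")
  if (any(is.na(coloc))) stop("co-localization matrix has absent rows")
  ord <- order(rownames(coloc))
  coloc <- coloc[ord, ord]
  d <- stats::as.dist(1 - coloc)
  hc <- stats::hclust(d, method = linkage)
  stats::cutree(hc, k = k)
}
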