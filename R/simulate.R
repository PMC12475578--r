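#' Synthetic four-stage multi-omic cohort with planted ground truth
#'
#' The generator emulates the data a stage-resolved epigenomic integration
#' study consumes: per-CpG beta-binomial methylation counts at a target mean
#' coverage, negative-binomial peak/gene counts, transcription-factor
#' motif-site sets with block co-localization structure, and survival times
#' coupled to panel methylation. Every planted effect is recorded in a truth
#' registry so downstream callers can be tested by parameter recovery.
#'
#' The genome layout is a single synthetic chromosome of regularly spaced
#' "loci": each locus carries five CpGs (50 bp apart, 200 bp span) and one
#' 300 bp accessibility peak covering them. A planted effect switches on at
#' its onset stage and persists through all later stages.
#'
#' @name synthetic_cohort
NULL

LOCUS_SPACING <- 3000L
CPGS_PER_LOCUS <- 5L

#' Cohort configuration
#'
#' @param n_per_stage named integer vector of samples per stage
#'   (CTL/AIS/MIA/IAC). The study cohort was 38/33/37/43; the desk-scale
#'   default is 10 per stage.
#' @param n_loci number of genomic loci (each = 5 CpGs + 1 peak).
#' @param n_genes number of genes in the expression matrix.
#' @param mean_coverage expected reads per CpG (Poisson, floored at 1);
#'   default 25.8.
#' @param baseline_meth baseline methylation level in `[0, 1]`.
#' @param meth_precision beta-binomial precision (larger = less biological
#'   overdispersion); default 30.
#' @param nb_mean baseline negative-binomial mean for peaks and genes.
#' @param nb_mean_spread lognormal sd of per-feature baseline means around
#'   `nb_mean` (0 = all features share the same mean).
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2).
#' @param size_factor_sd lognormal sd of per-sample library size factors.
#' @param n_panel_per_cat planted loci per (onset, direction) category that
#'   carry BOTH a methylation and an opposite-direction accessibility effect
#'   (the panel ground truth).
#' @param n_meth_only_per_cat planted methylation-only loci per category.
#' @param n_acc_only_per_cat planted accessibility-only loci per category.
#' @param n_deg_per_cat planted differentially expressed genes per category.
#' @param meth_delta planted methylation level shift (absolute), default 0.40
#'   (twice the 0.20 credible-difference calling threshold).
#' @param acc_lfc planted peak |log2 fold change|, default 4 (twice the
#'   DAR threshold of 2).
#' @param gene_lfc planted gene |log2 fold change|, default 1.16 (twice the
#'   DEG threshold of 0.58).
#' @param tf_clusters named list: cluster name -> character vector of TF
#'   names. NULL plants 3 clusters of 4 TFs.
#' @param tf_within_jaccard target Jaccard of locus occupancy for TFs in the
#'   same cluster, inside planted accessibility loci.
#' @param tf_between_jaccard target Jaccard across clusters (and genome-wide).
#' @param tf_loci_per_tf number of loci each TF occupies in each context.
#' @param survival_hazard_link coefficient coupling mean panel methylation to
#'   hazard; positive values make LOW methylation -> HIGH hazard.
#' @param baseline_hazard baseline event hazard (events per month).
#' @param max_follow_up administrative censoring horizon (months).
#' @param seed master seed; each modality draws from its own stream derived
#'   by a fixed offset.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_stage = c(CTL = 10L, AIS = 10L, MIA = 10L, IAC = 10L),
                          n_loci = 400L, n_genes = 1000L,
                          mean_coverage = 25.8, baseline_meth = 0.5,
                          meth_precision = 30,
                          nb_mean = 100, nb_mean_spread = 0.5,
                          nb_dispersion = 0.1, size_factor_sd = 0.15,
                          n_panel_per_cat = 8L, n_meth_only_per_cat = 5L,
                          n_acc_only_per_cat = 5L, n_deg_per_cat = 8L,
                          meth_delta = 0.40, acc_lfc = 4, gene_lfc = 1.16,
                          tf_clusters = NULL,
                          tf_within_jaccard = 0.8, tf_between_jaccard = 0.1,
                          tf_loci_per_tf = 60L,
                          survival_hazard_link = 4, baseline_hazard = 0.02,
                          max_follow_up = 60, seed = 1L) {
  stopifnot(all(names(n_per_stage) == STAGES), all(n_per_stage > 0),
            n_loci > 0, n_genes > 0, mean_coverage > 0,
            baseline_meth >= 0, baseline_meth <= 1,
            meth_precision > 0, nb_dispersion > 0)
  n_cat_loci <- 6L * (n_panel_per_cat + n_meth_only_per_cat + n_acc_only_per_cat)
  if (n_cat_loci > n_loci)
    stop("n_loci too small for the requested planted effects")
  if (is.null(tf_clusters))
    tf_clusters <- list(
      c1 = paste0("TF", 1:4), c2 = paste0("TF", 5:8), c3 = paste0("TF", 9:12))
  cfg <- list(n_per_stage = n_per_stage, n_loci = as.integer(n_loci),
              n_genes = as.integer(n_genes), mean_coverage = mean_coverage,
              baseline_meth = baseline_meth, meth_precision = meth_precision,
              nb_mean = nb_mean, nb_mean_spread = nb_mean_spread,
              nb_dispersion = nb_dispersion, size_factor_sd = size_factor_sd,
              n_panel_per_cat = n_panel_per_cat,
              n_meth_only_per_cat = n_meth_only_per_cat,
              n_acc_only_per_cat = n_acc_only_per_cat,
              n_deg_per_cat = n_deg_per_cat,
              meth_delta = meth_delta, acc_lfc = acc_lfc, gene_lfc = gene_lfc,
              tf_clusters = tf_clusters,
              tf_within_jaccard = tf_within_jaccard,
              tf_between_jaccard = tf_between_jaccard,
              tf_loci_per_tf = as.integer(tf_loci_per_tf),
              survival_hazard_link = survival_hazard_link,
              baseline_hazard = baseline_hazard,
              max_follow_up = max_follow_up, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# fixed per-modality seed offsets: adding CpGs never perturbs peak draws
seed_for <- function(config, modality) {
  offs <- c(layout = 101L, meth = 211L, peaks = 307L, genes = 401L,
            sites = 503L, survival = 601L)
  (config$seed + offs[[modality]]) %% .Machine$integer.max
}

sample_sheet_for <- function(config) {
  stage <- rep(STAGES, times = config$n_per_stage)
  data.frame(
    sample_id = sprintf("%s_%02d", stage,
                        unlist(lapply(config$n_per_stage, seq_len))),
    stage = factor(stage, levels = STAGES, ordered = TRUE),
    stringsAsFactors = FALSE)
}

#' Genome layout and planted-effect registry for a configuration
#'
#' Deterministic given the config seed. Locus effect assignments are drawn
#' once here so all modalities agree on which loci are planted.
#'
#' @param config a [cohort_config()].
#' @return list with `loci` (interval data.frame with locus ids), `cpgs`,
#'   `peaks`, and `truth` (registries of planted methylation, accessibility,
#'   gene and panel effects plus TF cluster labels).
#' @export
cohort_layout <- function(config) {
  set.seed(seed_for(config, "layout"))
  n <- config$n_loci
  offset <- (seq_len(n) - 1L) * LOCUS_SPACING
  loci <- intervals(rep("chr1", n), offset, offset + LOCUS_SPACING)
  loci$locus <- sprintf("L%04d", seq_len(n))
  cpg_start <- as.vector(outer(100L + 50L * (0:(CPGS_PER_LOCUS - 1L)),
                               offset, `+`))
  cpg_start <- sort(cpg_start)
  cpgs <- intervals(rep("chr1", length(cpg_start)), cpg_start, cpg_start + 1L)
  cpgs$locus <- loci$locus[findInterval(cpgs$start, offset)]
  peaks <- intervals(rep("chr1", n), offset + 50L, offset + 350L)
  peaks$peak_id <- sprintf("peak_%04d", seq_len(n))
  peaks$locus <- loci$locus

  cats <- expand.grid(onset = CASE_STAGES, direction = c("hyper", "hypo"),
                      stringsAsFactors = FALSE)
  per_cat <- config$n_panel_per_cat + config$n_meth_only_per_cat +
    config$n_acc_only_per_cat
  planted_idx <- if (per_cat > 0) sample.int(n, nrow(cats) * per_cat) else integer()
  reg <- data.frame(locus = character(), kind = character(),
                    onset = character(), meth_direction = character(),
                    acc_direction = character(), stringsAsFactors = FALSE)
  k <- 0L
  for (i in if (per_cat > 0) seq_len(nrow(cats)) else integer()) {
    idx <- planted_idx[k + seq_len(per_cat)]; k <- k + per_cat
    kind <- rep(c("panel", "meth_only", "acc_only"),
                c(config$n_panel_per_cat, config$n_meth_only_per_cat,
                  config$n_acc_only_per_cat))
    reg <- rbind(reg, data.frame(
      locus = loci$locus[idx], kind = kind,
      onset = cats$onset[i], meth_direction = cats$direction[i],
      # panel loci couple methylation and accessibility with opposite sign
      acc_direction = ifelse(cats$direction[i] == "hyper", "hypo", "hyper"),
      stringsAsFactors = FALSE))
  }
  meth_eff <- reg[reg$kind %in% c("panel", "meth_only"), ]
  meth_effects <- data.frame(locus = meth_eff$locus, onset = meth_eff$onset,
                             direction = meth_eff$meth_direction,
                             delta = ifelse(meth_eff$meth_direction == "hyper",
                                            config$meth_delta, -config$meth_delta),
                             stringsAsFactors = FALSE)
  acc_eff <- reg[reg$kind %in% c("panel", "acc_only"), ]
  acc_effects <- data.frame(
    locus = acc_eff$locus,
    peak_id = peaks$peak_id[match(acc_eff$locus, peaks$locus)],
    onset = acc_eff$onset, direction = acc_eff$acc_direction,
    log2fc = ifelse(acc_eff$acc_direction == "hyper",
                    config$acc_lfc, -config$acc_lfc),
    stringsAsFactors = FALSE)

  gcats <- cats[rep(seq_len(nrow(cats)), each = config$n_deg_per_cat), ]
  gidx <- sample.int(config$n_genes, nrow(gcats))
  gene_effects <- data.frame(
    gene = sprintf("gene_%04d", gidx), onset = gcats$onset,
    direction = ifelse(gcats$direction == "hyper", "up", "down"),
    log2fc = ifelse(gcats$direction == "hyper",
                    config$gene_lfc, -config$gene_lfc),
    stringsAsFactors = FALSE)

  truth <- list(meth_effects = meth_effects, acc_effects = acc_effects,
                gene_effects = gene_effects,
                panel_loci = reg$locus[reg$kind == "panel"],
                panel_registry = reg[reg$kind == "panel", ],
                tf_clusters = config$tf_clusters,
                clip_warnings = character())
  list(loci = loci, cpgs = cpgs, peaks = peaks, truth = truth)
}

rbetabinom <- function(n, size, mu, phi) {
  q <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  stats::rbinom(n, size, q)
}

#' Simulate per-sample methylation tracks
#'
#' Per CpG and sample, total reads are Poisson(`mean_coverage`) floored at 1
#' and methylated reads are beta-binomial around the stage-dependent mean:
#' the baseline level shifted by the planted delta for samples at or after
#' the effect's onset stage. Means pushed outside `[0, 1]` are clipped and
#' the clip is recorded in the truth registry.
#'
#' @param config a [cohort_config()].
#' @param layout result of [cohort_layout()] (computed if NULL).
#' @return list: `meth` (a [meth_matrix()]), `sheet` (sample sheet without
#'   survival columns), `truth` (layout truth with clip warnings filled in).
#' @export
simulate_methylation <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- cohort_layout(config)
  set.seed(seed_for(config, "meth"))
  sheet <- sample_sheet_for(config)
  cpgs <- layout$cpgs
  n_sites <- nrow(cpgs); n_samp <- nrow(sheet)

  mu <- matrix(config$baseline_meth, n_sites, n_samp)
  eff <- layout$truth$meth_effects
  stage_num <- as.integer(sheet$stage)  # CTL=1 ... IAC=4
  for (i in seq_len(nrow(eff))) {
    rows <- which(cpgs$locus == eff$locus[i])
    cols <- which(stage_num >= match(eff$onset[i], STAGES))
    mu[rows, cols] <- mu[rows, cols] + eff$delta[i]
  }
  clipped <- mu < 0 | mu > 1
  if (any(clipped)) {
    layout$truth$clip_warnings <- c(layout$truth$clip_warnings,
      sprintf("%d methylation means clipped to [0,1]", sum(clipped)))
    warning(sum(clipped), " planted methylation means clipped to [0,1]")
    mu <- pmin(pmax(mu, 0), 1)
  }
  total <- matrix(pmax(stats::rpois(n_sites * n_samp, config$mean_coverage), 1L),
                  n_sites, n_samp)
  meth <- matrix(rbetabinom(n_sites * n_samp, as.vector(total), as.vector(mu),
                            config$meth_precision),
                 n_sites, n_samp)
  colnames(total) <- colnames(meth) <- sheet$sample_id
  mm <- structure(list(sites = cpgs[, c("chrom", "start", "end", "strand")],
                       meth = meth, total = total),
                  class = "meth_matrix")
  list(meth = mm, sheet = sheet, truth = layout$truth)
}

#' Simulate a peak or gene count matrix
#'
#' Counts are negative binomial with mean
#' `size_factor * baseline_mean * 2^log2fc` (the planted fold change applied
#' to samples at or after the effect's onset) and dispersion
#' `nb_dispersion`. Per-sample size factors are lognormal with geometric
#' mean 1 and are recorded in the returned truth fragment.
#'
#' @param config a [cohort_config()].
#' @param modality `"peaks"` or `"genes"`.
#' @param layout result of [cohort_layout()] (computed if NULL).
#' @return list: `counts` (feature x sample integer matrix), `features`
#'   (peak interval data.frame for peaks, gene ids for genes), `sheet`,
#'   `size_factors`.
#' @export
simulate_counts <- function(config, modality = c("peaks", "genes"),
                            layout = NULL) {
  modality <- match.arg(modality)
  if (is.null(layout)) layout <- cohort_layout(config)
  set.seed(seed_for(config, modality))
  sheet <- sample_sheet_for(config)
  n_samp <- nrow(sheet)
  stage_num <- as.integer(sheet$stage)

  if (modality == "peaks") {
    ids <- layout$peaks$peak_id
    eff <- layout$truth$acc_effects
    eff_feature <- eff$peak_id
  } else {
    ids <- sprintf("gene_%04d", seq_len(config$n_genes))
    eff <- layout$truth$gene_effects
    eff_feature <- eff$gene
  }
  n_feat <- length(ids)
  base_mu <- config$nb_mean *
    exp(stats::rnorm(n_feat, 0, config$nb_mean_spread))
  log_sf <- stats::rnorm(n_samp, 0, config$size_factor_sd)
  sf <- exp(log_sf - mean(log_sf))  # geometric mean exactly 1

  lfc <- matrix(0, n_feat, n_samp)
  for (i in seq_len(nrow(eff))) {
    r <- match(eff_feature[i], ids)
    cols <- which(stage_num >= match(eff$onset[i], STAGES))
    lfc[r, cols] <- lfc[r, cols] + eff$log2fc[i]
  }
  mu <- outer(base_mu, sf) * 2^lfc
  counts <- matrix(stats::rnbinom(n_feat * n_samp, mu = as.vector(mu),
                                  size = 1 / config$nb_dispersion),
                   n_feat, n_samp,
                   dimnames = list(ids, sheet$sample_id))
  storage.mode(counts) <- "integer"
  features <- if (modality == "peaks") layout$peaks else ids
  list(counts = counts, features = features, sheet = sheet,
       size_factors = stats::setNames(sf, sheet$sample_id))
}

# Locus allocations hitting target pairwise Jaccard indices exactly (up to
# rounding). For a pair occupying t loci each with c common, J = c/(2t - c),
# so a shared fraction a = c/t = 2J/(1 + J).

# uniform sharing J across ALL TF pairs: one common set + unique remainders
alloc_uniform <- function(pool, tfs, J, cap) {
  n <- length(tfs); a <- 2 * J / (1 + J)
  t <- floor(length(pool) / max(n - a * (n - 1), 1e-9))
  t <- max(1L, min(t, cap))
  repeat {
    c_n <- round(a * t); u_n <- t - c_n
    if (c_n + n * u_n <= length(pool) || t <= 1) break
    t <- t - 1L
  }
  common <- pool[seq_len(c_n)]
  rest <- pool[-seq_len(c_n)]
  occ <- list(); idx <- 0L
  for (tf in tfs) {
    occ[[tf]] <- c(common, rest[idx + seq_len(u_n)])
    idx <- idx + u_n
  }
  occ
}

# block sharing: Jw within a cluster, Jb across clusters (via a global
# common set); per-cluster shared sets are drawn from disjoint subpools
alloc_clustered <- function(pool, clusters, Jw, Jb, cap) {
  a_w <- 2 * Jw / (1 + Jw); a_b <- 2 * Jb / (1 + Jb)
  k <- length(clusters); m <- max(lengths(clusters))
  denom <- max(a_b + k * (a_w - a_b) + k * m * (1 - a_w), 1e-9)
  t <- floor(length(pool) / denom)
  t <- max(2L, min(t, cap))
  need <- function(t) {
    c_n <- round(a_b * t); s_n <- round((a_w - a_b) * t)
    c_n + sum(vapply(clusters, function(cl)
      s_n + length(cl) * (t - c_n - s_n), numeric(1)))
  }
  while (need(t) > length(pool) && t > 2) t <- t - 1L
  c_n <- round(a_b * t); s_n <- round((a_w - a_b) * t)
  u_n <- t - c_n - s_n
  # allocate from the pool front in tiers (common, every cluster's shared
  # set, then unique sets) so shared occupancy concentrates at the head of
  # the pool for all clusters alike
  common <- pool[seq_len(c_n)]
  rest <- pool[-seq_len(c_n)]
  shared <- list(); idx <- 0L
  for (cl in names(clusters)) {
    shared[[cl]] <- rest[idx + seq_len(s_n)]; idx <- idx + s_n
  }
  occ <- list()
  for (cl in names(clusters)) {
    for (tf in clusters[[cl]]) {
      occ[[tf]] <- c(common, shared[[cl]], rest[idx + seq_len(u_n)])
      idx <- idx + u_n
    }
  }
  occ
}

#' Simulate TF motif-site interval sets with planted co-binding clusters
#'
#' TFs in the same planted cluster occupy overlapping sets of loci inside the
#' planted accessibility (DAR) loci, targeting the configured within-cluster
#' Jaccard; across clusters (and in the genome-wide background context)
#' occupancy overlap targets the lower between-cluster Jaccard. One to three
#' 10 bp sites are placed per occupied locus.
#'
#' @param config a [cohort_config()].
#' @param layout result of [cohort_layout()] (computed if NULL).
#' @return list: `sites` (named list of interval data.frames, one per TF),
#'   `cluster_labels` (named character vector TF -> cluster).
#' @export
simulate_sites <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- cohort_layout(config)
  if (length(config$tf_clusters) < 2) stop("need >= 2 planted TF clusters")
  set.seed(seed_for(config, "sites"))
  # panel loci (both methylation and accessibility change) come first in
  # the pool so shared TF occupancy concentrates where epi TFs bind
  shuf <- function(x) x[sample.int(length(x))]
  acc_loci <- unique(layout$truth$acc_effects$locus)
  panel <- intersect(acc_loci, layout$truth$panel_loci)
  dar_loci <- c(shuf(panel), shuf(setdiff(acc_loci, panel)))
  bg_loci <- shuf(setdiff(layout$loci$locus, dar_loci))
  in_dar <- alloc_clustered(dar_loci, config$tf_clusters,
                            config$tf_within_jaccard,
                            config$tf_between_jaccard,
                            config$tf_loci_per_tf)
  in_bg <- alloc_uniform(bg_loci, unlist(config$tf_clusters),
                         config$tf_between_jaccard, config$tf_loci_per_tf)
  occupancy <- lapply(stats::setNames(nm = unlist(config$tf_clusters)),
                      function(tf) c(in_dar[[tf]], in_bg[[tf]]))
  loci <- layout$loci
  # per-locus site positions drawn once, shared by every TF occupying the
  # locus, so site-level sharing mirrors locus-level sharing
  locus_sites <- lapply(seq_len(nrow(loci)), function(i) {
    n_sites <- sample(1:3, 1)
    loci$start[i] + 60L + sample.int(200L, n_sites)
  })
  sites <- lapply(occupancy, function(locus_ids) {
    idx <- match(locus_ids, loci$locus)
    pos <- unlist(locus_sites[idx])
    chrom <- rep(loci$chrom[idx], lengths(locus_sites[idx]))
    sort_intervals(intervals(chrom, pos, pos + 10L))
  })
  labels <- stats::setNames(
    rep(names(config$tf_clusters), lengths(config$tf_clusters)),
    unlist(config$tf_clusters))
  list(sites = sites, cluster_labels = labels)
}

#' Simulate survival columns coupled to panel methylation
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(-survival_hazard_link * mean panel methylation)`,
#' so a positive link makes LOW methylation mean HIGH hazard (the poor
#' prognosis of the hypomethylated panel). Censoring is independent uniform
#' on `[0, max_follow_up]`.
#'
#' @param config a [cohort_config()].
#' @param panel_meth named numeric vector: mean panel methylation per sample.
#' @return data.frame (sample_id, survival_time, event).
#' @export
simulate_survival <- function(config, panel_meth) {
  set.seed(seed_for(config, "survival"))
  hazard <- config$baseline_hazard *
    exp(-config$survival_hazard_link * panel_meth)
  t_event <- stats::rexp(length(panel_meth), rate = hazard)
  t_cens <- stats::runif(length(panel_meth), 0, config$max_follow_up)
  data.frame(sample_id = names(panel_meth),
             survival_time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Simulate the full cohort
#'
#' Runs the layout, methylation, peak, gene, TF-site and survival generators
#' in sequence. Deterministic given the config (bit-identical for identical
#' config and seed).
#'
#' @param config a [cohort_config()].
#' @return list with elements `meth`, `peak_counts`, `peaks`, `gene_counts`,
#'   `tf_sites`, `sheet` (with survival columns), `loci`, `truth`.
#' @export
simulate_cohort <- function(config) {
  layout <- cohort_layout(config)
  me <- simulate_methylation(config, layout)
  pk <- simulate_counts(config, "peaks", layout)
  gn <- simulate_counts(config, "genes", layout)
  tf <- simulate_sites(config, layout)

  panel_regions <- layout$loci[layout$loci$locus %in% me$truth$panel_loci, ]
  panel_meth <- colMeans(
    region_methylation(me$meth, panel_regions), na.rm = TRUE)
  surv <- simulate_survival(config, panel_meth)
  sheet <- merge(me$sheet, surv, by = "sample_id", sort = FALSE)
  sheet <- sheet[match(me$sheet$sample_id, sheet$sample_id), ]
  rownames(sheet) <- NULL

  truth <- me$truth
  truth$peak_size_factors <- pk$size_factors
  truth$gene_size_factors <- gn$size_factors
  truth$tf_cluster_labels <- tf$cluster_labels
  truth$survival = list(link = config$survival_hazard_link,
                        baseline_hazard = config$baseline_hazard)
  list(meth = me$meth, peak_counts = pk$counts, peaks = layout$peaks,
       gene_counts = gn$counts, tf_sites = tf$sites, sheet = sheet,
       loci = layout$loci, truth = truth)
}

#' Simulate per-sample peak metrics with a planted monotone coupling
#'
#' A small generator for correlation-recovery experiments: per peak and
#' sample a methylation level is drawn uniformly and accessibility is a
#' monotone decreasing function of it plus Gaussian noise (coupling < 0), a
#' monotone increasing function (coupling > 0), or independent noise
#' (coupling = 0).
#'
#' @param n_peaks,n_samples dimensions.
#' @param coupling -1, 0 or +1 times a strength in `[0, 1]`.
#' @param noise_sd Gaussian noise sd on the accessibility scale.
#' @param seed RNG seed.
#' @return list of two matrices, `meth` and `acc` (peak x sample).
#' @export
simulate_coupled_peaks <- function(n_peaks, n_samples, coupling = -1,
                                   noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  meth <- matrix(stats::runif(n_peaks * n_samples), n_peaks, n_samples)
  acc <- coupling * meth +
    matrix(stats::rnorm(n_peaks * n_samples, 0, noise_sd), n_peaks, n_samples)
  dimnames(meth) <- dimnames(acc) <-
    list(sprintf("peak_%04d", seq_len(n_peaks)),
         sprintf("S%03d", seq_len(n_samples)))
  list(meth = meth, acc = acc)
}
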