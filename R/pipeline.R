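#' End-to-end cohort pipeline
#'
#' Glue running the full stage-resolved integration on a cohort: DMC/DMR
#' calling and stage partition, DAR/DEG calling and stage partition, srDMR
#' and srDAR assembly, the overlap panel, and panel-based classification
#' and survival stratification.
#'
#' @name pipeline
NULL

#' Per-stage NB differential calls and onset partition for a count matrix
#'
#' @param counts feature x sample count matrix.
#' @param sheet sample sheet (sample_id, stage).
#' @param caller thresholding function applied to each [nb_test()] table
#'   ([call_dars()] or [call_degs()]).
#' @return list: `per_stage` (significant calls per case stage), `vectors`
#'   (stage-result vectors over all features), `partition` (feature ids per
#'   onset category).
#' @export
stage_differential <- function(counts, sheet, caller = call_dars) {
  ctl <- sheet$sample_id[sheet$stage == "CTL"]
  sf <- size_factors(counts)
  per_stage <- list()
  for (st in CASE_STAGES) {
    cs <- sheet$sample_id[sheet$stage == st]
    per_stage[[st]] <- caller(nb_test(counts, cs, ctl))
  }
  vectors <- stage_result_vectors(per_stage, rownames(counts))
  list(per_stage = per_stage, vectors = vectors,
       partition = stage_partition(vectors))
}

#' Assemble srDMRs into one table with a category column
#'
#' @param dmc_partition per-category DMC tables
#'   (from [stage_dmc_partition()]).
#' @param min_dmcs,max_gap DMR merge parameters.
#' @return data.frame: chrom, start, end, n_dmcs, direction, category.
#' @export
assemble_srdmrs <- function(dmc_partition, min_dmcs = 3, max_gap = 200) {
  dmrs <- stage_dmrs(dmc_partition, min_dmcs = min_dmcs, max_gap = max_gap)
  out <- do.call(rbind, lapply(names(dmrs), function(cat) {
    x <- dmrs[[cat]]
    if (nrow(x) == 0) return(NULL)
    x$category <- cat
    x
  }))
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_dmcs = integer(),
                      direction = character(), category = character()))
  rownames(out) <- NULL
  out
}

#' Assemble srDARs into one table with categories and peak coordinates
#'
#' @param dar_partition onset partition of peak ids
#'   (from [stage_differential()]).
#' @param peaks peak interval data.frame with `peak_id`.
#' @return data.frame: chrom, start, end, category, peak_id.
#' @export
assemble_srdars <- function(dar_partition, peaks) {
  out <- do.call(rbind, lapply(stage_categories(), function(cat) {
    ids <- dar_partition[[cat]]
    if (length(ids) == 0) return(NULL)
    pk <- peaks[match(ids, peaks$peak_id), ]
    data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
               category = cat, peak_id = pk$peak_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), category = character(),
                      peak_id = character()))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on a simulated or assembled cohort
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param classifier_seed seed for the train/test split and forest.
#' @return list: `srdmrs`, `srdars`, `deg_partition`, `panel` (per-srDAR
#'   deduplicated), `panel_pairs` (all overlapping pairs),
#'   `metric_correlations`, `binary_report`, `multiclass_report`,
#'   `survival`.
#' @export
run_cohort_pipeline <- function(cohort, classifier_seed = 1L) {
  sheet <- cohort$sheet
  dmc <- stage_dmc_partition(cohort$meth, sheet)
  srdmrs <- assemble_srdmrs(dmc$partition)
  dar <- stage_differential(cohort$peak_counts, sheet, call_dars)
  srdars <- assemble_srdars(dar$partition, cohort$peaks)
  deg <- stage_differential(cohort$gene_counts, sheet, call_degs)

  panel_pairs <- build_panel(srdmrs, srdars, cohort$meth, cohort$peak_counts)
  panel <- build_panel(srdmrs, srdars, cohort$meth, cohort$peak_counts,
                       dedup_by_srdar = TRUE)
  mc <- if (nrow(panel_pairs$pairs) >= 3)
    metric_correlations(panel_pairs) else NULL

  features <- panel$srdar_meth
  rownames(features) <- sprintf("panel_%03d", seq_len(nrow(features)))
  binary <- multiclass <- NULL
  if (nrow(features) >= 2) {
    binary <- train_eval_classifier(features, sheet$stage, "binary",
                                    seed = classifier_seed)
    multiclass <- train_eval_classifier(features, sheet$stage, "multiclass",
                                        seed = classifier_seed)
  }
  surv <- NULL
  if (nrow(features) >= 1 && "survival_time" %in% names(sheet)) {
    panel_meth <- colMeans(features, na.rm = TRUE)
    surv <- km_split_logrank(panel_meth, sheet)
  }
  list(srdmrs = srdmrs, srdars = srdars, dmc = dmc,
       dar_partition = dar$partition, deg_partition = deg$partition,
       panel = panel, panel_pairs = panel_pairs,
       metric_correlations = mc,
       binary_report = binary, multiclass_report = multiclass,
       survival = surv)
}
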