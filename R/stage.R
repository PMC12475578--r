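#' Mutually exclusive stage-onset categories
#'
#' Every feature tested at each case stage versus control carries a
#' stage-result vector of calls (hyper / hypo / ns for AIS, MIA, IAC). A
#' feature is assigned to the earliest stage with a significant call,
#' keeping the direction observed there; its status at later stages is no
#' longer considered. This yields six mutually exclusive categories —
#' {hyper, hypo} x {AIS, MIA, IAC} — plus "unassigned" for never-significant
#' features, and the six categories partition the ever-significant set.
#'
#' @name stage_assign
NULL

#' Assign one stage-result vector to its onset category
#'
#' @param calls character vector of length 3, stage-ordered (AIS, MIA, IAC),
#'   each `"hyper"`, `"hypo"` or `"ns"`.
#' @return category label: `"<direction>-<stage>"` or `"unassigned"`.
#' @export
assign_stage_category <- function(calls) {
  stopifnot(length(calls) == 3, all(calls %in% c("hyper", "hypo", "ns")))
  first <- which(calls != "ns")[1]
  if (is.na(first)) return("unassigned")
  paste0(calls[first], "-", CASE_STAGES[first])
}

#' All six category labels, stage-major order
#' @return character vector of the six category labels.
#' @export
stage_categories <- function() {
  as.vector(outer(c("hyper", "hypo"), CASE_STAGES, paste, sep = "-"))
}

#' Partition features into the six onset categories
#'
#' @param vectors data.frame with columns `feature`, `AIS`, `MIA`, `IAC`
#'   (each a call in hyper/hypo/ns); feature ids must be unique.
#' @return named list: one character vector of feature ids per category
#'   (six categories plus `unassigned`). The six sets are pairwise disjoint
#'   and their union is exactly the ever-significant features.
#' @export
stage_partition <- function(vectors) {
  stopifnot(all(c("feature", CASE_STAGES) %in% names(vectors)))
  if (anyDuplicated(vectors$feature)) stop("duplicate feature id")
  labels <- if (nrow(vectors) == 0) character() else
    apply(as.matrix(vectors[, CASE_STAGES]), 1, assign_stage_category)
  out <- lapply(c(stage_categories(), "unassigned"),
                function(cat) vectors$feature[labels == cat])
  names(out) <- c(stage_categories(), "unassigned")
  out
}

#' Build stage-result vectors from three per-stage differential tables
#'
#' @param per_stage named list (`AIS`, `MIA`, `IAC`) of data.frames with
#'   columns `feature` and `direction` — the significant calls at that stage
#'   (e.g. [call_dars()] output); features absent from a table are `ns`.
#' @param features universe of feature ids.
#' @return data.frame feature, AIS, MIA, IAC.
#' @export
stage_result_vectors <- function(per_stage, features) {
  stopifnot(all(CASE_STAGES %in% names(per_stage)))
  out <- data.frame(feature = features, stringsAsFactors = FALSE)
  for (st in CASE_STAGES) {
    tab <- per_stage[[st]]
    out[[st]] <- "ns"
    hit <- match(out$feature, tab$feature)
    out[[st]][!is.na(hit)] <- tab$direction[hit[!is.na(hit)]]
  }
  out
}

#' Stage-resolved DMRs (srDMRs)
#'
#' Applies [merge_dmcs_to_dmrs()] within each of the six DMC onset
#' categories separately, so DMCs of the same direction but different onset
#' never merge.
#'
#' @param dmc_partition named list of DMC data.frames, one per category
#'   (each sorted by chrom, start).
#' @param min_dmcs,max_gap merge parameters (defaults 3 and 200 bp).
#' @return named list of DMR data.frames per category.
#' @export
stage_dmrs <- function(dmc_partition, min_dmcs = 3, max_gap = 200) {
  lapply(dmc_partition, merge_dmcs_to_dmrs,
         min_dmcs = min_dmcs, max_gap = max_gap)
}

#' Stage-resolved DMC partition from a methylation matrix
#'
#' Calls DMCs for each case stage against control, builds per-site
#' stage-result vectors, and partitions them into onset categories.
#'
#' @param meth a [meth_matrix()].
#' @param sheet sample sheet with `sample_id` and `stage`.
#' @param min_credible_dif DMC threshold (default 0.20).
#' @return list: `partition` (named list of per-category DMC data.frames,
#'   sorted), `vectors` (stage-result vectors), `per_stage` (raw DMC tables).
#' @export
stage_dmc_partition <- function(meth, sheet, min_credible_dif = 0.20) {
  ctl <- sheet$sample_id[sheet$stage == "CTL"]
  per_stage <- list()
  for (st in CASE_STAGES) {
    dm <- call_dmcs(meth, sheet$sample_id[sheet$stage == st], ctl,
                    min_credible_dif = min_credible_dif)
    dm$feature <- sprintf("%s:%d", dm$chrom, dm$start)
    per_stage[[st]] <- dm
  }
  ever <- unique(unlist(lapply(per_stage, `[[`, "feature")))
  vectors <- stage_result_vectors(per_stage, ever)
  sets <- stage_partition(vectors)
  site_key <- sprintf("%s:%d", meth$sites$chrom, meth$sites$start)
  partition <- lapply(sets[stage_categories()], function(ids) {
    if (length(ids) == 0)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), direction = character(),
                        feature = character(), stringsAsFactors = FALSE))
    idx <- match(ids, site_key)
    onset <- vectors[match(ids, vectors$feature), ]
    df <- data.frame(chrom = meth$sites$chrom[idx],
                     start = meth$sites$start[idx],
                     end = meth$sites$end[idx],
                     direction = apply(as.matrix(onset[, CASE_STAGES]), 1,
                                       function(v) v[v != "ns"][1]),
                     feature = ids, stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  list(partition = partition, vectors = vectors, per_stage = per_stage)
}
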