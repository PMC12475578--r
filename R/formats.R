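#' Tabular formats: methylation tracks, count matrices, sample sheets
#'
#' All tabular files are tab-delimited with a header row; writers emit a
#' deterministic column order and coordinate-sorted rows so that
#' read-then-write round-trips are the identity.
#'
#' @name formats
NULL

STAGES <- c("CTL", "AIS", "MIA", "IAC")
CASE_STAGES <- c("AIS", "MIA", "IAC")

#' Read a per-sample methylation track
#'
#' A track is a TSV with header columns chrom, start, end, methylated, total:
#' one row per CpG with methylated/total read counts. The methylation level
#' is always derived as methylated/total, never stored.
#'
#' @param path input TSV.
#' @param sample_id optional sample identifier attached to the result
#'   (defaults to the file base name without extension).
#' @return data.frame (chrom, start, end, methylated, total) sorted by
#'   (chrom, start), with attribute `sample_id`.
#' @export
read_methylation_track <- function(path, sample_id = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "methylated", "total")
  if (!all(need %in% names(x)))
    stop("track parse error: missing columns ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x <- x[, need]
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 !is.finite(x$methylated) | !is.finite(x$total))
  if (length(bad) > 0)
    stop("track parse error at line ", bad[1] + 1L, ": malformed row")
  if (any(x$end <= x$start))
    stop("track parse error at line ",
         which(x$end <= x$start)[1] + 1L, ": end <= start")
  bad <- which(x$methylated > x$total | x$methylated < 0)
  if (length(bad) > 0)
    stop("track parse error at line ", bad[1] + 1L,
         ": methylated exceeds total")
  ord <- order(x$chrom, x$start)
  if (any(ord != seq_len(nrow(x))))
    stop("track parse error: input not sorted by (chrom, start)")
  if (anyDuplicated(paste(x$chrom, x$start)))
    stop("track parse error: duplicate CpG position")
  rownames(x) <- NULL
  attr(x, "sample_id") <- if (is.null(sample_id))
    sub("\\.[^.]*$", "", basename(path)) else sample_id
  x
}

#' Write a methylation track
#' @param track data.frame as returned by [read_methylation_track()].
#' @param path output TSV path.
#' @export
write_methylation_track <- function(track, path) {
  out <- track[order(track$chrom, track$start),
               c("chrom", "start", "end", "methylated", "total")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble per-sample tracks into a methylation matrix
#'
#' @param tracks named list of track data.frames (names are sample ids); all
#'   tracks must cover the same CpG sites.
#' @return object of class `meth_matrix`: list with `sites` (interval
#'   data.frame), `meth` and `total` (site x sample count matrices).
#' @export
meth_matrix <- function(tracks) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  ref <- tracks[[1]]
  key <- paste(ref$chrom, ref$start)
  for (tr in tracks) {
    if (!identical(paste(tr$chrom, tr$start), key))
      stop("all tracks must share an identical CpG site set")
  }
  meth <- vapply(tracks, function(t) t$methylated, numeric(nrow(ref)))
  total <- vapply(tracks, function(t) t$total, numeric(nrow(ref)))
  structure(list(
    sites = intervals(ref$chrom, ref$start, ref$end),
    meth = matrix(meth, nrow = nrow(ref), dimnames = list(NULL, names(tracks))),
    total = matrix(total, nrow = nrow(ref), dimnames = list(NULL, names(tracks)))
  ), class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", nrow(x$sites), "CpG sites x",
      ncol(x$meth), "samples\n")
  invisible(x)
}

#' Read a feature x sample count matrix
#'
#' TSV with a `feature` id column followed by one column per sample.
#'
#' @param path input TSV.
#' @return integer matrix with feature row names and sample column names.
#' @export
read_count_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "feature") stop("count matrix must start with a 'feature' column")
  m <- as.matrix(x[, -1, drop = FALSE])
  if (any(m < 0) || any(m != round(m)))
    stop("count matrix entries must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- x$feature
  m
}

#' Write a count matrix
#' @param m count matrix with row and column names.
#' @param path output TSV path.
#' @export
write_count_matrix <- function(m, path) {
  out <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns: sample_id, stage (CTL/AIS/MIA/IAC), and optionally survival_time,
#' event (0/1), age, sex. The stage column becomes an ordered factor
#' CTL < AIS < MIA < IAC.
#'
#' @param path input TSV.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(x)
}

validate_sample_sheet <- function(x) {
  if (!all(c("sample_id", "stage") %in% names(x)))
    stop("sample sheet needs sample_id and stage columns")
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(x$stage %in% STAGES))
    stop("stage labels must be in {", paste(STAGES, collapse = ", "), "}")
  x$stage <- factor(x$stage, levels = STAGES, ordered = TRUE)
  if ("survival_time" %in% names(x) && any(x$survival_time < 0, na.rm = TRUE))
    stop("survival_time must be non-negative")
  if ("event" %in% names(x) && !all(x$event %in% c(0, 1, NA)))
    stop("event must be 0/1")
  x
}

#' Write a sample sheet
#' @param sheet sample sheet data.frame.
#' @param path output TSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet$stage <- as.character(sheet$stage)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
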