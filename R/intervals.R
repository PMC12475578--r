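#' Genomic intervals and interval algebra
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' an interval covers positions `start, ..., end - 1`. CpG sites are width-1
#' intervals keyed by the cytosine position. Strand is carried through the
#' readers but ignored by all overlap logic.
#'
#' @name intervals
NULL

#' Construct a validated interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
intervals <- function(chrom, start, end, strand = NULL) {
  if (is.null(strand)) strand <- rep(".", length(chrom))
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(strand) == length(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be numeric and non-missing")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start (half-open, non-empty)")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Sort an interval table by (chrom, start, end)
#' @param x interval data.frame.
#' @return sorted data.frame (row names dropped).
#' @export
sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    # shift to 1-based closed for IRanges; width preserved
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals (one from `a`, one from `b`) sharing at
#' least one base, with the overlap width. Half-open adjacency (shared
#' boundary coordinate only) is not an overlap.
#'
#' @param a,b interval data.frames (chrom, start, end).
#' @return data.frame with columns `a_idx`, `b_idx` (row indices into the
#'   inputs) and `overlap` (shared bases, >= 1). Zero rows when nothing
#'   overlaps.
#' @export
intersect_intervals <- function(a, b) {
  empty <- data.frame(a_idx = integer(), b_idx = integer(), overlap = integer())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  ga <- as_granges(a); gb <- as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  if (length(hits) == 0) return(empty)
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  out <- data.frame(a_idx = ai, b_idx = bi, overlap = as.integer(ov))
  out <- out[order(out$a_idx, out$b_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED3+ interval file
#'
#' @param path path to a tab-delimited BED file (no header). Columns beyond
#'   the sixth are ignored; column 6, when present, is the strand.
#' @return interval data.frame (chrom, start, end, strand).
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3))
    stop("BED parse error at line ", which(n < 3)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop("BED parse error at line ", bad[1], ": non-numeric coordinate")
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop("BED parse error at line ", bad[1], ": end <= start (empty interval)")
  strand <- rep(".", length(chrom))
  has6 <- n >= 6
  strand[has6] <- vapply(fields[has6], `[[`, character(1), 6)
  intervals(chrom, start, end, strand)
}

#' Write intervals as coordinate-sorted BED
#'
#' Emits BED3 when every strand is `"."`, BED6 otherwise (name `"."`,
#' score 0).
#'
#' @param x interval data.frame.
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  x <- sort_intervals(x)
  if (is.null(x$strand) || all(x$strand == ".")) {
    out <- x[, c("chrom", "start", "end")]
  } else {
    out <- data.frame(x$chrom, x$start, x$end, ".", 0L, x$strand)
  }
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
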