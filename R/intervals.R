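#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits
NULL

# All intervals in this package are 0-based half-open [start, end), the BED
# convention. GRanges (1-based closed) is used only transiently for overlap
# queries; conversion happens at this boundary and nowhere else.

#' Construct a validated interval table
#'
#' The universal coordinate unit of the package: a data.frame with columns
#' `chrom`, `start`, `end` (0-based half-open) and optionally `strand`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` required.
#' @param strand optional; one of `"+"`, `"-"`, `"."` per interval.
#' @param ... further equal-length columns carried along.
#' @return data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", ".")))
      stop("strand must be '+', '-' or '.'")
    df$strand <- strand
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

# Empty interval table with the standard columns.
empty_intervals <- function(strand = FALSE) {
  df <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                   stringsAsFactors = FALSE)
  if (strand) df$strand <- character(0)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

# data.frame (0-based half-open) -> GRanges (1-based closed).
as_granges <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

# GRanges -> 0-based half-open data.frame.
from_granges <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

# Pairwise overlap widths (bp) between query i and subject j for all
# overlapping pairs; returns data.frame(query, subject, overlap_bp).
overlap_pairs <- function(query, subject) {
  gq <- as_granges(query)
  gs <- as_granges(subject)
  hits <- GenomicRanges::findOverlaps(gq, gs)
  if (length(hits) == 0)
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = integer(0)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- pmin(query$end[qi], subject$end[si]) - pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, overlap_bp = w)
}

# Logical: does each query interval overlap any subject interval (>= 1 bp)?
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges(query), as_granges(subject))
}

# Coalesce overlapping/adjacent intervals into their union.
reduce_intervals <- function(df, min_gap = 0L) {
  if (nrow(df) == 0) return(empty_intervals())
  gr <- GenomicRanges::reduce(as_granges(df), min.gapwidth = min_gap + 1L)
  out <- from_granges(gr)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Per-chromosome set difference a \ b, as intervals.
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0) return(empty_intervals())
  if (nrow(b) == 0) return(a[, c("chrom", "start", "end")])
  ga <- as_granges(a)
  gb <- as_granges(b)
  out <- GenomicRanges::setdiff(ga, GenomicRanges::reduce(gb))
  from_granges(out)
}

# Clip intervals to [0, chrom_size]; drops empty results.
clip_to_chrom <- function(df, chrom_sizes) {
  if (nrow(df) == 0) return(df)
  sz <- chrom_sizes$size[match(df$chrom, chrom_sizes$chrom)]
  if (any(is.na(sz)))
    stop("interval on unknown chromosome: ",
         paste(unique(df$chrom[is.na(sz)]), collapse = ", "))
  df$start <- pmax(df$start, 0)
  df$end <- pmin(df$end, sz)
  df[df$start < df$end, , drop = FALSE]
}
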