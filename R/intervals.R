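#' Genomic intervals
#'
#' All coordinates in this package are 0-based half-open (BED convention).
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand`; [GenomicRanges::GRanges] is used internally for overlap queries.
#' Conversion to 1-based inclusive coordinates happens only at report
#' boundaries.
#'
#' @param chrom Chromosome / reference name(s).
#' @param start 0-based inclusive start position(s).
#' @param end 0-based exclusive end position(s).
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @return A data frame with one row per interval.
#' @examples
#' genomic_interval("chr1", 0, 100)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval must satisfy start < end")
  data.frame(
    chrom = rep_len(as.character(chrom), length(start)),
    start = start, end = end,
    strand = rep_len(as.character(strand), length(start)),
    stringsAsFactors = FALSE
  )
}

# internal: 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Overlap width of two interval sets, elementwise
#'
#' Strand-blind: callers apply any strand rules. Intervals on different
#' chromosomes overlap by 0; half-open adjacency (`[0,10)` vs `[10,20)`)
#' overlaps by 0.
#'
#' @param a,b Interval data frames of equal length (or length 1, recycled).
#' @return Integer vector of overlap widths in bp.
#' @examples
#' overlap_bp(genomic_interval("chr1", 0, 10), genomic_interval("chr1", 5, 20))
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  w <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  w[a$chrom[ai] != b$chrom[bi]] <- 0L
  as.integer(pmax(0L, w))
}

#' All positively-overlapping query/subject pairs
#'
#' The pair set is exactly the pairs with overlap > 0, sorted by query then
#' subject index. Backed by [GenomicRanges::findOverlaps()].
#'
#' @param query,subject Interval data frames.
#' @return Data frame with integer columns `query` and `subject`.
#' @export
bulk_intersect <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(), subject = integer()))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges0(query), as_granges0(subject),
    minoverlap = 1L, ignore.strand = TRUE
  )
  out <- data.frame(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
  out[order(out$query, out$subject), , drop = FALSE]
}
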