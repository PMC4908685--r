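#' Spliced transcript alignments
#'
#' A set of spliced transcript alignments (spliced ESTs, PacBio isoform
#' predictions, ...) is a data frame with one row per alignment record:
#'
#' * `id` — record name; the same id may carry several alignments
#'   (`n_alignments` > 1).
#' * `chrom`, `start`, `end` — 0-based half-open alignment span.
#' * `align_strand` — alignment direction of the cDNA to the genome
#'   (`"+"`/`"-"`); this is *not* the transcriptional direction.
#' * `block_starts`, `block_ends` — list columns of integer vectors, the
#'   aligned exon blocks in genomic order (0-based half-open).
#' * `intron_orientation` — signed integer; positive means the
#'   transcriptional direction matches the alignment direction, negative
#'   means it opposes it, zero means it is undetermined.
#' * `txn_strand` — resolved transcriptional strand (`"+"`, `"-"` or
#'   `"undetermined"`); filled in by [resolve_txn_strand()].
#' * `n_alignments` — number of alignment records sharing this `id`.
#'
#' @param id,chrom,align_strand Character vectors.
#' @param block_starts,block_ends Lists of integer vectors (genomic order,
#'   0-based half-open).
#' @param intron_orientation Integer vector.
#' @param n_alignments Optional integer; if `NULL`, computed from `id`.
#' @return A `spliced_transcripts` data frame.
#' @export
spliced_transcripts <- function(id, chrom, align_strand, block_starts,
                                block_ends, intron_orientation,
                                n_alignments = NULL) {
  chrom <- rep_len(as.character(chrom), length(id))
  align_strand <- rep_len(as.character(align_strand), length(id))
  intron_orientation <- rep_len(as.integer(intron_orientation), length(id))
  stopifnot(length(block_starts) == length(id),
            length(block_ends) == length(id))
  block_starts <- lapply(block_starts, as.integer)
  block_ends <- lapply(block_ends, as.integer)
  for (i in seq_along(id)) {
    bs <- block_starts[[i]]; be <- block_ends[[i]]
    if (length(bs) != length(be) || length(bs) < 1L)
      stop("record ", id[i], ": malformed blocks")
    if (any(bs >= be)) stop("record ", id[i], ": empty block")
    if (is.unsorted(bs, strictly = TRUE) || any(be[-length(be)] > bs[-1L]))
      stop("record ", id[i], ": blocks must be sorted and non-overlapping")
  }
  x <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = vapply(block_starts, function(b) b[1L], integer(1)),
    end = vapply(block_ends, function(b) b[length(b)], integer(1)),
    align_strand = as.character(align_strand),
    intron_orientation = as.integer(intron_orientation),
    txn_strand = NA_character_,
    stringsAsFactors = FALSE
  )
  x$block_starts <- block_starts
  x$block_ends <- block_ends
  x$n_alignments <- if (is.null(n_alignments)) {
    as.integer(table(x$id)[x$id])
  } else {
    as.integer(n_alignments)
  }
  class(x) <- c("spliced_transcripts", class(x))
  x
}

#' Resolve transcriptional strand from intron orientation
#'
#' The alignment strand of a spliced cDNA record reflects how the read was
#' aligned, not the direction of transcription. A positive intron
#' orientation (splice-site consensus agreeing with the alignment) means the
#' transcriptional direction matches the alignment direction; negative means
#' it is opposite; zero leaves the record `"undetermined"`. Idempotent.
#'
#' @param tx A `spliced_transcripts` data frame.
#' @return The same data frame with `txn_strand` filled in.
#' @export
resolve_txn_strand <- function(tx) {
  flip <- c("+" = "-", "-" = "+")
  tx$txn_strand <- ifelse(
    tx$intron_orientation > 0L, tx$align_strand,
    ifelse(tx$intron_orientation < 0L, flip[tx$align_strand], "undetermined")
  )
  tx
}

#' Transcription start sites of spliced transcripts
#'
#' Width-1 intervals: the alignment start for `"+"` transcripts, the last
#' aligned base for `"-"` transcripts. Records with undetermined strand are
#' an error; drop them (see [resolve_txn_strand()]) before calling.
#'
#' @param tx A strand-resolved `spliced_transcripts` data frame.
#' @return An interval data frame (one width-1 row per record) with an `id`
#'   column.
#' @export
tss_of <- function(tx) {
  if (any(is.na(tx$txn_strand)) || any(!tx$txn_strand %in% c("+", "-"))) {
    bad <- tx$id[is.na(tx$txn_strand) | !tx$txn_strand %in% c("+", "-")]
    stop("cannot place a TSS for records with undetermined strand: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  pos <- ifelse(tx$txn_strand == "+", tx$start, tx$end - 1L)
  out <- genomic_interval(tx$chrom, pos, pos + 1L, tx$txn_strand)
  out$id <- tx$id
  out
}

#' Repeat annotation
#'
#' @param chrom,start,end,strand Interval fields (0-based half-open;
#'   strand `"+"`/`"-"`).
#' @param subfamily Repeat subfamily name (e.g. `"L1HS"`, `"L1PA4"`,
#'   `"L1M5"`).
#' @param family Repeat family (e.g. `"L1"`); must be non-empty.
#' @return A `repeat_elements` data frame.
#' @export
repeat_elements <- function(chrom, start, end, strand, subfamily, family) {
  if (any(!nzchar(family))) stop("repeat family must be non-empty")
  if (any(!strand %in% c("+", "-"))) stop("repeat strand must be + or -")
  x <- genomic_interval(chrom, start, end, strand)
  x$subfamily <- as.character(subfamily)
  x$family <- as.character(family)
  class(x) <- c("repeat_elements", class(x))
  x
}

#' Gene models
#'
#' One row per gene with exon blocks as list columns. The TSS is the start
#' of the first exon for `"+"` genes and the last base of the last exon for
#' `"-"` genes.
#'
#' @param gene_id,chrom,strand Character vectors.
#' @param exon_starts,exon_ends Lists of integer vectors (sorted,
#'   non-overlapping, 0-based half-open).
#' @return A `gene_models` data frame with a computed `tss` column.
#' @export
gene_models <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  exon_starts <- lapply(exon_starts, as.integer)
  exon_ends <- lapply(exon_ends, as.integer)
  if (any(!strand %in% c("+", "-"))) stop("gene strand must be + or -")
  for (i in seq_along(gene_id)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (any(es >= ee) || is.unsorted(es, strictly = TRUE))
      stop("gene ", gene_id[i], ": malformed exons")
  }
  x <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand), stringsAsFactors = FALSE
  )
  x$exon_starts <- exon_starts
  x$exon_ends <- exon_ends
  x$tss <- ifelse(
    strand == "+",
    vapply(exon_starts, function(e) e[1L], integer(1)),
    vapply(exon_ends, function(e) e[length(e)] - 1L, integer(1))
  )
  class(x) <- c("gene_models", class(x))
  x
}

# internal: explode blocks of a spliced_transcripts / gene_models table into
# one interval row per block, keeping the parent row index
explode_blocks <- function(chrom, starts_list, ends_list) {
  n <- lengths(starts_list)
  data.frame(
    chrom = rep(chrom, n),
    start = unlist(starts_list, use.names = FALSE),
    end = unlist(ends_list, use.names = FALSE),
    parent = rep(seq_along(n), n),
    block = sequence(n),
    stringsAsFactors = FALSE
  )
}
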