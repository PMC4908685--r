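#' Default local-alignment scoring
#'
#' Match +2, mismatch -3, gap open -5, gap extend -2. A gap of length L
#' costs `open + L * extend` (the first gapped base pays both penalties).
#' @return Named list of scoring parameters.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

# substitution matrix over A/C/G/T/N; N mismatches everything
.subst_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

#' Affine-gap local alignment of a query against a consensus
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment()])
#' of the query in both orientations against the consensus; the better
#' score wins, ties going to the forward orientation. Query coordinates are
#' reported on the original (forward) query, so for reverse-complement
#' alignments `query_start = 0` still means the query 5' end.
#'
#' @param query,consensus Character scalars or `DNAString`s.
#' @param scoring See [align_scoring()].
#' @param min_score Alignments scoring below this are reported as
#'   unmappable (`score = 0`, empty spans). Default 40.
#' @param first_nt Align only the first `first_nt` bases of the query (the
#'   5' end is what is being placed); `Inf` to disable. Default 1000.
#' @return List of class `local_alignment`: `score`, `orientation`
#'   (`"forward"`/`"revcomp"`), `consensus_start`, `consensus_end`,
#'   `query_start`, `query_end` (all 0-based half-open), `mappable`.
#' @export
local_align <- function(query, consensus, scoring = align_scoring(),
                        min_score = 40, first_nt = 1000) {
  query <- as.character(query)
  consensus <- as.character(consensus)
  if (!nzchar(query) || !nzchar(consensus)) stop("empty sequence")
  if (is.finite(first_nt) && nchar(query) > first_nt) {
    query <- substr(query, 1L, first_nt)
  }
  qlen <- nchar(query)
  mat <- .subst_matrix(scoring)
  run <- function(q) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(q),
      subject = Biostrings::DNAString(consensus),
      type = "local", substitutionMatrix = mat,
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
    )
  }
  fwd <- run(query)
  rev <- run(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(query))))
  use_rev <- BiocGenerics::score(rev) > BiocGenerics::score(fwd)
  aln <- if (use_rev) rev else fwd
  sc <- BiocGenerics::score(aln)
  out <- list(score = max(0, sc),
              orientation = if (use_rev) "revcomp" else "forward",
              consensus_start = NA_integer_, consensus_end = NA_integer_,
              query_start = NA_integer_, query_end = NA_integer_,
              mappable = FALSE)
  class(out) <- "local_alignment"
  if (sc < min_score) {
    out$score <- 0
    return(out)
  }
  ps <- IRanges::start(Biostrings::pattern(aln))
  pe <- IRanges::end(Biostrings::pattern(aln))
  ss <- IRanges::start(Biostrings::subject(aln))
  se <- IRanges::end(Biostrings::subject(aln))
  out$consensus_start <- ss - 1L
  out$consensus_end <- se
  if (use_rev) {
    # map aligned span of the reverse-complemented query back onto the
    # original query coordinates
    out$query_start <- qlen - pe
    out$query_end <- qlen - ps + 1L
  } else {
    out$query_start <- ps - 1L
    out$query_end <- pe
  }
  out$mappable <- TRUE
  out
}

#' TSS position on the consensus, as a percentage
#'
#' The transcript 5'-most aligned base maps to `consensus_start` for
#' forward alignments and to `consensus_end - 1` for reverse-complement
#' alignments (the antisense-promoter case: the transcript reads off the
#' consensus antisense strand, so its 5' end sits at the highest aligned
#' consensus coordinate).
#'
#' @param aln A `local_alignment`.
#' @param consensus_length Full consensus length in bp.
#' @return Percent position in `[0, 100]`.
#' @export
tss_percent_position <- function(aln, consensus_length) {
  if (!isTRUE(aln$mappable)) stop("unmappable alignment: no TSS position")
  pos <- if (aln$orientation == "forward") {
    aln$consensus_start
  } else {
    aln$consensus_end - 1L
  }
  100 * pos / consensus_length
}

#' Consensus TSS-position profiles per subfamily age class
#'
#' Aligns each accepted transcript sequence to the consensus of its
#' subfamily age class and collects the TSS percent positions.
#'
#' @param classes Character vector: subfamily age class per transcript.
#' @param seqs Character vector of transcript sequences (transcription
#'   orientation), parallel to `classes`.
#' @param consensus Named character vector or `DNAStringSet`, one consensus
#'   per class present in `classes`.
#' @param scoring,min_score,first_nt Passed to [local_align()].
#' @return List of class `tss_profiles`: per class, a list with
#'   `positions` (percent values of mappable transcripts) and
#'   `n_unmappable`.
#' @export
build_profile <- function(classes, seqs, consensus,
                          scoring = align_scoring(), min_score = 40,
                          first_nt = 1000) {
  if (methods::is(consensus, "XStringSet")) {
    consensus <- stats::setNames(as.character(consensus), names(consensus))
  }
  missing <- setdiff(unique(classes), names(consensus))
  if (length(missing)) {
    stop("no consensus sequence for class(es): ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(split(seq_along(classes), classes), function(idx) {
    cls <- classes[idx[1L]]
    cons <- consensus[[cls]]
    clen <- nchar(cons)
    pos <- numeric(0)
    n_un <- 0L
    for (i in idx) {
      aln <- local_align(seqs[i], cons, scoring, min_score, first_nt)
      if (aln$mappable) {
        pos <- c(pos, tss_percent_position(aln, clen))
      } else {
        n_un <- n_un + 1L
      }
    }
    list(positions = pos, n_unmappable = n_un)
  })
  class(out) <- "tss_profiles"
  out
}
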