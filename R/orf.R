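STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find ATG-initiated open reading frames on a transcript
#'
#' Scans the three forward frames of a transcript sequence (assumed to be
#' in transcription orientation) and reports all maximal ATG-initiated
#' ORFs: within each frame, the first ATG after the previous terminator
#' opens an ORF running to the next stop codon (or to the end of the
#' sequence, flagged `has_stop = FALSE`). A codon containing `N` ends
#' translation at the preceding codon. Peptide lengths exclude the stop
#' codon. A transcript is called coding when any ORF reaches 100 amino
#' acids.
#'
#' @param seq A single nucleotide sequence (character scalar, A/C/G/T/N).
#' @param min_aa Coding-call threshold in amino acids (default 100).
#' @return Data frame with one row per ORF: `frame` (0/1/2), `start_nt`,
#'   `end_nt` (0-based half-open on the transcript, including the stop
#'   codon when present), `peptide_length_aa`, `has_stop`,
#'   `is_coding_call`.
#' @examples
#' find_orfs(paste0("ATG", strrep("GCT", 99), "TAA"))
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  empty <- data.frame(frame = integer(), start_nt = integer(),
                      end_nt = integer(), peptide_length_aa = integer(),
                      has_stop = logical(), is_coding_call = logical())
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) return(empty)
  out <- list()
  for (frame in 0:2) {
    n_codon <- (n - frame) %/% 3L
    if (n_codon < 1L) next
    pos <- frame + 3L * (seq_len(n_codon) - 1L) # 0-based codon starts
    codons <- substring(seq, pos + 1L, pos + 3L)
    is_stop <- codons %in% STOP_CODONS
    has_n <- grepl("[^ACGT]", codons)
    # terminators partition the frame; an N-codon ends translation without
    # counting as a stop
    term <- which(is_stop | has_n)
    seg_start <- c(1L, term + 1L)
    for (s in seq_along(seg_start)) {
      lo <- seg_start[s]
      hi <- if (s <= length(term)) term[s] - 1L else n_codon
      if (lo > hi) next
      atg <- which(codons[lo:hi] == "ATG")
      if (length(atg) == 0L) next
      first <- lo + atg[1L] - 1L
      stopped <- s <= length(term) && is_stop[term[s]]
      len <- hi - first + 1L
      end_nt <- pos[hi] + 3L + if (stopped) 3L else 0L
      out[[length(out) + 1L]] <- data.frame(
        frame = frame, start_nt = pos[first], end_nt = end_nt,
        peptide_length_aa = len, has_stop = stopped,
        is_coding_call = len >= min_aa
      )
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start_nt, res$frame), , drop = FALSE]
}

#' Coding fraction of a transcript cohort
#'
#' @param seqs Named character vector (or [Biostrings::DNAStringSet]) of
#'   transcript sequences in transcription orientation.
#' @param min_aa Coding-call threshold (default 100 aa).
#' @return List: `n`, `n_coding`, `fraction`, and `peptide_aa`
#'   (mean/min/max over the longest called peptide of each coding
#'   transcript).
#' @export
coding_fraction <- function(seqs, min_aa = 100L) {
  if (length(seqs) == 0L) stop("empty cohort")
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  best <- vapply(seqs, function(s) {
    orfs <- find_orfs(s, min_aa = min_aa)
    if (nrow(orfs) == 0L) 0L else max(orfs$peptide_length_aa)
  }, integer(1))
  coding <- best >= min_aa
  pep <- best[coding]
  list(
    n = length(seqs), n_coding = sum(coding),
    fraction = mean(coding), is_coding = unname(coding),
    peptide_aa = if (length(pep)) {
      c(mean = mean(pep), min = min(pep), max = max(pep))
    } else {
      c(mean = NA_real_, min = NA_real_, max = NA_real_)
    }
  )
}
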