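#' Read JASPAR-format count matrices
#'
#' Parses the JASPAR text format: a `>ID name` header followed by four
#' rows `A [ 4 19 0 ... ]` (brackets optional), rows in A/C/G/T order or
#' labelled. Several matrices per file are supported.
#'
#' @param path Path to the JASPAR-format file.
#' @return Named list of `pwm` objects (see [pwm()]).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR header ('>') found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    id <- strsplit(sub("^>\\s*", "", lines[heads[h]]), "\\s+")[[1]][1]
    body <- lines[(heads[h] + 1L):(bounds[h + 1L] - 1L)]
    rows <- lapply(body[seq_len(min(4L, length(body)))], function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      base <- NA_character_
      if (parts[1] %in% c("A", "C", "G", "T")) {
        base <- parts[1]
        parts <- parts[-1]
      }
      list(base = base, counts = as.numeric(parts))
    })
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    labels <- vapply(rows, `[[`, character(1), "base")
    rownames(counts) <- if (all(!is.na(labels))) labels else c("A", "C", "G", "T")
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    out[[id]] <- pwm(counts, motif_id = id)
  }
  out
}

#' Position weight matrix
#'
#' @param counts 4 x W non-negative matrix, rows A/C/G/T.
#' @param motif_id Identifier string.
#' @param background Length-4 background probabilities (sum to 1),
#'   default uniform.
#' @param pseudocount Added per cell before column normalization; the
#'   default scales with the column count sum (1% of it).
#' @return Object of class `pwm` with the log2-odds matrix precomputed.
#' @export
pwm <- function(counts, motif_id = "motif", background = rep(0.25, 4),
                pseudocount = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM counts must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 1L) stop("PWM must have width >= 1")
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  rownames(counts) <- c("A", "C", "G", "T")
  csum <- colSums(counts)
  if (is.null(pseudocount)) pseudocount <- 0.01 * csum
  pseudocount <- rep_len(pseudocount, ncol(counts))
  prob <- sweep(counts, 2, pseudocount / 4, `+`)
  prob <- sweep(prob, 2, colSums(prob), `/`)
  lo <- log2(prob / background)
  structure(
    list(motif_id = motif_id, counts = counts, background = background,
         pseudocount = pseudocount, log_odds = lo,
         min_score = sum(apply(lo, 2, min)),
         max_score = sum(apply(lo, 2, max))),
    class = "pwm"
  )
}

#' Reverse-complement a PWM
#' @param x A `pwm`.
#' @return The reverse-complemented `pwm` (columns reversed, A<->T, C<->G).
#' @export
reverse_complement_pwm <- function(x) {
  rc <- x$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(x$counts))),
                 drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  pwm(rc, motif_id = paste0(x$motif_id, "_rc"), background = x$background,
      pseudocount = rev(x$pseudocount))
}

# score every window of seq against the log-odds matrix; windows containing
# a non-ACGT base score -Inf
.window_scores <- function(seq, log_odds) {
  W <- ncol(log_odds)
  n <- nchar(seq)
  if (n < W) return(numeric(0))
  idx <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  nwin <- n - W + 1L
  scores <- numeric(nwin)
  ok <- rep(TRUE, nwin)
  for (j in seq_len(W)) {
    b <- idx[j:(j + nwin - 1L)]
    bad <- is.na(b)
    ok <- ok & !bad
    b[bad] <- 1L
    scores <- scores + log_odds[cbind(b, j)]
  }
  scores[!ok] <- -Inf
  scores
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Scores every window on both strands with the log2-odds matrix and keeps
#' windows whose relative score, `(score - min) / (max - min)` with
#' min/max the PWM's attainable extremes, reaches the threshold. Minus
#' strand windows are scored with the reverse-complemented PWM at the same
#' forward-sequence coordinates.
#'
#' @param seq Character scalar to scan.
#' @param x A `pwm`.
#' @param threshold Relative score in (0, 1]; the conventional cutoff for
#'   transcription-factor site scanning is 0.9.
#' @return Data frame of hits sorted by start: `motif_id`, `start`, `end`
#'   (0-based half-open on the forward sequence), `strand`, `score`
#'   (log2-odds), `relative_score`.
#' @export
scan_pwm <- function(seq, x, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  W <- ncol(x$log_odds)
  empty <- data.frame(motif_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), relative_score = numeric())
  if (nchar(seq) < W) return(empty)
  rng <- x$max_score - x$min_score
  hit_frame <- function(scores, strand) {
    rel <- (scores - x$min_score) / rng
    keep <- which(rel >= threshold)
    if (length(keep) == 0L) return(empty)
    data.frame(motif_id = x$motif_id, start = keep - 1L,
               end = keep - 1L + W, strand = strand,
               score = scores[keep], relative_score = rel[keep])
  }
  fwd <- hit_frame(.window_scores(seq, x$log_odds), "+")
  rc <- reverse_complement_pwm(x)
  rev <- hit_frame(.window_scores(seq, rc$log_odds), "-")
  out <- rbind(fwd, rev)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format motif hits as a 1-based inclusive site table
#'
#' Converts 0-based half-open hit coordinates to the 1-based inclusive
#' dialect used in site reports ("448 to 453").
#'
#' @param hits Data frame from [scan_pwm()].
#' @return Data frame with `motif_id`, `start`, `end` (1-based inclusive),
#'   `strand`, `relative_score`, `site` (formatted string).
#' @export
report_sites <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(motif_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      relative_score = numeric(), site = character()))
  }
  data.frame(
    motif_id = hits$motif_id,
    start = hits$start + 1L, end = hits$end,
    strand = hits$strand, relative_score = hits$relative_score,
    site = paste(hits$start + 1L, "to", hits$end),
    stringsAsFactors = FALSE
  )
}
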