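#' A set of aligned reads with a library size
#'
#' @param reads Data frame with columns `chrom` (reference name), `start`,
#'   `end` (0-based half-open), `strand`.
#' @param library_size Total mapped reads in the library (for RPM
#'   normalization); must be at least the number of records.
#' @return Object of class `read_set`.
#' @export
read_set <- function(reads, library_size) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (library_size < nrow(reads)) {
    stop("library_size must be >= number of read records")
  }
  structure(list(reads = reads, library_size = as.numeric(library_size)),
            class = "read_set")
}

#' Per-base read coverage in RPM
#'
#' `value[i]` is the number of reads overlapping base `i`, scaled by
#' `1e6 / library_size`. Reads are counted by full-interval overlap, each
#' supplied record once. Read parts outside `[0, reference_length)` are
#' clipped.
#'
#' @param rs A `read_set` whose reads all lie on one reference.
#' @param reference_length Length of the reference in bp.
#' @return Numeric vector of length `reference_length` (class
#'   `signal_track` semantics: plain per-bp values).
#' @export
coverage_rpm <- function(rs, reference_length) {
  if (rs$library_size <= 0) stop("library_size must be > 0")
  r <- rs$reads
  r <- r[r$end > 0 & r$start < reference_length, , drop = FALSE]
  if (nrow(r) == 0L) return(numeric(reference_length))
  ir <- IRanges::IRanges(start = pmax(r$start, 0L) + 1L,
                         end = pmin(r$end, reference_length))
  cov <- IRanges::coverage(ir, width = reference_length)
  as.numeric(cov) * 1e6 / rs$library_size
}

#' Per-base log2 fold-change track
#'
#' `log2((chip + eps) / (input + eps))` elementwise. The pseudo-RPM `eps`
#' keeps zero-coverage bases finite.
#'
#' @param chip,input Equal-length numeric per-bp tracks (RPM).
#' @param eps Pseudocount in RPM units (default 0.25).
#' @return Numeric track of the same length.
#' @export
log2fc_track <- function(chip, input, eps = 0.25) {
  if (length(chip) != length(input)) stop("track length mismatch")
  log2((chip + eps) / (input + eps))
}

#' LOESS-smooth a per-bp track
#'
#' Local degree-1 (linear) regression with tricube weights over the
#' nearest `span * n` points, evaluated at every position. Constant and
#' exactly linear tracks are reproduced to machine tolerance.
#'
#' @param track Numeric per-bp track, length >= 10.
#' @param span LOESS span (alpha) in (0, 1]; default 0.1.
#' @return Smoothed numeric track of the same length.
#' @export
loess_smooth <- function(track, span = 0.1) {
  n <- length(track)
  if (n < 10L) stop("track too short to smooth (need >= 10 points)")
  stopifnot(span > 0, span <= 1)
  x <- seq_len(n)
  fit <- stats::loess(track ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' TSS metaprofile: binned, input-subtracted RPM around start sites
#'
#' For every TSS, read depth in 20 bins of 100 bp across
#' `[TSS - 1000, TSS + 1000)` is computed in RPM (full-interval overlap
#' counting); minus-strand windows are reversed so bin 1 is always 1000 bp
#' upstream in transcription orientation. Bins are averaged over TSSs; if
#' an input read set is supplied its per-bin RPM profile is subtracted.
#' TSS windows extending outside the reference are dropped and counted.
#'
#' @param tss Data frame with `chrom`, `pos` (0-based TSS position) and
#'   `strand`.
#' @param chip A `read_set`.
#' @param input Optional `read_set` of the input/control library.
#' @param strand_match If `TRUE`, only reads on the TSS strand are counted
#'   (nascent-transcription mode for GRO-seq style libraries).
#' @param ref_lengths Named vector of reference lengths used for the
#'   out-of-bounds check.
#' @param flank Half-window in bp (default 1000).
#' @param binsize Bin width in bp (default 100).
#' @return List of class `meta_profile`: `bin_mid` (window-relative bin
#'   centers), `value` (mean input-subtracted RPM per bin), `n_tss`,
#'   `n_dropped`.
#' @export
tss_metaprofile <- function(tss, chip, input = NULL, strand_match = FALSE,
                            ref_lengths = NULL, flank = 1000L,
                            binsize = 100L) {
  nbin <- as.integer(2L * flank / binsize)
  ok <- rep(TRUE, nrow(tss))
  if (!is.null(ref_lengths)) {
    ok <- tss$pos - flank >= 0L &
      tss$pos + flank <= ref_lengths[tss$chrom]
  } else {
    ok <- tss$pos - flank >= 0L
  }
  n_dropped <- sum(!ok)
  tss <- tss[ok, , drop = FALSE]
  if (nrow(tss) == 0L) stop("no TSS windows inside the reference")

  bin_matrix <- function(rs) {
    r <- rs$reads
    # all bins of all windows as one range set, then count reads per bin
    starts <- rep(tss$pos - flank, each = nbin) +
      rep(seq_len(nbin) - 1L, times = nrow(tss)) * binsize
    bins <- data.frame(
      chrom = rep(tss$chrom, each = nbin),
      start = starts, end = starts + binsize,
      window = rep(seq_len(nrow(tss)), each = nbin),
      strand = rep(tss$strand, each = nbin)
    )
    reads_iv <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                           strand = r$strand)
    hits <- bulk_intersect(bins, reads_iv)
    if (strand_match && nrow(hits) > 0L) {
      hits <- hits[bins$strand[hits$query] == r$strand[hits$subject], ,
                   drop = FALSE]
    }
    counts <- matrix(0, nrow(tss), nbin)
    if (nrow(hits) > 0L) {
      tab <- table(hits$query)
      q <- as.integer(names(tab))
      counts[cbind(bins$window[q], (q - 1L) %% nbin + 1L)] <- as.numeric(tab)
    }
    # flip minus-strand windows so bin 1 = upstream
    minus <- tss$strand == "-"
    counts[minus, ] <- counts[minus, rev(seq_len(nbin)), drop = FALSE]
    counts * 1e6 / rs$library_size
  }

  prof <- colMeans(bin_matrix(chip))
  if (!is.null(input)) prof <- prof - colMeans(bin_matrix(input))
  structure(
    list(bin_mid = seq(-flank + binsize / 2, flank - binsize / 2,
                       by = binsize),
         value = unname(prof), n_tss = nrow(tss), n_dropped = n_dropped),
    class = "meta_profile"
  )
}
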