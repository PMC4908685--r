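# Independent reference implementations used only to check the package's
# fast paths. Deliberately naive: quadratic loops, no vectorization tricks.

# all-pairs interval intersection
oracle_intersect <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          min(query$end[i], subject$end[j]) -
          max(query$start[i], subject$start[j]) > 0) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) return(data.frame(query = integer(),
                                           subject = integer()))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

random_intervals <- function(n, n_chrom = 2, span = 1000) {
  s <- sample.int(span, n, replace = TRUE)
  genomic_interval(paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
                   s, s + sample.int(50, n, replace = TRUE))
}

# Gotoh local alignment score, affine gaps: a gap of length L costs
# open + L * extend (both negative); plain O(nm) dynamic program
oracle_local_score <- function(a, b, match = 2, mismatch = -3,
                               open = -5, extend = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      Ix[i, j] <- max(M[i - 1, j] + open + extend, Ix[i - 1, j] + extend)
      Iy[i, j] <- max(M[i, j - 1] + open + extend, Iy[i, j - 1] + extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# every ATG in every frame, translated codon by codon with substring
oracle_orfs <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (start in seq_len(max(0, n - 2))) {
    if (substring(seq, start, start + 2) != "ATG") next
    pos <- start
    len <- 0L
    has_stop <- FALSE
    while (pos + 2 <= n) {
      codon <- substring(seq, pos, pos + 2)
      if (grepl("[^ACGT]", codon)) break
      if (codon %in% stops) { has_stop <- TRUE; break }
      len <- len + 1L
      pos <- pos + 3L
    }
    end_nt <- (start - 1L) + 3L * len + if (has_stop) 3L else 0L
    found[[length(found) + 1L]] <- data.frame(
      frame = (start - 1L) %% 3L, start_nt = start - 1L, end_nt = end_nt,
      peptide_length_aa = len, has_stop = has_stop,
      is_coding_call = len >= min_aa
    )
  }
  if (length(found) == 0L) {
    return(data.frame(frame = integer(), start_nt = integer(),
                      end_nt = integer(), peptide_length_aa = integer(),
                      has_stop = logical(), is_coding_call = logical()))
  }
  all <- do.call(rbind, found)
  # keep maximal ORFs: drop any ATG nested inside a longer ORF ending at
  # the same point in the same frame
  keep <- rep(TRUE, nrow(all))
  for (k in seq_len(nrow(all))) {
    same <- all$frame == all$frame[k] & all$end_nt == all$end_nt[k] &
      all$start_nt < all$start_nt[k]
    if (any(same)) keep[k] <- FALSE
  }
  res <- all[keep, , drop = FALSE]
  res <- res[order(res$start_nt, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-window PWM scores by explicit loops
oracle_pwm_hits <- function(seq, x, threshold) {
  W <- ncol(x$log_odds)
  chars <- strsplit(toupper(seq), "")[[1]]
  score_at <- function(window, lo) {
    s <- 0
    for (j in seq_len(W)) {
      k <- match(window[j], c("A", "C", "G", "T"))
      if (is.na(k)) return(-Inf)
      s <- s + lo[k, j]
    }
    s
  }
  rc <- reverse_complement_pwm(x)
  rows <- list()
  for (i in seq_len(length(chars) - W + 1)) {
    win <- chars[i:(i + W - 1)]
    for (strand in c("+", "-")) {
      lo <- if (strand == "+") x$log_odds else rc$log_odds
      sc <- score_at(win, lo)
      rel <- (sc - x$min_score) / (x$max_score - x$min_score)
      if (rel >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + W, strand = strand,
          score = sc, relative_score = rel
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      relative_score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# textbook BH step-up: q_(k) = min over i >= k of p_(i) * n / i
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# chi-squared upper tail by numerical integration of the density
oracle_chi2_p <- function(stat, df) {
  stats::integrate(function(x) stats::dchisq(x, df), stat, Inf,
                   rel.tol = 1e-12)$value
}

# per-base coverage by explicit counting
oracle_coverage <- function(reads, len, library_size) {
  v <- numeric(len)
  for (i in seq_len(nrow(reads))) {
    lo <- max(reads$start[i] + 1L, 1L)
    hi <- min(reads$end[i], len)
    if (lo <= hi) v[lo:hi] <- v[lo:hi] + 1
  }
  v * 1e6 / library_size
}
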