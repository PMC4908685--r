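#' Configuration for the synthetic cohort generator
#'
#' The generator lays genes out on fixed-size slots along a small synthetic
#' genome and plants, with known ground truth: true antisense-promoter
#' chimeras (TSS inside an antisense L1, spliced into a gene exon),
#' exonization decoys (an ASP-lookalike candidate whose anchor L1 is also
#' carried exon-L1-exon by an independent transcript), ordinary gene
#' transcripts, records with undetermined orientation, multi-alignment
#' records, consensus-derived L1 sequences with planted motif sites, and
#' promoter-shaped read pileups at the planted TSSs.
#'
#' @param seed Integer seed fixing every output.
#' @param n_chrom,chrom_len Synthetic genome shape.
#' @param n_chimera,n_exonization,n_plain,n_zero_orientation Planted record
#'   counts (true chimeras, exonization decoy candidates, plain gene
#'   transcripts, undetermined-orientation records).
#' @param n_multi_alignment How many of the true chimeras carry a second
#'   alignment of the same id elsewhere in the genome.
#' @param class_mix Probabilities over the four subfamily age classes for
#'   planted anchor L1s.
#' @param sense_fraction Fraction of chimeras sense to their cognate gene.
#' @param coding_fraction Probability that a chimera transcript carries a
#'   planted ORF (>= 100 aa starting with ATG).
#' @param mutation_rate Per-base substitution rate applied to
#'   consensus-derived genomic L1 sequence.
#' @param young_tss_range Antisense TSS position (bp on the consensus) for
#'   L1HS / L1PA2_8 anchors, drawn uniformly (5' UTR placement).
#' @param ancient_tss_frac_range TSS position as a fraction of consensus
#'   length for the two ancient classes (3'-end placement).
#' @param consensus_len Named consensus lengths per class.
#' @param n_background_l1 Unrelated L1 elements scattered in spare slots.
#' @param n_plain_genes Genes over which plain transcripts distribute.
#' @param sequences Generate genome/transcript/consensus sequences
#'   (set `FALSE` to skip when only intervals are needed).
#' @param reads Generate ChIP/input/GRO read sets (requires TSSs; implies
#'   nothing about sequences).
#' @param chip_reads_per_tss Mean reads planted downstream of each TSS.
#' @param read_len,pileup_span Read length and promoter pileup width (bp).
#' @param library_size Library size used for every generated read set.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 4L, chrom_len = 600000L,
                       n_chimera = 50L, n_exonization = 20L,
                       n_plain = 30L, n_zero_orientation = 5L,
                       n_multi_alignment = 5L,
                       class_mix = c(L1HS = 0.05, L1PA2_8 = 0.30,
                                     ancient_primate = 0.20,
                                     ancient_mammalian = 0.45),
                       sense_fraction = 0.92,
                       coding_fraction = 0.271,
                       mutation_rate = 0.05,
                       young_tss_range = c(20, 600),
                       ancient_tss_frac_range = c(0.80, 0.98),
                       consensus_len = c(L1HS = 6064L, L1PA2_8 = 6100L,
                                         ancient_primate = 6000L,
                                         ancient_mammalian = 5900L),
                       n_background_l1 = 16L,
                       n_plain_genes = 10L,
                       sequences = TRUE, reads = FALSE,
                       chip_reads_per_tss = 30L, read_len = 36L,
                       pileup_span = 200L, library_size = 1e6) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("n_chimera", "n_exonization", "n_plain",
                       "n_zero_orientation", "n_multi_alignment")]) < 0L)) {
    stop("planted counts must be >= 0")
  }
  if (cfg$n_multi_alignment > cfg$n_chimera) {
    stop("n_multi_alignment cannot exceed n_chimera")
  }
  if (cfg$mutation_rate < 0 || cfg$mutation_rate >= 1) {
    stop("mutation_rate must lie in [0, 1)")
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must sum to 1")
  }
  if (cfg$n_chimera > 0L && any(consensus_len <= 0L)) {
    stop("chimeras requested but a consensus length is not positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

# ---- internal sequence helpers ---------------------------------------------

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(s)
  v <- strsplit(s, "")[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  v[hit] <- vapply(v[hit], function(b) sample(alt[[b]], 1L), character(1))
  paste(v, collapse = "")
}

# filler guaranteed free of ORFs >= ~20 codons: random chunks interleaved
# with a cassette containing a stop codon in all three frames
.stop_rich <- function(n) {
  cassette <- "TAAATAAATAA"
  parts <- character(0)
  tot <- 0L
  while (tot < n) {
    chunk <- .random_seq(sample(30:50, 1L))
    parts <- c(parts, chunk, cassette)
    tot <- tot + nchar(chunk) + nchar(cassette)
  }
  substr(paste(parts, collapse = ""), 1L, n)
}

# exon cassette of length `n` with one planted ORF of `len_aa` codons
# (ATG + body + TAA) embedded in stop-rich filler
.orf_cassette <- function(n, len_aa) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  body_pool <- setdiff(codons, c(STOP_CODONS, "ATG"))
  orf <- paste0("ATG",
                paste(sample(body_pool, len_aa - 1L, replace = TRUE),
                      collapse = ""),
                "TAA")
  if (nchar(orf) + 60L > n) stop("exon too short for planted ORF")
  pre <- .stop_rich(45L)
  post <- .stop_rich(n - 45L - nchar(orf))
  paste0(pre, orf, post)
}

#' Standalone transcript cohort with a planted coding rate
#'
#' Generates transcript-like sequences where each is coding (one planted
#' ORF of 100-268 aa, mean about 140) with probability `coding_fraction`,
#' and guaranteed free of 100-aa ORFs otherwise.
#'
#' @param n Number of sequences.
#' @param coding_fraction Bernoulli probability of planting an ORF.
#' @param len Sequence length (default 900 nt).
#' @param seed Optional seed.
#' @return List: `seqs` (character), `coding` (logical ground truth),
#'   `planted_aa` (integer, NA for non-coding).
#' @export
sim_transcript_seqs <- function(n, coding_fraction = 0.271, len = 900L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coding <- stats::runif(n) < coding_fraction
  planted <- rep(NA_integer_, n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (coding[i]) {
      aa <- min(100L + stats::rgeom(1L, 1 / 40), 268L)
      planted[i] <- aa
      seqs[i] <- .orf_cassette(len, aa)
    } else {
      seqs[i] <- .stop_rich(len)
    }
  }
  list(seqs = seqs, coding = coding, planted_aa = planted)
}

# subfamily names drawn per age class
.subfamily_name <- function(class) {
  pool <- switch(class,
    L1HS = c("L1HS", "L1PA1"),
    L1PA2_8 = paste0("L1PA", 2:8),
    ancient_primate = c("L1PA10", "L1PA13", "L1PB1", "L1P2"),
    ancient_mammalian = c("L1M2", "L1M5", "L1ME3", "HAL1")
  )
  sample(pool, 1L)
}
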