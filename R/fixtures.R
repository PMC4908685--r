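#' Hand-built micro-fixtures for screen edge cases
#'
#' Tiny deterministic inputs exercising one rule each:
#'
#' * `"exonization_decoy"` — one candidate with its TSS in an antisense L1
#'   plus an independent exon-L1-exon supporter; the candidate must land
#'   in `removed_exonization`.
#' * `"boundary_tss"` — two candidates with the TSS at the last base
#'   inside the L1 (accepted) and one base past its end (rejected);
#'   half-open convention.
#' * `"overlapping_l1"` — the TSS falls inside two overlapping antisense
#'   L1s; the anchor must be the one with the larger overlap with the
#'   TSS-containing block (`expected_anchor` names it).
#' * `"zero_orientation"` — a single record with intron orientation 0 that
#'   must be dropped with count 1.
#'
#' @param name Fixture name.
#' @return List with `transcripts`, `repeats`, `genes` and
#'   fixture-specific expectation fields.
#' @export
make_fixture <- function(name) {
  gene <- gene_models("gene_A", "chr1", "+",
                      list(c(100L, 300L, 5000L)),
                      list(c(200L, 400L, 5500L)))
  switch(
    name,
    exonization_decoy = {
      l1 <- repeat_elements("chr1", 1000L, 1600L, "-", "L1PA4", "L1")
      tx <- spliced_transcripts(
        id = c("cand", "supp"),
        chrom = "chr1", align_strand = c("+", "+"),
        block_starts = list(c(1200L, 5000L), c(300L, 1100L, 5000L)),
        block_ends = list(c(1450L, 5400L), c(400L, 1250L, 5300L)),
        intron_orientation = c(2L, 1L)
      )
      list(transcripts = tx, repeats = l1, genes = gene,
           expected_removed = "cand")
    },
    boundary_tss = {
      l1 <- repeat_elements("chr1", 1000L, 1600L, "-", "L1PA4", "L1")
      tx <- spliced_transcripts(
        id = c("inside", "outside"),
        chrom = "chr1", align_strand = c("+", "+"),
        block_starts = list(c(1599L, 5000L), c(1600L, 5000L)),
        block_ends = list(c(1800L, 5400L), c(1800L, 5400L)),
        intron_orientation = c(1L, 1L)
      )
      list(transcripts = tx, repeats = l1, genes = gene,
           expected_accepted = "inside")
    },
    overlapping_l1 = {
      l1 <- repeat_elements("chr1", c(1000L, 1150L), c(1300L, 1700L),
                            c("-", "-"), c("L1M5", "L1PA3"), "L1")
      tx <- spliced_transcripts(
        id = "cand", chrom = "chr1", align_strand = "+",
        block_starts = list(c(1200L, 5000L)),
        block_ends = list(c(1450L, 5400L)),
        intron_orientation = 1L
      )
      # block [1200,1450): 100 bp in L1M5 vs 250 bp in L1PA3
      list(transcripts = tx, repeats = l1, genes = gene,
           expected_anchor = "L1PA3")
    },
    zero_orientation = {
      l1 <- repeat_elements("chr1", 1000L, 1600L, "-", "L1PA4", "L1")
      tx <- spliced_transcripts(
        id = "ambig", chrom = "chr1", align_strand = "+",
        block_starts = list(c(1200L, 5000L)),
        block_ends = list(c(1450L, 5400L)),
        intron_orientation = 0L
      )
      list(transcripts = tx, repeats = l1, genes = gene,
           expected_dropped = 1L)
    },
    stop("unknown fixture: ", name)
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits the generator's outputs in the plain-text formats the readers
#' consume: `transcripts.bed` (BED12) + `orientation.tsv`, `repeats.bed`
#' (BED6 + subfamily + family), `genes.bed` (BED12), `truth.tsv`, and when
#' sequences/reads were generated `consensus.fa`, `transcripts.fa`,
#' `genome.fa` and `reads_<name>.bed`.
#'
#' @param sim An `l1asp_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed12(sim$transcripts, file.path(dir, "transcripts.bed"))
  utils::write.table(
    data.frame(unique(sim$transcripts$id),
               sim$transcripts$intron_orientation[
                 !duplicated(sim$transcripts$id)]),
    file.path(dir, "orientation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write_repeats_bed(sim$repeats, file.path(dir, "repeats.bed"))
  write_genes_bed12(sim$genes, file.path(dir, "genes.bed"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$consensus)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$consensus),
      file.path(dir, "consensus.fa")
    )
    seqs <- sim$tx_seq
    names(seqs) <- make.unique(names(seqs), sep = "#")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                file.path(dir, "transcripts.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                                file.path(dir, "genome.fa"))
  }
  if (!is.null(sim$reads)) {
    for (nm in names(sim$reads)) {
      write_reads_bed(sim$reads[[nm]],
                      file.path(dir, paste0("reads_", nm, ".bed")))
    }
  }
  invisible(dir)
}
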