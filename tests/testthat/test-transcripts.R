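two_block <- function(io, align = "+") {
  spliced_transcripts("t1", "chr1", align, list(c(100L, 400L)),
                      list(c(180L, 500L)), io)
}

test_that("intron orientation converts alignment strand to txn strand", {
  expect_identical(resolve_txn_strand(two_block(3L, "+"))$txn_strand, "+")
  expect_identical(resolve_txn_strand(two_block(-2L, "+"))$txn_strand, "-")
  expect_identical(resolve_txn_strand(two_block(0L, "-"))$txn_strand,
                   "undetermined")
  expect_identical(resolve_txn_strand(two_block(-1L, "-"))$txn_strand, "+")
  # idempotent
  once <- resolve_txn_strand(two_block(2L))
  expect_identical(resolve_txn_strand(once), once)
})

test_that("TSS is the 5' end in transcription orientation", {
  plus <- resolve_txn_strand(two_block(1L, "+"))
  expect_identical(tss_of(plus)[, c("start", "end")],
                   data.frame(start = 100L, end = 101L))
  minus <- resolve_txn_strand(two_block(-1L, "+"))
  expect_identical(tss_of(minus)[, c("start", "end")],
                   data.frame(start = 499L, end = 500L))
  expect_error(tss_of(resolve_txn_strand(two_block(0L))), "undetermined")
})

test_that("TSS lies within the 5'-most block in transcription orientation", {
  set.seed(7)
  for (i in 1:50) {
    nb <- sample(2:5, 1)
    starts <- cumsum(sample(50:300, nb))
    ends <- starts + sample(30:49, nb)
    tx <- resolve_txn_strand(spliced_transcripts(
      "t", "chr1", sample(c("+", "-"), 1), list(starts), list(ends),
      sample(c(-2L, -1L, 1L, 2L), 1)
    ))
    pos <- tss_of(tx)$start
    blk <- if (tx$txn_strand == "+") 1L else nb
    expect_gte(pos, starts[blk])
    expect_lt(pos, ends[blk])
  }
})

test_that("constructor enforces block ordering and non-overlap", {
  expect_error(spliced_transcripts("t", "chr1", "+", list(c(10L, 5L)),
                                   list(c(20L, 30L)), 1L), "sorted")
  expect_error(spliced_transcripts("t", "chr1", "+", list(c(10L, 15L)),
                                   list(c(20L, 30L)), 1L), "sorted")
  expect_error(spliced_transcripts("t", "chr1", "+", list(10L),
                                   list(10L), 1L), "empty block")
})

test_that("BED12 and annotation tables round-trip through disk", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(seed = 3, n_chimera = 8,
                                    n_exonization = 3, n_plain = 5,
                                    n_zero_orientation = 2,
                                    n_multi_alignment = 2,
                                    n_background_l1 = 4,
                                    sequences = FALSE))
  write_sim(sim, dir)
  tx2 <- read_bed12(file.path(dir, "transcripts.bed"),
                    file.path(dir, "orientation.tsv"))
  expect_identical(tx2$id, sim$transcripts$id)
  expect_identical(tx2$block_starts, sim$transcripts$block_starts)
  expect_identical(tx2$block_ends, sim$transcripts$block_ends)
  expect_identical(tx2$align_strand, sim$transcripts$align_strand)
  expect_identical(tx2$intron_orientation,
                   sim$transcripts$intron_orientation)
  expect_identical(tx2$n_alignments, sim$transcripts$n_alignments)
  rep2 <- read_repeats_bed(file.path(dir, "repeats.bed"))
  expect_identical(rep2$start, sim$repeats$start)
  expect_identical(rep2$subfamily, sim$repeats$subfamily)
  g2 <- read_genes_bed12(file.path(dir, "genes.bed"))
  expect_identical(g2$gene_id, sim$genes$gene_id)
  expect_identical(g2$exon_starts, sim$genes$exon_starts)
  expect_identical(g2$tss, sim$genes$tss)
  # screening the re-read files gives the same calls
  r1 <- screen(sim$transcripts, sim$repeats, sim$genes)
  r2 <- screen(tx2, rep2, g2)
  expect_identical(r2$accepted$transcript_id, r1$accepted$transcript_id)
})
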