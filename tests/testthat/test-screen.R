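test_that("subfamily names map onto the four age classes", {
  expect_identical(classify_subfamily("L1HS"), "L1HS")
  expect_identical(classify_subfamily("L1PA1"), "L1HS")
  expect_identical(classify_subfamily("L1PA5"), "L1PA2_8")
  expect_identical(classify_subfamily("L1PA10"), "ancient_primate")
  expect_identical(classify_subfamily("L1PB1"), "ancient_primate")
  expect_identical(classify_subfamily("L1M5"), "ancient_mammalian")
  expect_identical(classify_subfamily("HAL1"), "ancient_mammalian")
  expect_error(classify_subfamily("AluY"), "unmapped.*AluY")
})

test_that("gene-overlap annotation computes orientation and TSS distance", {
  gplus <- gene_models("g", "chr1", "+", list(c(1000L, 8000L)),
                       list(c(1500L, 9000L)))
  a <- annotate_gene_overlap("+", 5000L, gplus, 120L)
  expect_identical(a$relative_orientation, "sense")
  expect_identical(a$tss_distance, 4000L)
  gminus <- gene_models("g", "chr1", "-", list(c(1000L, 8500L)),
                        list(c(1500L, 9001L)))
  b <- annotate_gene_overlap("+", 5000L, gminus, 120L)
  expect_identical(b$relative_orientation, "antisense")
  expect_identical(b$tss_distance, 4000L)
  expect_identical(annotate_gene_overlap("+", 1000L, gplus, 1L)$tss_distance,
                   0L)
})

test_that("exonization structure requires flanking blocks on both sides", {
  l1 <- repeat_elements("chr1", 1000L, 1600L, "-", "L1PA4", "L1")
  mk <- function(starts, ends) {
    resolve_txn_strand(spliced_transcripts("t", "chr1", "+", list(starts),
                                           list(ends), 1L))
  }
  # exon - L1 - exon: middle block inside the antisense L1
  expect_true(is_exonization_support(
    mk(c(300L, 1100L, 5000L), c(400L, 1250L, 5300L)), l1))
  # 5'-most block starts inside the L1: ASP candidate, not exonization
  expect_false(is_exonization_support(
    mk(c(1200L, 5000L), c(1450L, 5300L)), l1))
  # same strand as the L1
  sense_tx <- resolve_txn_strand(spliced_transcripts(
    "t", "chr1", "-", list(c(300L, 1100L, 5000L)),
    list(c(400L, 1250L, 5300L)), 1L))
  expect_false(is_exonization_support(sense_tx, l1))
  # no block overlapping the L1 at all
  expect_false(is_exonization_support(
    mk(c(300L, 5000L), c(400L, 5300L)), l1))
})

test_that("micro-fixtures exercise the screen's edge rules", {
  fx <- make_fixture("exonization_decoy")
  res <- screen(fx$transcripts, fx$repeats, fx$genes)
  expect_identical(nrow(res$accepted), 0L)
  expect_identical(res$removed_exonization$transcript_id,
                   fx$expected_removed)

  fx <- make_fixture("boundary_tss")
  res <- screen(fx$transcripts, fx$repeats, fx$genes)
  expect_identical(res$accepted$transcript_id, fx$expected_accepted)

  fx <- make_fixture("overlapping_l1")
  res <- screen(fx$transcripts, fx$repeats, fx$genes)
  expect_identical(res$accepted$subfamily, fx$expected_anchor)

  fx <- make_fixture("zero_orientation")
  res <- screen(fx$transcripts, fx$repeats, fx$genes)
  expect_identical(res$dropped_zero_orientation, fx$expected_dropped)
  expect_identical(nrow(res$accepted), 0L)

  expect_error(make_fixture("nonsense"), "unknown fixture")
})

test_that("screen recovers planted truth and partitions its input", {
  for (seed in c(21, 22, 23)) {
    sim <- simulate_cohort(sim_config(seed = seed, sequences = FALSE))
    res <- screen(sim$transcripts, sim$repeats, sim$genes)
    want <- sort(sim$truth$id[sim$truth$label == "true_chimera"])
    expect_identical(sort(res$accepted$transcript_id), want)
    expect_identical(
      sort(res$removed_exonization$transcript_id),
      sort(sim$truth$id[sim$truth$label == "exonization_decoy"])
    )
    expect_identical(res$dropped_zero_orientation,
                     sim$config$n_zero_orientation)
    # accepted and removed are disjoint
    expect_length(intersect(res$accepted$transcript_id,
                            res$removed_exonization$transcript_id), 0)
    # multi-alignment records are flagged, not removed
    expect_identical(sum(res$accepted$multi_alignment),
                     as.integer(sim$config$n_multi_alignment))
    # age-class counts sum to the number of accepted calls
    tl <- tally(res)
    expect_identical(sum(tl$per_class), nrow(res$accepted))
    expect_identical(sum(tl$orientation), nrow(res$gene_overlaps))
  }
})

test_that("screen output is invariant under input shuffling", {
  sim <- simulate_cohort(sim_config(seed = 31, n_chimera = 15,
                                    n_exonization = 5, n_plain = 10,
                                    sequences = FALSE))
  res1 <- screen(sim$transcripts, sim$repeats, sim$genes)
  set.seed(1)
  shuf <- sim$transcripts[sample(nrow(sim$transcripts)), ]
  rshuf <- sim$repeats[sample(nrow(sim$repeats)), ]
  res2 <- screen(shuf, rshuf, sim$genes)
  expect_identical(sort(res2$accepted$transcript_id),
                   sort(res1$accepted$transcript_id))
  ov1 <- res1$gene_overlaps[order(res1$gene_overlaps$transcript_id), ]
  ov2 <- res2$gene_overlaps[order(res2$gene_overlaps$transcript_id), ]
  rownames(ov1) <- rownames(ov2) <- NULL
  expect_equal(ov1, ov2)
})

test_that("unresolved strands are an error, empty inputs are not", {
  sim <- simulate_cohort(sim_config(seed = 5, n_chimera = 3,
                                    n_exonization = 0, n_plain = 0,
                                    n_zero_orientation = 0,
                                    n_multi_alignment = 0,
                                    sequences = FALSE))
  tx <- sim$transcripts
  tx$txn_strand <- NA_character_
  tx$intron_orientation <- NULL
  expect_error(screen(tx, sim$repeats, sim$genes))
  res <- screen(sim$transcripts, sim$repeats[0, ], sim$genes)
  expect_identical(nrow(res$accepted), 0L)
})
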