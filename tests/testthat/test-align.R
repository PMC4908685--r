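test_that("an exact substring aligns at its own span with full score", {
  set.seed(301)
  cons <- random_dna(400)
  q <- substr(cons, 101, 150)
  aln <- local_align(q, cons)
  expect_identical(aln$orientation, "forward")
  expect_equal(aln$score, 50 * 2)
  expect_identical(aln$consensus_start, 100L)
  expect_identical(aln$consensus_end, 150L)
  expect_identical(aln$query_start, 0L)
  expect_identical(aln$query_end, 50L)
})

test_that("a reverse-complement substring aligns at the same span", {
  set.seed(302)
  cons <- random_dna(400)
  q <- revcomp_chr(substr(cons, 101, 150))
  aln <- local_align(q, cons)
  expect_identical(aln$orientation, "revcomp")
  expect_equal(aln$score, 100)
  expect_identical(aln$consensus_start, 100L)
  expect_identical(aln$consensus_end, 150L)
  # the query 5' end is the last-aligned base in revcomp orientation
  expect_identical(aln$query_start, 0L)
})

test_that("scores equal the quadratic DP oracle on random pairs", {
  set.seed(303)
  for (i in 1:100) {
    a <- random_dna(sample(30:60, 1))
    b <- random_dna(sample(30:60, 1))
    if (i %% 2 == 0) { # plant a shared (sometimes mutated) substring
      sub <- substr(b, 5, 5 + sample(10:25, 1))
      substr(a, 3, 2 + nchar(sub)) <- sub
    }
    got <- local_align(a, b, min_score = 0)$score
    want <- max(oracle_local_score(a, b),
                oracle_local_score(revcomp_chr(a), b))
    expect_equal(got, want)
  }
})

test_that("score is invariant under reverse-complementing both sequences", {
  set.seed(304)
  for (i in 1:20) {
    a <- random_dna(40)
    b <- random_dna(80)
    s1 <- local_align(a, b, min_score = 0)$score
    s2 <- local_align(revcomp_chr(a), revcomp_chr(b), min_score = 0)$score
    expect_equal(s1, s2)
  }
})

test_that("weak alignments fall below the reporting threshold", {
  set.seed(305)
  aln <- local_align(random_dna(60), random_dna(200), min_score = 40)
  expect_false(aln$mappable)
  expect_identical(aln$score, 0)
  expect_error(tss_percent_position(aln, 200), "unmappable")
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("TSS percent position reads off the consensus coordinate", {
  fake <- structure(list(orientation = "forward", consensus_start = 0L,
                         consensus_end = 50L, mappable = TRUE),
                    class = "local_alignment")
  expect_equal(tss_percent_position(fake, 6000), 0)
  fake$consensus_start <- 3000L
  expect_equal(tss_percent_position(fake, 6000), 50)
  rc <- structure(list(orientation = "revcomp", consensus_start = 380L,
                       consensus_end = 401L, mappable = TRUE),
                  class = "local_alignment")
  expect_equal(tss_percent_position(rc, 6064), 100 * 400 / 6064)
})

test_that("planted antisense TSS positions are recovered per class", {
  sim <- simulate_cohort(sim_config(seed = 306, n_chimera = 24,
                                    n_exonization = 0, n_plain = 0,
                                    n_zero_orientation = 0,
                                    n_multi_alignment = 0,
                                    mutation_rate = 0, sequences = TRUE))
  tr <- sim$truth[sim$truth$label == "true_chimera", ]
  prof <- build_profile(tr$class, unname(sim$tx_seq[tr$tx_row]),
                        sim$consensus)
  for (cls in names(prof)) {
    L <- nchar(sim$consensus[[cls]])
    want <- sort(100 * tr$consensus_pos[tr$class == cls] / L)
    got <- sort(prof[[cls]]$positions)
    expect_identical(prof[[cls]]$n_unmappable, 0L)
    expect_equal(got, want, tolerance = 1e-6)
    if (cls %in% c("L1HS", "L1PA2_8")) {
      expect_true(all(got <= 10))    # 5' UTR placement
    } else {
      expect_true(all(got >= 80))    # 3'-end placement
    }
  }
  expect_error(build_profile("L1HS", "ACGT", c(other = "ACGT")),
               "no consensus")
})
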