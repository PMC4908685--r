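mk_reads <- function(starts, ends, strand = "+", chrom = "ref",
                     library_size = 1e6) {
  read_set(data.frame(chrom = chrom, start = starts, end = ends,
                      strand = strand, stringsAsFactors = FALSE),
           library_size)
}

test_that("coverage_rpm counts overlapping reads and scales by library", {
  rs <- mk_reads(0L, 10L, library_size = 1e6)
  cov <- coverage_rpm(rs, 20L)
  expect_equal(cov, c(rep(1, 10), rep(0, 10)))
  rs2 <- mk_reads(0L, 10L, library_size = 2e6)
  expect_equal(coverage_rpm(rs2, 20L), cov / 2)
  expect_error(coverage_rpm(mk_reads(0L, 5L, library_size = 0), 10L),
               "library_size")
})

test_that("coverage matches the per-base counting oracle and conserves mass", {
  set.seed(501)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    st <- sample.int(180, n, replace = TRUE) - 1L
    rs <- mk_reads(st, st + sample(5:30, n, replace = TRUE),
                   library_size = 5e5)
    got <- coverage_rpm(rs, 200L)
    expect_equal(got, oracle_coverage(rs$reads, 200L, 5e5))
    # total mass = sum of (clipped) read lengths, RPM-scaled
    lens <- pmin(rs$reads$end, 200L) - pmax(rs$reads$start, 0L)
    expect_equal(sum(got), sum(lens) * 1e6 / 5e5)
  }
})

test_that("log2 fold-change track follows the closed form", {
  chip <- c(1, 2, 4, 0)
  expect_equal(log2fc_track(chip, chip), rep(0, 4))
  expect_equal(log2fc_track(2 * chip, chip, eps = 1e-12),
               c(1, 1, 1, 0), tolerance = 1e-6)
  set.seed(502)
  a <- runif(50); b <- runif(50)
  expect_equal(log2fc_track(a, b, eps = 0.25),
               log2((a + 0.25) / (b + 0.25)))
  expect_error(log2fc_track(1:3, 1:4), "length mismatch")
})

test_that("LOESS smoothing reproduces constants and linear ramps exactly", {
  expect_equal(loess_smooth(rep(3.5, 200)), rep(3.5, 200),
               tolerance = 1e-9)
  ramp <- 0.02 * seq_len(300) - 1
  expect_equal(loess_smooth(ramp), ramp, tolerance = 1e-9)
  expect_error(loess_smooth(1:5), "too short")
})

test_that("LOESS recovers a noisy sinusoid within the noise scale", {
  set.seed(503)
  n <- 500
  truth <- sin(seq(0, 4 * pi, length.out = n))
  noisy <- truth + rnorm(n, sd = 0.2)
  sm <- loess_smooth(noisy, span = 0.1)
  interior <- 50:(n - 50)
  expect_lt(max(abs(sm[interior] - truth[interior])), 2 * 0.2)
})

test_that("metaprofile places a downstream read in the right bin", {
  tss <- data.frame(chrom = "ref", pos = 5000L, strand = "+")
  rs <- mk_reads(5050L, 5080L)
  mp <- tss_metaprofile(tss, rs, ref_lengths = c(ref = 10000L))
  expect_length(mp$value, 20L)
  expect_identical(which(mp$value > 0), 11L) # bin [0, +100)
  expect_equal(mp$bin_mid[11], 50)
  expect_equal(mp$value[11], 1e6 / 1e6)
})

test_that("mirror-imaged pileups give identical flipped profiles", {
  tss <- data.frame(chrom = "ref", pos = c(5000L, 20000L),
                    strand = c("+", "-"))
  # + TSS: reads at +50; - TSS: reads at -50 relative genomic, i.e.
  # downstream in transcription orientation
  rs <- mk_reads(c(5050L, 19920L), c(5080L, 19950L), c("+", "-"))
  mp_plus <- tss_metaprofile(tss[1, ], rs, ref_lengths = c(ref = 30000L))
  mp_minus <- tss_metaprofile(tss[2, ], rs, ref_lengths = c(ref = 30000L))
  expect_equal(mp_plus$value, mp_minus$value)
  # order invariance of the TSS list
  both <- tss_metaprofile(tss, rs, ref_lengths = c(ref = 30000L))
  flipped <- tss_metaprofile(tss[2:1, ], rs, ref_lengths = c(ref = 30000L))
  expect_equal(both$value, flipped$value)
})

test_that("input-subtracted profile vanishes when input equals chip", {
  set.seed(504)
  st <- sample.int(8000, 200) + 1000L
  rs <- mk_reads(st, st + 36L)
  tss <- data.frame(chrom = "ref", pos = c(3000L, 6000L), strand = "+")
  mp <- tss_metaprofile(tss, rs, input = rs, ref_lengths = c(ref = 10000L))
  expect_equal(mp$value, rep(0, 20))
})

test_that("strand matching keeps only same-strand reads", {
  tss <- data.frame(chrom = "ref", pos = 5000L, strand = "+")
  rs <- mk_reads(c(5050L, 5050L), c(5080L, 5080L), c("+", "-"))
  matched <- tss_metaprofile(tss, rs, strand_match = TRUE,
                             ref_lengths = c(ref = 10000L))
  unmatched <- tss_metaprofile(tss, rs, strand_match = FALSE,
                               ref_lengths = c(ref = 10000L))
  expect_equal(unmatched$value[11], 2 * matched$value[11])
})

test_that("TSS windows leaving the reference are dropped and counted", {
  tss <- data.frame(chrom = "ref", pos = c(500L, 5000L), strand = "+")
  rs <- mk_reads(5050L, 5080L)
  mp <- tss_metaprofile(tss, rs, ref_lengths = c(ref = 10000L))
  expect_identical(mp$n_tss, 1L)
  expect_identical(mp$n_dropped, 1L)
  expect_error(
    tss_metaprofile(tss[1, , drop = FALSE], rs,
                    ref_lengths = c(ref = 10000L)),
    "no TSS windows"
  )
})
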