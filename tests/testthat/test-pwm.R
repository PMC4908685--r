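one_hot <- function(word, weight = 100) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, nchar(word), dimnames = list(bases, NULL))
  for (j in seq_len(nchar(word))) {
    counts[substr(word, j, j), j] <- weight
  }
  pwm(counts, motif_id = word)
}

test_that("a one-hot PWM hits its own consensus with relative score 1", {
  p <- one_hot("ACGT")
  hits <- scan_pwm("ACGT", p, threshold = 1)
  # ACGT is its own reverse complement: one hit per strand
  expect_identical(nrow(hits), 2L)
  expect_true(all(hits$relative_score == 1))
  expect_identical(hits$start, c(0L, 0L))

  p2 <- one_hot("AAGT")
  fw <- scan_pwm("AAGT", p2, threshold = 1)
  expect_identical(fw$strand, "+")
  rv <- scan_pwm("ACTT", p2, threshold = 1)
  expect_identical(rv$strand, "-")
  expect_identical(rv$start, 0L)
})

test_that("scan matches the exhaustive per-window oracle", {
  set.seed(401)
  for (i in 1:100) {
    W <- sample(4:9, 1)
    counts <- matrix(sample(0:20, 4 * W, replace = TRUE), 4)
    if (any(colSums(counts) == 0)) counts <- counts + 1
    p <- pwm(counts)
    seq <- random_dna(sample(50:200, 1))
    thr <- stats::runif(1, 0.6, 0.95)
    got <- scan_pwm(seq, p, thr)[, c("start", "end", "strand", "score",
                                     "relative_score")]
    want <- oracle_pwm_hits(seq, p, thr)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("lowering the threshold only adds hits", {
  set.seed(402)
  p <- pwm(matrix(sample(0:15, 24, replace = TRUE) + 1, 4))
  seq <- random_dna(300)
  hi <- scan_pwm(seq, p, 0.9)
  lo <- scan_pwm(seq, p, 0.7)
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(hi) %in% key(lo)))
  expect_gte(nrow(lo), nrow(hi))
})

test_that("a window and its reverse complement score identically", {
  set.seed(403)
  for (i in 1:20) {
    W <- sample(5:8, 1)
    p <- pwm(matrix(sample(1:20, 4 * W, replace = TRUE), 4))
    win <- random_dna(W)
    fwd <- scan_pwm(win, p, threshold = 1e-9)
    plus <- fwd$score[fwd$strand == "+"]
    rc_minus <- scan_pwm(revcomp_chr(win), p, threshold = 1e-9)
    minus <- rc_minus$score[rc_minus$strand == "-"]
    expect_equal(plus, minus)
  }
})

test_that("site reports use 1-based inclusive coordinates", {
  hits <- data.frame(motif_id = c("m", "m"), start = c(447L, 12L),
                     end = c(453L, 21L), strand = c("+", "-"),
                     score = c(1, 1), relative_score = c(0.95, 0.92))
  rep <- report_sites(hits)
  expect_identical(rep$site, c("448 to 453", "13 to 21"))
  expect_identical(nrow(report_sites(hits[0, ])), 0L)
})

test_that("JASPAR count matrices are parsed and planted sites recovered", {
  path <- system.file("extdata", "yy1like_synthetic.jaspar",
                      package = "l1asp")
  mats <- read_jaspar(path)
  expect_identical(names(mats), "MA9001.1")
  expect_identical(ncol(mats[[1]]$counts), 6L)

  sim <- simulate_cohort(sim_config(seed = 404, n_chimera = 2,
                                    n_exonization = 0, n_plain = 0,
                                    n_zero_orientation = 0,
                                    n_multi_alignment = 0,
                                    sequences = TRUE))
  utr <- substr(sim$consensus[["L1HS"]], 1, 1000)
  hits <- scan_pwm(utr, mats[[1]], threshold = 0.9)
  found <- paste(hits$start, hits$strand)
  planted <- paste(sim$motif_sites$start, sim$motif_sites$strand)
  expect_true(all(planted %in% found))
  sites <- report_sites(hits)
  expect_true("448 to 453" %in% sites$site)
})

test_that("degenerate scans return empty hit tables", {
  p <- one_hot("ACGTAA")
  expect_identical(nrow(scan_pwm("ACG", p, 0.9)), 0L)
  expect_error(scan_pwm("ACGTACGT", p, 0))
})
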