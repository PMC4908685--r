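#' Generate a synthetic cohort with known ground truth
#'
#' Builds a small synthetic genome laid out in 12-kb gene slots (three
#' exons per gene) and plants every record category the screen must
#' handle. Anchor L1 elements are consensus-derived segments around the
#' planted antisense TSS: young-class anchors carry a 5'-UTR TSS
#' (uniform over `young_tss_range`), ancient-class anchors a 3'-end TSS.
#' Where a gene is drawn on the minus strand the whole slot is mirrored,
#' which preserves every planted consensus position. Deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `l1asp_sim`: `transcripts`
#'   (`spliced_transcripts`), `repeats`, `genes`, `truth` (one row per
#'   record: `id`, `label`, `gene_id`, `class`, `consensus_pos`, `coding`,
#'   `multi_alignment`, `zero_orientation`, `tss_chrom`, `tss_pos`,
#'   `tss_strand`), `consensus` (named character, if sequences),
#'   `tx_seq` (per primary record, if sequences), `genome` (if sequences),
#'   `motif_sites`, `reads` (if requested), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  slot_len <- 12000L
  # local layout of a plus-strand gene slot
  EX1 <- c(1000L, 1200L); EX2 <- c(4200L, 5100L); EX3 <- c(7100L, 7400L)
  L1S_SENSE <- 1400L; L1S_ANTI <- 5400L; BLK1 <- 240L

  n_genes <- cfg$n_chimera + cfg$n_exonization + cfg$n_plain_genes +
    cfg$n_zero_orientation
  n_slots <- n_genes + cfg$n_multi_alignment + cfg$n_background_l1
  capacity <- cfg$n_chrom * (cfg$chrom_len %/% slot_len)
  if (n_slots > capacity) {
    stop("genome too small for requested cohort (", n_slots, " slots, ",
         capacity, " available)")
  }
  slot_chrom <- paste0("chr", (seq_len(n_slots) - 1L) %%
                         cfg$n_chrom + 1L)
  slot_start <- ((seq_len(n_slots) - 1L) %/% cfg$n_chrom) * slot_len

  # consensus sequences with planted motif sites in the L1HS 5' UTR
  consensus <- NULL
  motif_sites <- data.frame(consensus = character(), start = integer(),
                            end = integer(), strand = character())
  motif_str <- "ATGGCG"
  if (cfg$sequences) {
    consensus <- vapply(cfg$consensus_len, .random_seq, character(1))
    plant <- function(seq, pos, s) {
      m <- if (s == "+") motif_str else .revcomp(motif_str)
      substr(seq, pos + 1L, pos + nchar(m)) <- m
      seq
    }
    consensus[["L1HS"]] <- plant(consensus[["L1HS"]], 12L, "-")
    consensus[["L1HS"]] <- plant(consensus[["L1HS"]], 447L, "+")
    motif_sites <- data.frame(
      consensus = "L1HS", start = c(12L, 447L),
      end = c(12L + nchar(motif_str), 447L + nchar(motif_str)),
      strand = c("-", "+"), stringsAsFactors = FALSE
    )
  }

  rep_acc <- list(); gene_acc <- list(); tx_acc <- list()
  truth_acc <- list(); paint_l1 <- list(); paint_exon <- list()
  flip <- c("+" = "-", "-" = "+")

  add_gene <- function(gid, slot, gs) {
    S <- slot_start[slot]
    iv <- function(a) if (gs == "+") S + a else S + slot_len - rev(a)
    ex <- lapply(list(EX1, EX2, EX3), iv)
    ex <- ex[order(vapply(ex, `[`, integer(1), 1L))]
    gene_acc[[length(gene_acc) + 1L]] <<- list(
      gene_id = gid, chrom = slot_chrom[slot], strand = gs,
      starts = vapply(ex, `[`, integer(1), 1L),
      ends = vapply(ex, `[`, integer(1), 2L)
    )
  }

  add_repeat <- function(slot, gs, local_iv, local_strand, subfamily,
                         class, cs, ce) {
    S <- slot_start[slot]
    g <- if (gs == "+") S + local_iv else S + slot_len - rev(local_iv)
    s <- if (gs == "+") local_strand else flip[[local_strand]]
    rep_acc[[length(rep_acc) + 1L]] <<- list(
      chrom = slot_chrom[slot], start = g[1L], end = g[2L], strand = s,
      subfamily = subfamily, class = class
    )
    paint_l1[[length(paint_l1) + 1L]] <<- list(
      chrom = slot_chrom[slot], start = g[1L], end = g[2L], strand = s,
      class = class, cs = cs, ce = ce
    )
    length(rep_acc)
  }

  add_tx <- function(id, slot, gs, local_blocks, local_txn, io) {
    S <- slot_start[slot]
    blocks <- lapply(local_blocks, function(a) {
      if (gs == "+") S + a else S + slot_len - rev(a)
    })
    blocks <- blocks[order(vapply(blocks, `[`, integer(1), 1L))]
    txn <- if (local_txn == "undetermined") "undetermined"
           else if (gs == "+") local_txn else flip[[local_txn]]
    align <- if (txn %in% c("+", "-")) {
      if (io >= 0L) txn else flip[[txn]]
    } else {
      sample(c("+", "-"), 1L)
    }
    tx_acc[[length(tx_acc) + 1L]] <<- list(
      id = id, chrom = slot_chrom[slot], align_strand = align,
      starts = vapply(blocks, `[`, integer(1), 1L),
      ends = vapply(blocks, `[`, integer(1), 2L),
      io = io, txn = txn
    )
    length(tx_acc)
  }

  draw_anchor <- function() {
    cls <- sample(names(cfg$class_mix), 1L, prob = cfg$class_mix)
    L <- cfg$consensus_len[[cls]]
    p <- if (cls %in% c("L1HS", "L1PA2_8")) {
      round(stats::runif(1, cfg$young_tss_range[1], cfg$young_tss_range[2]))
    } else {
      round(stats::runif(1, cfg$ancient_tss_frac_range[1] * L,
                         cfg$ancient_tss_frac_range[2] * L))
    }
    p <- max(20L, min(as.integer(p), L - 35L))
    list(class = cls, L = L, p = p,
         cs = max(0L, p - 280L), ce = min(L, p + 30L),
         subfamily = .subfamily_name(cls))
  }

  slot <- 0L
  # ---- true chimeras (and undetermined-orientation lookalikes) ----
  n_chim_like <- cfg$n_chimera + cfg$n_zero_orientation
  for (i in seq_len(n_chim_like)) {
    slot <- slot + 1L
    zero <- i > cfg$n_chimera
    id <- if (zero) sprintf("zero_%04d", i - cfg$n_chimera)
          else sprintf("chim_%04d", i)
    gid <- sprintf("gene_%04d", slot)
    gs <- sample(c("+", "-"), 1L)
    add_gene(gid, slot, gs)
    a <- draw_anchor()
    sense <- stats::runif(1) < cfg$sense_fraction
    if (sense) {
      l1_iv <- c(L1S_SENSE, L1S_SENSE + (a$ce - a$cs))
      t <- L1S_SENSE + (a$ce - 1L - a$p)
      blocks <- list(c(t, t + BLK1), EX2)
      txn <- "+"
      l1_strand <- "-"
    } else {
      l1_iv <- c(L1S_ANTI, L1S_ANTI + (a$ce - a$cs))
      t <- L1S_ANTI + (a$p - a$cs)
      blocks <- list(EX2, c(t - BLK1 + 1L, t + 1L))
      txn <- "-"
      l1_strand <- "+"
    }
    rid <- add_repeat(slot, gs, l1_iv, l1_strand, a$subfamily, a$class,
                      a$cs, a$ce)
    io <- if (zero) 0L else sample(c(-3L, -2L, -1L, 1L, 2L, 3L), 1L)
    ti <- add_tx(id, slot, gs, blocks, if (zero) "undetermined" else txn, io)
    coding <- !zero && stats::runif(1) < cfg$coding_fraction
    paint_exon[[length(paint_exon) + 1L]] <- list(
      slot = slot, gs = gs, local_iv = EX2, txn_local = txn,
      coding = coding,
      len_aa = if (coding) min(100L + stats::rgeom(1L, 1 / 40), 268L)
               else NA_integer_
    )
    truth_acc[[length(truth_acc) + 1L]] <- list(
      id = id, label = if (zero) "noise" else "true_chimera",
      gene_id = gid, anchor = rid, class = a$class, consensus_pos = a$p,
      coding = if (zero) NA else coding,
      multi_alignment = !zero && i <= cfg$n_multi_alignment,
      zero_orientation = zero, sense = sense, tx_row = ti
    )
  }

  # ---- exonization decoys: candidate + independent supporter ----
  for (j in seq_len(cfg$n_exonization)) {
    slot <- slot + 1L
    gid <- sprintf("gene_%04d", slot)
    gs <- sample(c("+", "-"), 1L)
    add_gene(gid, slot, gs)
    a <- draw_anchor()
    a$p <- max(150L, a$p)
    a$cs <- max(0L, a$p - 280L); a$ce <- min(a$L, a$p + 30L)
    l1_iv <- c(L1S_SENSE, L1S_SENSE + (a$ce - a$cs))
    rid <- add_repeat(slot, gs, l1_iv, "-", a$subfamily, a$class,
                      a$cs, a$ce)
    t <- L1S_SENSE + (a$ce - 1L - a$p)
    cand_id <- sprintf("decoy_%04d", j)
    ti <- add_tx(cand_id, slot, gs, list(c(t, t + BLK1), EX2), "+",
                 sample(c(-2L, 1L, 2L), 1L))
    inner <- c(L1S_SENSE + 20L, L1S_SENSE + 120L)
    add_tx(sprintf("supp_%04d", j), slot, gs,
           list(EX1, inner, c(EX2[1L], EX2[1L] + 300L)), "+",
           sample(c(-2L, 1L, 2L), 1L))
    truth_acc[[length(truth_acc) + 1L]] <- list(
      id = cand_id, label = "exonization_decoy", gene_id = gid,
      anchor = rid, class = a$class, consensus_pos = a$p, coding = NA,
      multi_alignment = FALSE, zero_orientation = FALSE, sense = TRUE,
      tx_row = ti
    )
    truth_acc[[length(truth_acc) + 1L]] <- list(
      id = sprintf("supp_%04d", j), label = "plain_gene_est",
      gene_id = gid, anchor = NA_integer_, class = NA_character_,
      consensus_pos = NA_integer_, coding = NA, multi_alignment = FALSE,
      zero_orientation = FALSE, sense = TRUE, tx_row = length(tx_acc)
    )
  }

  # ---- plain gene transcripts over a shared pool of genes ----
  plain_slots <- slot + seq_len(cfg$n_plain_genes)
  for (g in seq_len(cfg$n_plain_genes)) {
    slot <- slot + 1L
    add_gene(sprintf("gene_%04d", slot), slot, sample(c("+", "-"), 1L))
  }
  plain_gs <- vapply(gene_acc[plain_slots], `[[`, character(1), "strand")
  for (k in seq_len(cfg$n_plain)) {
    gsel <- (k - 1L) %% cfg$n_plain_genes + 1L
    ti <- add_tx(sprintf("plain_%04d", k), plain_slots[gsel],
                 plain_gs[gsel], list(EX2, EX3), "+",
                 sample(c(-2L, 1L, 2L), 1L))
    truth_acc[[length(truth_acc) + 1L]] <- list(
      id = sprintf("plain_%04d", k), label = "plain_gene_est",
      gene_id = sprintf("gene_%04d", plain_slots[gsel]),
      anchor = NA_integer_, class = NA_character_,
      consensus_pos = NA_integer_, coding = NA, multi_alignment = FALSE,
      zero_orientation = FALSE, sense = TRUE, tx_row = ti
    )
  }

  # ---- secondary alignments for multi-alignment chimeras ----
  for (m in seq_len(cfg$n_multi_alignment)) {
    slot <- slot + 1L
    S <- slot_start[slot]
    io <- tx_acc[[truth_acc[[m]]$tx_row]]$io
    add_tx(sprintf("chim_%04d", m), slot, "+",
           list(c(2000L, 2200L), c(2600L, 2800L)), "+", io)
  }

  # ---- background L1 elements in spare slots ----
  for (b in seq_len(cfg$n_background_l1)) {
    slot <- slot + 1L
    cls <- sample(names(cfg$class_mix), 1L, prob = cfg$class_mix)
    L <- cfg$consensus_len[[cls]]
    len <- sample(400:1500, 1L)
    cs <- sample.int(L - len, 1L) - 1L
    add_repeat(slot, "+", c(3000L, 3000L + len),
               sample(c("+", "-"), 1L), .subfamily_name(cls), cls,
               cs, cs + len)
  }

  # ---- assemble tables ----
  repeats <- repeat_elements(
    vapply(rep_acc, `[[`, character(1), "chrom"),
    vapply(rep_acc, `[[`, integer(1), "start"),
    vapply(rep_acc, `[[`, integer(1), "end"),
    vapply(rep_acc, `[[`, character(1), "strand"),
    vapply(rep_acc, `[[`, character(1), "subfamily"),
    "L1"
  )
  genes <- gene_models(
    vapply(gene_acc, `[[`, character(1), "gene_id"),
    vapply(gene_acc, `[[`, character(1), "chrom"),
    vapply(gene_acc, `[[`, character(1), "strand"),
    lapply(gene_acc, `[[`, "starts"),
    lapply(gene_acc, `[[`, "ends")
  )
  tx <- spliced_transcripts(
    vapply(tx_acc, `[[`, character(1), "id"),
    vapply(tx_acc, `[[`, character(1), "chrom"),
    vapply(tx_acc, `[[`, character(1), "align_strand"),
    lapply(tx_acc, `[[`, "starts"),
    lapply(tx_acc, `[[`, "ends"),
    vapply(tx_acc, `[[`, integer(1), "io")
  )
  truth <- do.call(rbind, lapply(truth_acc, function(r) {
    data.frame(r[setdiff(names(r), "tx_row")], stringsAsFactors = FALSE)
  }))
  truth$tx_row <- vapply(truth_acc, `[[`, integer(1), "tx_row")
  # genomic TSS of each record, in transcription orientation
  truth$tss_chrom <- tx$chrom[truth$tx_row]
  txn_all <- vapply(tx_acc, `[[`, character(1), "txn")
  truth$tss_strand <- txn_all[truth$tx_row]
  truth$tss_pos <- ifelse(truth$tss_strand == "+", tx$start[truth$tx_row],
                          tx$end[truth$tx_row] - 1L)
  truth$tss_pos[truth$tss_strand == "undetermined"] <- NA_integer_

  out <- list(transcripts = tx, repeats = repeats, genes = genes,
              truth = truth, consensus = consensus,
              motif_sites = motif_sites, config = cfg)

  # ---- sequences: paint the genome, extract transcripts ----
  if (cfg$sequences) {
    genome <- stats::setNames(
      vapply(seq_len(cfg$n_chrom), function(i) .random_seq(cfg$chrom_len),
             character(1)),
      paste0("chr", seq_len(cfg$n_chrom))
    )
    for (pj in paint_l1) {
      seg <- substr(consensus[[pj$class]], pj$cs + 1L, pj$ce)
      seg <- .mutate_seq(seg, cfg$mutation_rate)
      if (pj$strand == "-") seg <- .revcomp(seg)
      substr(genome[[pj$chrom]], pj$start + 1L, pj$end) <- seg
    }
    for (pe in paint_exon) {
      S <- slot_start[pe$slot]
      g <- if (pe$gs == "+") S + pe$local_iv else
        S + slot_len - rev(pe$local_iv)
      n <- g[2L] - g[1L]
      cassette <- if (pe$coding) .orf_cassette(n, pe$len_aa)
                  else .stop_rich(n)
      txn_final <- if (pe$gs == "+") pe$txn_local else flip[[pe$txn_local]]
      if (txn_final == "-") cassette <- .revcomp(cassette)
      chrom <- slot_chrom[pe$slot]
      substr(genome[[chrom]], g[1L] + 1L, g[2L]) <- cassette
    }
    tx_seq <- vapply(seq_len(nrow(tx)), function(i) {
      s <- paste(substring(genome[[tx$chrom[i]]],
                           tx$block_starts[[i]] + 1L,
                           tx$block_ends[[i]]), collapse = "")
      if (txn_all[i] == "-") s <- .revcomp(s)
      s
    }, character(1))
    names(tx_seq) <- tx$id
    out$genome <- genome
    out$tx_seq <- tx_seq
  }

  # ---- read pileups around planted chimera TSSs ----
  if (cfg$reads) {
    tss <- truth[truth$label == "true_chimera", , drop = FALSE]
    mk_pileup <- function(strand_mode) {
      rows <- lapply(seq_len(nrow(tss)), function(i) {
        n <- stats::rpois(1L, cfg$chip_reads_per_tss)
        if (n == 0L) return(NULL)
        d <- sample.int(cfg$pileup_span, n, replace = TRUE) - 1L
        if (tss$tss_strand[i] == "+") {
          st <- tss$tss_pos[i] + d
        } else {
          st <- tss$tss_pos[i] - d - cfg$read_len + 1L
        }
        data.frame(chrom = tss$tss_chrom[i], start = st,
                   end = st + cfg$read_len,
                   strand = if (strand_mode == "match") tss$tss_strand[i]
                            else sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      read_set(do.call(rbind, rows), cfg$library_size)
    }
    mk_uniform <- function(n_per_chrom) {
      rows <- lapply(paste0("chr", seq_len(cfg$n_chrom)), function(ch) {
        st <- sample.int(cfg$chrom_len - cfg$read_len, n_per_chrom)
        data.frame(chrom = ch, start = st, end = st + cfg$read_len,
                   strand = sample(c("+", "-"), n_per_chrom,
                                   replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      read_set(do.call(rbind, rows), cfg$library_size)
    }
    clen <- cfg$consensus_len[["L1HS"]]
    mk_consensus <- function(centers) {
      ctr <- sample(centers, 2000L, replace = TRUE) +
        round(stats::rnorm(2000L, 0, 30))
      st <- pmax(0L, pmin(as.integer(ctr) - 18L, clen - cfg$read_len))
      read_set(data.frame(chrom = "L1HS", start = st,
                          end = st + cfg$read_len,
                          strand = sample(c("+", "-"), 2000L,
                                          replace = TRUE),
                          stringsAsFactors = FALSE),
               cfg$library_size)
    }
    out$reads <- list(
      chip = mk_pileup("any"), gro = mk_pileup("match"),
      input = mk_uniform(2000L),
      chip_consensus = mk_consensus(c(20L, 450L)),
      input_consensus = mk_consensus(seq(18L, clen - 18L))
    )
  }

  class(out) <- "l1asp_sim"
  out
}

#' @export
print.l1asp_sim <- function(x, ...) {
  cat("synthetic L1 ASP cohort:",
      nrow(x$transcripts), "alignment records,",
      nrow(x$repeats), "L1 elements,", nrow(x$genes), "genes\n")
  print(table(x$truth$label))
  invisible(x)
}
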