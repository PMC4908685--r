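#' Default L1 subfamily age-class map
#'
#' Ordered regular-expression rules assigning L1 subfamily names to four
#' evolutionary age classes: human-specific `L1HS` (includes L1PA1, a
#' synonym), recent primate `L1PA2_8`, `ancient_primate` (all other
#' L1PA/L1PB/L1P names), and `ancient_mammalian` (L1M-type, L1ME, HAL1 and
#' any remaining L1-family name). The first matching rule wins.
#'
#' @return Data frame with columns `pattern` (regex) and `class`.
#' @export
default_subfamily_map <- function() {
  data.frame(
    pattern = c("^(L1HS|L1PA1)$", "^L1PA[2-8]$", "^(L1PA|L1PB|L1P)",
                "^(L1M|L1ME|HAL1|L1)"),
    class = c("L1HS", "L1PA2_8", "ancient_primate", "ancient_mammalian"),
    stringsAsFactors = FALSE
  )
}

#' Read a subfamily class map from a two-column TSV (pattern, class)
#' @param path Path to the tab-separated file (no header).
#' @return Data frame usable as `map` in [classify_subfamily()].
#' @export
read_subfamily_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  data.frame(pattern = x[[1]], class = x[[2]], stringsAsFactors = FALSE)
}

#' Classify L1 subfamily names into age classes
#'
#' @param name Character vector of subfamily names (L1 family).
#' @param map Ordered rule table; see [default_subfamily_map()].
#' @return Character vector of classes.
#' @export
classify_subfamily <- function(name, map = default_subfamily_map()) {
  out <- rep(NA_character_, length(name))
  for (i in seq_len(nrow(map))) {
    hit <- is.na(out) & grepl(map$pattern[i], name)
    out[hit] <- map$class[i]
  }
  if (anyNA(out)) {
    stop("unmapped subfamily name(s): ",
         paste(unique(name[is.na(out)]), collapse = ", "))
  }
  out
}

#' Does a transcript support exonization of an L1 element?
#'
#' Exonization means the L1 is carried as an *internal* exon of a host-gene
#' transcript (exon–L1–exon): the transcript is antisense to the L1, at
#' least one block overlaps the L1, and there is at least one block entirely
#' 5' of the first L1-overlapping block and one entirely 3' of the last
#' (in transcript orientation). A transcript whose 5'-most block starts
#' inside the L1 is an antisense-promoter candidate, not exonization.
#'
#' @param tx A strand-resolved `spliced_transcripts` data frame (its rows
#'   are each tested).
#' @param l1 A single-row `repeat_elements` data frame.
#' @return Logical vector, one per transcript row.
#' @export
is_exonization_support <- function(tx, l1) {
  vapply(seq_len(nrow(tx)), function(i) {
    if (!tx$txn_strand[i] %in% c("+", "-")) return(FALSE)
    if (tx$txn_strand[i] == l1$strand || tx$chrom[i] != l1$chrom) return(FALSE)
    bs <- tx$block_starts[[i]]; be <- tx$block_ends[[i]]
    ov <- which(pmin(be, l1$end) - pmax(bs, l1$start) > 0L)
    if (length(ov) == 0L) return(FALSE)
    # blocks are sorted and non-overlapping, so indices outside [min(ov),
    # max(ov)] are entirely outside the L1-overlapping stretch; flanking on
    # both genomic sides equals flanking on both transcript sides
    min(ov) > 1L && max(ov) < length(bs)
  }, logical(1))
}

#' Per-gene overlap annotation for an accepted call
#'
#' @param txn_strand Transcript transcriptional strand.
#' @param transcript_tss Transcript TSS position (0-based).
#' @param gene A single-row `gene_models` data frame.
#' @param overlap Exonic overlap in bp (> 0).
#' @return One-row data frame: `gene_id`, `relative_orientation`
#'   (`"sense"`/`"antisense"` of transcript vs gene), `tss_distance`
#'   (signed bp from the gene TSS to the transcript TSS, positive =
#'   downstream in gene orientation), `overlap_bp`.
#' @export
annotate_gene_overlap <- function(txn_strand, transcript_tss, gene, overlap) {
  d <- transcript_tss - gene$tss
  if (gene$strand == "-") d <- -d
  data.frame(
    gene_id = gene$gene_id,
    relative_orientation = ifelse(txn_strand == gene$strand,
                                  "sense", "antisense"),
    tss_distance = as.integer(d),
    overlap_bp = as.integer(overlap),
    stringsAsFactors = FALSE
  )
}

#' Screen spliced transcripts for L1 antisense-promoter chimeras
#'
#' Applies the three selection criteria:
#'
#' 1. the transcript TSS lies inside an annotated L1 element and the
#'    transcriptional direction is antisense to that L1;
#' 2. at least one transcript block overlaps at least one annotated exon of
#'    a gene (minimum 1 bp);
#' 3. no independent transcript (different id) supports exonization of the
#'    same anchor L1 (exon–L1–exon structure; see
#'    [is_exonization_support()]). The veto is per anchor element.
#'
#' Records with undetermined transcriptional strand (zero intron
#' orientation) are dropped up front and counted. Records with multiple
#' alignments are flagged, never removed. When the TSS falls inside two
#' overlapping L1s, the anchor is the antisense one; if both qualify, the
#' one with the larger overlap with the TSS-containing block, ties broken
#' by smaller start.
#'
#' @param tx A `spliced_transcripts` data frame; strand is resolved here if
#'   `intron_orientation` is populated and `txn_strand` is not.
#' @param repeats A `repeat_elements` data frame; restricted to family
#'   `"L1"` internally.
#' @param genes A `gene_models` data frame.
#' @param class_map Subfamily age-class rules
#'   (see [default_subfamily_map()]).
#' @return An object of class `l1asp_screen`: list with
#'   `accepted` (one row per accepted call: `transcript_id`, anchor
#'   coordinates and subfamily, `subfamily_class`, `tss`, `txn_strand`,
#'   `multi_alignment`), `gene_overlaps` (one row per accepted
#'   transcript–gene pair), `removed_exonization` (candidates passing
#'   criteria 1–2 but vetoed by 3), `dropped_zero_orientation` (count), and
#'   `n_input`.
#' @export
screen <- function(tx, repeats, genes, class_map = default_subfamily_map()) {
  repeats <- repeats[repeats$family == "L1", , drop = FALSE]
  if (all(is.na(tx$txn_strand))) tx <- resolve_txn_strand(tx)
  if (any(is.na(tx$txn_strand)))
    stop("transcripts must be strand-resolved before screening")
  n_input <- nrow(tx)

  dropped <- sum(tx$txn_strand == "undetermined")
  tx <- tx[tx$txn_strand != "undetermined", , drop = FALSE]
  spliced <- lengths(tx$block_starts) >= 2L
  tx <- tx[spliced, , drop = FALSE]

  empty_call <- data.frame(
    transcript_id = character(), anchor_chrom = character(),
    anchor_start = integer(), anchor_end = integer(),
    anchor_strand = character(), subfamily = character(),
    subfamily_class = character(), tss = integer(),
    txn_strand = character(), multi_alignment = logical(),
    stringsAsFactors = FALSE
  )
  empty_ov <- data.frame(transcript_id = character(), gene_id = character(),
                         relative_orientation = character(),
                         tss_distance = integer(), overlap_bp = integer(),
                         stringsAsFactors = FALSE)
  res <- list(accepted = empty_call, gene_overlaps = empty_ov,
              removed_exonization = empty_call,
              dropped_zero_orientation = dropped, n_input = n_input)
  class(res) <- "l1asp_screen"
  if (nrow(tx) == 0L || nrow(repeats) == 0L) return(res)

  # C1: TSS inside an antisense L1; pick an anchor per candidate
  tss <- tss_of(tx)
  hits <- bulk_intersect(tss, repeats)
  if (nrow(hits) > 0L) {
    anti <- tx$txn_strand[hits$query] != repeats$strand[hits$subject]
    hits <- hits[anti, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(res)

  # several antisense L1s may contain the TSS: prefer the larger overlap
  # with the TSS-containing block, then the smaller start
  anchor_of <- integer(0)
  for (q in unique(hits$query)) {
    subj <- hits$subject[hits$query == q]
    if (length(subj) > 1L) {
      tb <- if (tx$txn_strand[q] == "+") 1L else length(tx$block_starts[[q]])
      blk <- genomic_interval(tx$chrom[q], tx$block_starts[[q]][tb],
                              tx$block_ends[[q]][tb])
      ovl <- overlap_bp(blk, repeats[subj, , drop = FALSE])
      subj <- subj[order(-ovl, repeats$start[subj])]
    }
    anchor_of[as.character(q)] <- subj[1L]
  }
  cand_idx <- as.integer(names(anchor_of))
  anchor_idx <- unname(anchor_of)

  # C2: >= 1 bp exonic overlap with >= 1 gene
  tx_blocks <- explode_blocks(tx$chrom, tx$block_starts, tx$block_ends)
  gene_exons <- explode_blocks(genes$chrom, genes$exon_starts,
                               genes$exon_ends)
  bhits <- bulk_intersect(tx_blocks, gene_exons)
  if (nrow(bhits) > 0L) {
    pair <- data.frame(
      tx = tx_blocks$parent[bhits$query],
      gene = gene_exons$parent[bhits$subject],
      ov = overlap_bp(tx_blocks[bhits$query, , drop = FALSE],
                      gene_exons[bhits$subject, , drop = FALSE])
    )
    pair <- stats::aggregate(ov ~ tx + gene, data = pair, FUN = sum)
  } else {
    pair <- data.frame(tx = integer(), gene = integer(), ov = integer())
  }

  # C3: exonization veto per anchor L1 element, by independent transcripts
  # (an "independent" supporter is any record with a different id than the
  # candidate; the veto removes every candidate anchored in that element)
  supporter_ids <- lapply(unique(anchor_idx), function(a) {
    l1 <- repeats[a, , drop = FALSE]
    near <- which(tx$chrom == l1$chrom & tx$start < l1$end &
                    tx$end > l1$start)
    if (length(near) == 0L) return(character(0))
    unique(tx$id[near[is_exonization_support(tx[near, , drop = FALSE], l1)]])
  })
  names(supporter_ids) <- as.character(unique(anchor_idx))

  build_calls <- function(sel) {
    i <- cand_idx[sel]; a <- anchor_idx[sel]
    data.frame(
      transcript_id = tx$id[i], anchor_chrom = repeats$chrom[a],
      anchor_start = repeats$start[a], anchor_end = repeats$end[a],
      anchor_strand = repeats$strand[a], subfamily = repeats$subfamily[a],
      subfamily_class = classify_subfamily(repeats$subfamily[a], class_map),
      tss = ifelse(tx$txn_strand[i] == "+", tx$start[i], tx$end[i] - 1L),
      txn_strand = tx$txn_strand[i],
      multi_alignment = tx$n_alignments[i] > 1L,
      stringsAsFactors = FALSE
    )
  }

  has_exon_overlap <- cand_idx %in% pair$tx
  vetoed <- vapply(seq_along(cand_idx), function(s) {
    supp <- supporter_ids[[as.character(anchor_idx[s])]]
    any(supp != tx$id[cand_idx[s]])
  }, logical(1))
  acc_sel <- which(has_exon_overlap & !vetoed)
  rem_sel <- which(has_exon_overlap & vetoed)

  res$accepted <- build_calls(acc_sel)
  res$removed_exonization <- build_calls(rem_sel)

  if (length(acc_sel) > 0L) {
    ovs <- lapply(acc_sel, function(s) {
      i <- cand_idx[s]
      p <- pair[pair$tx == i, , drop = FALSE]
      t_tss <- if (tx$txn_strand[i] == "+") tx$start[i] else tx$end[i] - 1L
      do.call(rbind, lapply(seq_len(nrow(p)), function(k) {
        g <- genes[p$gene[k], , drop = FALSE]
        cbind(transcript_id = tx$id[i],
              annotate_gene_overlap(tx$txn_strand[i], t_tss, g, p$ov[k]))
      }))
    })
    res$gene_overlaps <- do.call(rbind, ovs)
    rownames(res$gene_overlaps) <- NULL
  }
  res
}

#' @export
print.l1asp_screen <- function(x, ...) {
  cat("L1 ASP chimera screen\n")
  cat("  input records:           ", x$n_input, "\n")
  cat("  dropped (orientation 0): ", x$dropped_zero_orientation, "\n")
  cat("  accepted calls:          ", nrow(x$accepted), "\n")
  cat("  removed (exonization):   ", nrow(x$removed_exonization), "\n")
  cat("  gene overlaps:           ", nrow(x$gene_overlaps), "\n")
  invisible(x)
}

#' Summaries of an accepted call set
#'
#' @param res An `l1asp_screen` object.
#' @return List with `per_gene` (EST count per gene), `per_class`
#'   (subfamily age-class counts over accepted calls), `orientation`
#'   (sense/antisense counts over transcript-gene pairs), `n_accepted`,
#'   `n_multi_alignment`.
#' @export
tally <- function(res) {
  per_gene <- table(res$gene_overlaps$gene_id)
  per_class <- table(factor(res$accepted$subfamily_class,
                            levels = c("L1HS", "L1PA2_8", "ancient_primate",
                                       "ancient_mammalian")))
  orientation <- table(factor(res$gene_overlaps$relative_orientation,
                              levels = c("sense", "antisense")))
  list(per_gene = per_gene, per_class = per_class, orientation = orientation,
       n_accepted = nrow(res$accepted),
       n_multi_alignment = sum(res$accepted$multi_alignment))
}
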