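#' Read a BED12 spliced-alignment table
#'
#' Standard BED12 semantics: `blockSizes`/`blockStarts` are comma-separated
#' (a trailing comma is tolerated) and block starts are relative to
#' `chromStart`. The strand column is taken as the *alignment* strand.
#'
#' @param path Path to a tab-separated BED12 file (no header).
#' @param orientation Optional named integer vector or path to a
#'   two-column tab-separated table (`id`, `intron_orientation`). Records
#'   without an entry get orientation 0 (undetermined).
#' @return A `spliced_transcripts` data frame (strand not yet resolved).
#' @export
read_bed12 <- function(path, orientation = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character", "integer", "integer",
                                          "character", "integer",
                                          "character", "character"))
  split_csv <- function(s) lapply(strsplit(sub(",$", "", s), ","), as.integer)
  sizes <- split_csv(raw$V11)
  offs <- split_csv(raw$V12)
  block_starts <- Map(function(cs, o) cs + o, raw$V2, offs)
  block_ends <- Map(`+`, block_starts, sizes)
  ori <- orientation
  if (is.character(ori) && length(ori) == 1L) ori <- read_orientation(ori)
  io <- if (is.null(ori)) 0L else {
    v <- unname(ori[raw$V4]); v[is.na(v)] <- 0L; as.integer(v)
  }
  spliced_transcripts(raw$V4, raw$V1, raw$V6, block_starts, block_ends, io)
}

#' Read an intron-orientation table
#'
#' @param path Two-column tab-separated file: record id, signed integer
#'   intron orientation (positive: transcription matches alignment strand;
#'   negative: opposite; zero: undetermined).
#' @return Named integer vector.
#' @export
read_orientation <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.integer(x[[2]]), x[[1]])
}

#' Write spliced transcripts as BED12
#'
#' @param tx A `spliced_transcripts` data frame.
#' @param path Output path.
#' @export
write_bed12 <- function(tx, path) {
  sizes <- vapply(seq_len(nrow(tx)), function(i)
    paste0(paste(tx$block_ends[[i]] - tx$block_starts[[i]], collapse = ","), ","),
    character(1))
  offs <- vapply(seq_len(nrow(tx)), function(i)
    paste0(paste(tx$block_starts[[i]] - tx$start[i], collapse = ","), ","),
    character(1))
  out <- data.frame(
    tx$chrom, tx$start, tx$end, tx$id, 0L, tx$align_strand,
    tx$start, tx$end, "0,0,0", lengths(tx$block_starts), sizes, offs
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a RepeatMasker-style repeat BED (6 columns + subfamily, family)
#'
#' Columns: chrom, start, end, name, score, strand, subfamily, family.
#' The `name` column is ignored in favor of the explicit subfamily column.
#'
#' @param path Path to the tab-separated file (no header).
#' @param family_filter If non-`NULL`, keep only rows with this family
#'   (e.g. `"L1"`).
#' @return A `repeat_elements` data frame.
#' @export
read_repeats_bed <- function(path, family_filter = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  rep <- repeat_elements(x[[1]], x[[2]], x[[3]], x[[6]], x[[7]], x[[8]])
  if (!is.null(family_filter)) rep <- rep[rep$family == family_filter, ]
  rep
}

#' Write repeats as BED6 + subfamily + family
#' @param rep A `repeat_elements` data frame.
#' @param path Output path.
#' @export
write_repeats_bed <- function(rep, path) {
  out <- data.frame(rep$chrom, rep$start, rep$end, rep$subfamily, 0L,
                    rep$strand, rep$subfamily, rep$family)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read gene models from BED12 (one line per gene, exons as blocks)
#' @param path Path to a BED12 file.
#' @return A `gene_models` data frame.
#' @export
read_genes_bed12 <- function(path) {
  tx <- read_bed12(path)
  gene_models(tx$id, tx$chrom, tx$align_strand, tx$block_starts,
              tx$block_ends)
}

#' Write gene models as BED12
#' @param genes A `gene_models` data frame.
#' @param path Output path.
#' @export
write_genes_bed12 <- function(genes, path) {
  tx <- spliced_transcripts(genes$gene_id, genes$chrom, genes$strand,
                            genes$exon_starts, genes$exon_ends, 1L)
  write_bed12(tx, path)
}

#' Read aligned reads from BED6 into a read set
#'
#' @param path Tab-separated BED6 (chrom, start, end, name, score, strand).
#' @param library_size Total mapped reads in the library, for RPM
#'   normalization (supplied, not inferred from the file).
#' @return A `read_set` (see [read_set()]).
#' @export
read_reads_bed <- function(path, library_size) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  read_set(data.frame(chrom = x[[1]], start = x[[2]], end = x[[3]],
                      strand = x[[6]], stringsAsFactors = FALSE),
           library_size)
}

#' Write a read set as BED6
#' @param rs A `read_set`.
#' @param path Output path.
#' @export
write_reads_bed <- function(rs, path) {
  r <- rs$reads
  out <- data.frame(r$chrom, r$start, r$end, ".", 0L, r$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
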