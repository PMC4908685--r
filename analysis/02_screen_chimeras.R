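#!/usr/bin/env Rscript
# Step 2 — run the three-criterion screen on the simulated tables.
#
# Reads the BED/TSV files from step 1 (exercising the same I/O path a real
# spliced-EST table would take), resolves transcriptional strand from the
# intron-orientation table, screens for transcripts starting inside an
# antisense L1 and splicing into a gene exon, removes exonization-supported
# candidates, and compares the calls against the planted truth.

library(l1asp)

dir <- "results/sim"
tx <- read_bed12(file.path(dir, "transcripts.bed"),
                 file.path(dir, "orientation.tsv"))
repeats <- read_repeats_bed(file.path(dir, "repeats.bed"),
                            family_filter = "L1")
genes <- read_genes_bed12(file.path(dir, "genes.bed"))
truth <- read.delim(file.path(dir, "truth.tsv"))

res <- screen(tx, repeats, genes)
print(res)

write.table(res$accepted, "results/accepted_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$gene_overlaps, "results/gene_overlaps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$removed_exonization, "results/removed_exonization.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

planted <- truth$id[truth$label == "true_chimera"]
cat("\nsensitivity:",
    length(intersect(res$accepted$transcript_id, planted)) /
      length(planted),
    "  false calls:",
    length(setdiff(res$accepted$transcript_id, planted)), "\n")
cat("accepted calls by subfamily age class:\n")
print(table(res$accepted$subfamily_class))
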