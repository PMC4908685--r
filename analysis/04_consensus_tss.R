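#!/usr/bin/env Rscript
# Step 4 — map accepted transcript 5' ends onto the L1 consensus.
#
# Each accepted transcript is locally aligned (affine-gap, both
# orientations) to the consensus of its subfamily age class; the TSS is
# read off as a percent position along the consensus. Young classes are
# expected near the 5' UTR, ancient classes near the 3' end.

library(l1asp)
library(Biostrings)

accepted <- read.delim("results/accepted_calls.tsv")
fa <- readDNAStringSet("results/sim/transcripts.fa")
names(fa) <- sub("#.*$", "", names(fa))
consensus <- readDNAStringSet("results/sim/consensus.fa")

seqs <- as.character(fa[match(accepted$transcript_id, names(fa))])
prof <- build_profile(accepted$subfamily_class, seqs, consensus)

rows <- do.call(rbind, lapply(names(prof), function(cls) {
  p <- prof[[cls]]
  if (length(p$positions) == 0) return(NULL)
  data.frame(subfamily_class = cls, tss_percent = p$positions)
}))
write.table(rows, "results/tss_percent_positions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (cls in names(prof)) {
  p <- prof[[cls]]
  if (length(p$positions) == 0) next
  cat(sprintf("%-18s n=%2d  median %5.1f%%  unmappable %d\n", cls,
              length(p$positions), median(p$positions), p$n_unmappable))
}
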