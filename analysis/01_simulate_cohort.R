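#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study cohort.
#
# The generator plants 50 true antisense-promoter chimeras, 20 exonization
# decoys (each with an independent exon-L1-exon supporter), 30 plain gene
# transcripts, 5 undetermined-orientation records and 5 multi-alignment
# records, together with consensus-derived L1 sequences, transcript
# sequences and promoter-shaped read pileups. Everything downstream reads
# the plain-text files written here.

library(l1asp)

out <- "results/sim"
sim <- simulate_cohort(sim_config(seed = 42, sequences = TRUE,
                                  reads = TRUE))
write_sim(sim, out)

cat("cohort written to", out, "\n")
print(sim)
cat("\nPlanted subfamily age classes among true chimeras:\n")
print(table(sim$truth$class[sim$truth$label == "true_chimera"]))
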