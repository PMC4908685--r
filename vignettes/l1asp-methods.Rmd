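---
title: "Detecting and characterizing L1 antisense-promoter chimeric transcripts"
author: "l1asp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing L1 antisense-promoter chimeric transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Background and model

Full-length LINE-1 (L1) retrotransposons carry a bidirectional promoter in
their 5' UTR. Besides the sense promoter that drives the element's own
transcription, an antisense promoter (ASP) can initiate transcripts on the
opposite strand that splice into exons of neighboring genes, producing
chimeric RNAs: a 5' end derived from L1 antisense sequence fused to gene
exons. `l1asp` implements a genome-wide screen for such chimeras from
spliced transcript alignments (spliced ESTs, long-read isoform
predictions), plus the downstream characterizations that place the
antisense start sites on L1 consensus sequences and profile the promoter
chromatin.

A candidate is accepted when all three criteria hold:

1. **ASP initiation.** The transcript's transcription start site (TSS)
   lies inside an annotated L1 element and the transcriptional direction
   is antisense to that element.
2. **Genic splicing.** At least one aligned block of the transcript
   overlaps (>= 1 bp) an annotated exon of a gene.
3. **No exonization support.** No independent transcript (different
   record id) carries the same anchor L1 as an *internal* exon
   (exon–L1–exon). Intronic antisense L1s contain cryptic splice sites
   and can be exonized into ordinary gene transcripts; a transcript
   fragment of such an mRNA mimics ASP initiation, so any anchor with
   exonization support is conservatively discarded — the veto applies to
   every candidate anchored in that element, whether or not the
   supporting transcript splices into the same gene.

Because a cDNA's alignment strand reflects how the read was aligned, not
the direction of transcription, transcription strand is resolved from the
splice-site consensus summarized as a signed intron-orientation integer:
positive means transcription matches the alignment strand, negative means
it opposes it, and zero leaves the record undetermined. Undetermined
records are dropped automatically and counted (`dropped_zero_orientation`)
rather than curated by hand. Records whose id has several alignments are
flagged (`multi_alignment`) but never removed.

When a TSS falls inside two overlapping L1 annotations, the anchor is the
antisense element; if both qualify, the element with the larger overlap
with the TSS-containing block wins, with ties broken by smaller start.
This rule is arbitrary but deterministic, which we prefer to an
unreported dependence on input order.

## Subfamily age classes

Accepted calls are binned by the evolutionary age of the anchor's
subfamily: human-specific `L1HS` (with L1PA1 as a synonym), recent
primate `L1PA2_8` (L1PA2 through L1PA8), `ancient_primate` (all other
L1PA/L1PB/L1P names), and `ancient_mammalian` (L1M-type, L1ME, HAL1 and
every other L1-family name). No canonical name-to-bin table exists, so
the map is an ordered rule list (`default_subfamily_map()`) that can be
replaced from a two-column file. Half-L1 (HAL1) elements are included
with the ancient mammalian class.

## Coding potential

A transcript is called coding when any forward reading frame contains an
ATG-initiated open reading frame of at least 100 amino acids — the
conventional peptide threshold separating putative coding transcripts
from lncRNA-like ones. Peptide lengths count the initiator methionine
and exclude the stop codon; ORFs may be 3'-incomplete (no stop before
the sequence end) and are flagged accordingly. A codon containing `N`
conservatively ends translation at the preceding codon. All maximal
ATG-initiated ORFs are reported and the coding call is made on the
longest, so a single long ORF anywhere in the transcript suffices.
Reverse-strand frames are deliberately not scanned: the screen defines
the transcript orientation, so an antisense ORF would belong to a
different molecule. Model-based coding likelihoods and homology evidence
are out of scope; the criterion is purely structural.

## Consensus TSS mapping

To ask where on the element the antisense promoter fires, each accepted
transcript is aligned to the full-length consensus of its subfamily age
class with an affine-gap Smith–Waterman local alignment run in both
orientations (an ASP transcript reads off the antisense strand, so it
typically aligns as the reverse complement of the consensus). The TSS is
then the consensus coordinate matched to the transcript's 5'-most
aligned base — `consensus_start` for forward alignments,
`consensus_end - 1` for reverse-complement ones — expressed as a percent
of consensus length.

Numerical choices:

* scoring defaults to match +2, mismatch −3, gap open −5, gap extend −2;
  a gap of length L costs `open + L × extend`;
* alignments scoring below 40 are reported unmappable and counted —
  on 100–300 bp queries this suppresses spurious anchors (a score of 40
  corresponds to 20 exact matched bases);
* only the first 1000 nt of a transcript are aligned, since the 5' end
  is what is being placed;
* one consensus per age class (four sequences) rather than one per
  subfamily; the class-to-consensus assignment is an input, not a
  constant, since published consensus sets differ.

## Motif scanning

Position weight matrices in JASPAR count format are scanned over both
strands with the standard relative-score rule: the log2-odds score of a
window, rescaled by the PWM's attainable extremes
(`(s − s_min) / (s_max − s_min)`), must reach the threshold
(conventionally 0.9). Counts receive a pseudocount of 1% of the column
total (split evenly over the four bases) before column normalization
against a uniform background; both are configurable. Windows containing
a non-ACGT base never match. Site tables are reported 1-based inclusive
("448 to 453"), the dialect of motif-site reports, while all internal
coordinates stay 0-based half-open.

## Signal tracks and TSS metaprofiles

Read coverage is counted by full-interval overlap — every supplied
record once — and normalized to reads per million (RPM) using a supplied
library size, never one inferred from the (region-restricted) input.
ChIP enrichment over a consensus is the per-bp
`log2((chip + ε) / (input + ε))` with ε = 0.25 RPM by default, smoothed
by degree-1 LOESS with tricube weights and span α = 0.1 evaluated at
every base (exact on constant and linear tracks to machine tolerance).

TSS metaprofiles use a ±1000 bp window in 20 bins of 100 bp,
left-closed. Minus-strand windows are reversed before averaging so that
bin 1 is always 1000 bp upstream in transcription orientation; windows
leaving the reference are dropped and counted rather than padded. When
an input library is given its per-bin RPM profile is subtracted, so
`input = chip` cancels to exactly zero. For nascent-transcription data
(GRO-seq style), `strand_match = TRUE` keeps only reads on the TSS
strand. A 5'-end-only counting mode is deliberately absent from the
default path: depth-style counting is what the profiles elsewhere in the
package mean by enrichment.

## Statistics and reporting

The sense/antisense orientation split of transcript–gene overlaps is
tested with a Pearson chi-squared goodness-of-fit statistic against an
equal split — the only null consistent with asking whether chimeras
prefer one orientation. Degrees of freedom are `k − 1` and the p-value
comes from the chi-squared survival function. Benjamini–Hochberg step-up
adjustment is provided for any multiple-testing need and is checked
against a textbook reimplementation. Reports print percentages to one
decimal with numerators and denominators alongside, so every headline
fraction is an auditable count ratio.

## The synthetic cohort generator

Real inputs for this screen are large public alignment tables that
cannot be shipped or rebuilt here, so correctness is established on
synthetic cohorts with planted ground truth (`simulate_cohort()`). The
generator lays genes out on 12-kb slots of a small multi-chromosome
genome (three exons per gene) and plants:

* **true chimeras** — an anchor L1 antisense to the transcript, the TSS
  inside it, splicing into the host gene's second exon. 92% are sense to
  the cognate gene by default, matching the strong sense bias of real
  chimera catalogs;
* **exonization decoys** — the same local geometry plus an independent
  exon–L1–exon supporter transcript, so criteria 1–2 pass and
  criterion 3 must remove the candidate;
* **plain gene transcripts**, **zero-orientation records** and
  **multi-alignment records** (a second alignment of the same id in a
  spare slot).

Default cohort composition is 50 chimeras, 20 decoys, 30 plain records,
5 zero-orientation and 5 multi-alignment records — small enough that the
whole screen runs in about a second, large enough that every rule is
exercised many times per seed. Anchor classes are drawn with mix
(5% L1HS, 30% L1PA2-8, 20% ancient primate, 45% ancient mammalian),
approximating the age composition reported for genome-wide chimera
catalogs, where ancient elements dominate.

Anchor elements are consensus-derived segments around the planted TSS:
young-class anchors place the antisense TSS uniformly within the first
600 bp of the consensus (the 5' UTR), ancient-class anchors within the
final 20% of the element — the qualitative contrast the TSS-position
profiles are expected to reproduce. Genomic L1 copies are mutated away
from their consensus at 5% per base by default, a mid-range divergence
between young (<1%) and ancient (>15%) elements; the TSS-recovery
checks run at 0% and 10%. Transcript sequences are extracted from the
painted genome, so the records the screen accepts are the same records
the ORF caller and the consensus aligner see. Planted coding
transcripts (Bernoulli with rate 0.271, the coding fraction reported
for real chimera cohorts) carry one ORF of 100–268 aa (mean ≈ 140,
a shifted geometric); non-coding transcripts' exonic sequence is laced
with stop codons in all three frames so that no spurious 100-aa ORF can
arise, and the L1-derived first block is kept at 240 nt for the same
reason. Promoter-shaped read pileups put ~30 reads per TSS uniformly in
the 200 bp downstream (strand-matched for the GRO-style set), with a
uniform input library; consensus-reference ChIP reads pile at 20 bp and
450 bp, the two characterized YY1 positions on young L1 promoters. A
synthetic YY1-like count matrix ships in `inst/extdata/` and its sites
are planted at consensus positions 13–18 (minus strand) and 448–453
(plus strand).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: genomic repeat nesting and fragmented or
rearranged L1 copies, overlapping genes and alternative isoforms,
alignment error and chimeric artifacts in EST libraries, tissue
composition, indel mutations (only substitutions are simulated), and
biased genomic backgrounds. The screen's sensitivity of 1.0 on planted
cohorts reflects unambiguous planted geometry, not expected performance
on noisy public alignments.

## Problem sizes and determinism

Every source of randomness goes through R's RNG under a caller-supplied
seed; a fixed seed fixes every output byte. Oracle-equivalence suites run
100 random instances per engine (interval intersection vs an all-pairs
scan, the aligner vs a quadratic dynamic program, the PWM scanner vs
exhaustive window scoring, the ORF finder vs an exhaustive ATG scan, BH
vs the textbook step-up); screen correctness runs 20 seeded cohorts of
110 records; consensus TSS recovery uses 15-transcript cohorts against a
6064-bp consensus. These sizes keep the full suite in well under a
minute per component while leaving each property several hundred
assertions.

## Known limitations

* The exonization veto removes every candidate anchored in a supported
  element; loci where most transcripts favor ASP initiation over
  exonization are still vetoed, which is conservative.
* Orientation resolution trusts the single signed intron-orientation
  integer; multi-intron records with internally conflicting splice-site
  orientations are not re-examined.
* The local aligner reports one best alignment; multi-hit chaining and
  E-values are out of scope, so heavily rearranged elements may map to a
  secondary segment.
* PWM relative scores are not calibrated to p-values.
* Tissue/cancer annotation, GO enrichment and external database
  cross-referencing are outside the package: the report module stops at
  auditable count fractions.
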