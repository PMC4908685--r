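# l1asp — LINE-1 antisense-promoter chimeric transcript screen

Full-length LINE-1 (L1) retrotransposons carry a bidirectional promoter
in their 5' UTR. The antisense promoter (ASP) can fire into flanking
genomic sequence and splice into exons of neighboring genes, producing
chimeric transcripts: a 5' end from the L1 antisense strand fused to
gene exons. `l1asp` is an R package, with a driver workflow under
`analysis/`, for detecting such chimeras genome-wide from spliced
transcript alignments and characterizing them — for transcriptomics /
retrotransposon researchers who have spliced-alignment tables (EST-style
BED12 plus an intron-orientation table, or long-read isoform
predictions), a RepeatMasker-style L1 annotation and gene models.

## The screen

A spliced alignment record with resolved transcription strand is accepted
as an L1 ASP chimera iff

1. its TSS lies inside an annotated L1 element *E* and its transcription
   strand is antisense to *E* (`strand(tx) != strand(E)`);
2. at least one aligned block overlaps (≥ 1 bp) an annotated gene exon;
3. no independent record (different id) supports *exonization* of *E*,
   i.e. carries *E* as an internal exon–L1–exon structure.

Transcription strand comes from the intron-orientation integer *o*:
`txn = align` if *o* > 0, `txn = -align` if *o* < 0, undetermined
(dropped, counted) if *o* = 0. Multi-alignment ids are flagged, never
removed. Downstream modules classify anchors into four subfamily age
classes (L1HS, L1PA2–8, ancient primate, ancient mammalian), call coding
potential (ATG-initiated ORF ≥ 100 aa), place each transcript 5' end on
its class consensus by affine-gap local alignment (TSS as percent of
consensus length), scan position weight matrices at a relative-score
threshold `(s − s_min)/(s_max − s_min) ≥ 0.9`, and build ±1000 bp /
100 bp-bin input-subtracted RPM metaprofiles around TSSs. Everything is
exercised end-to-end on synthetic cohorts with planted ground truth
(`simulate_cohort()`).

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated cohort (50 planted chimeras, 20 exonization decoys, 30 plain
gene transcripts, 5 undetermined-orientation and 5 multi-alignment
records):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_screen_chimeras.R
...
Rscript analysis/06_report.R
```

Step 2 prints

```
L1 ASP chimera screen
  input records:            130
  dropped (orientation 0):  5
  accepted calls:           50
  removed (exonization):    20
  gene overlaps:            50

sensitivity: 1   false calls: 0
```

— all 50 planted chimeras recovered, every decoy removed by the
exonization veto, every ambiguous-orientation record dropped. Step 3
calls coding potential on the accepted transcripts
(`coding: 19/50 = 38.0% (planted 38.0%)`; called peptides averaged
142 aa). Step 4 places the antisense TSS on the class consensus: young
classes map into the 5' UTR (L1HS median 8.5%, L1PA2-8 median 4.9% of
consensus length) while ancient classes map to the 3' end (medians
≈ 88–89%) — the age-dependent promoter-position contrast the screen is
meant to expose. Step 5 recovers the planted YY1-like motif sites
(`13 to 18` on the minus strand, `448 to 453` on the plus strand, both
at relative score 1.0) and shows ChIP and strand-matched GRO
metaprofile maxima immediately downstream of the TSS (+150 bp bin).
Step 6 reproduces, as arithmetic on their printed counts, the headline
fractions of the published human chimera catalog (sense overlaps
2134/2316 = 92.1%, chi-squared = 1645.2, log10 p ≈ −359, coding
546/2015 = 27.1%, ...), confirming the reporting conventions.

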