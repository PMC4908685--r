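Package: l1asp
Title: Detection and Characterization of LINE-1 Antisense Promoter Chimeric Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A genome-wide screen for chimeric transcripts initiated at the
    LINE-1 (L1) antisense promoter, reconstructed from spliced transcript
    alignments. Candidate transcripts must start inside an annotated L1
    element in the antisense orientation and splice into an exon of a
    neighboring gene; candidates explained by L1 exonization are removed.
    Accepted calls are characterized by L1 subfamily age class, coding
    potential (open reading frames of at least 100 amino acids beginning
    with methionine), transcription start position on L1 consensus
    sequences via local alignment, position weight matrix scanning with a
    relative-score threshold, and ChIP/GRO-seq style metaprofiles around
    transcription start sites. A synthetic-data generator with planted
    ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
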