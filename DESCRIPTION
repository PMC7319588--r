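Package: lcrtools
Title: Detection and Annotation of Low Complexity Regions in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified toolkit for detecting low complexity regions (LCRs),
    compositionally biased regions and short tandem repeats in protein
    sequences. Implements five complementary detectors: SEG (two-pass
    Shannon-entropy segmentation with minimum-probability optimization),
    CAST (iterative homopolymer similarity with BLOSUM62), fLPS (binomial
    lowest-probability subsequences), SIMPLE (short-motif repetitiveness
    against shuffled-sequence nulls) and GBSC (repeat detection via weighted
    graphs of consecutive 2-mers). Adds per-position Shannon-entropy tracks,
    amino-acid frequency comparison, per-region residue enrichment,
    strict/permissive multi-method consensus, coverage statistics, sequence
    masking and a command-line interface over FASTA input with TSV, GFF3 and
    FASTA region output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
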