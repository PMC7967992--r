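Package: alnspect
Title: Pairwise Alignment Visualisation and Chimeric Read Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses pairwise alignments of long reads or contigs against
    reference sequences from five common formats (PAF, SAM, BLAST tabular,
    PSL, MUMmer coords/tiling), normalises them to a single 0-based
    half-open coordinate convention, flags potentially chimeric query
    sequences by an explicit geometric rule (exactly two non-overlapping
    alignments jointly covering most of the query), splits flagged reads at
    the estimated join for re-assembly, computes binned coverage of target
    sequences, and renders four types of publication-quality alignment and
    coverage diagrams as SVG or TikZ vector images. Includes a deterministic
    synthetic-data generator that plants chimeras with known joins so the
    whole pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
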