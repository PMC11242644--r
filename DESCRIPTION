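Package: mitorec
Title: Repeat-Mediated Recombination Analysis for Multipartite Plant Mitogenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the structural dynamics of multi-chromosomal
    plant mitochondrial genomes. Detects maximal exact repeats (direct and
    inverted) on circular molecules and decomposes overlapping copies into
    core/extension families; enumerates alternative genome conformations
    arising from repeat-mediated recombination (fission at direct repeats,
    inversion at inverted repeats); estimates per-repeat recombination
    frequencies from long reads spanning junction sequences; detects
    plastid-derived insertions (MTPTs) by seed-and-chain homology search;
    scans microsatellites with MISA-compatible thresholds; and computes
    codon-usage (RSCU), Nei-Gojobori Ka/Ks, and protein mass/isoelectric
    point statistics. Ships a ground-truthed synthetic mitogenome and
    long-read simulator so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
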