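Package: seriomap
Title: Pseudo-Testcross Linkage Maps and BAC-End Sequence Analysis for
    Outbred Fish Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of sex-specific genetic linkage maps from a single
    outbred F1 family by the pseudo-testcross strategy: backcross conversion of
    codominant SSR genotypes, two-point recombination and LOD analysis,
    LOD-threshold grouping, recombination-minimizing marker ordering with
    double-recombinant correction, and Kosambi map distances. Companion tools
    estimate genome length (interval-padding and (m+1)/(m-1) inflation
    estimators) and map coverage, summarize BAC libraries and end-sequence
    surveys, mine microsatellite (SSR) motifs from masked end reads, and
    post-process BLAST tabular hits into Oxford grids for comparative synteny.
    Simulators for crosses, reads and hit tables provide planted-truth inputs
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
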