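Package: rrbsdmr
Title: Differentially Methylated Region Calling from RRBS Coverage Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of reduced representation bisulfite
    sequencing (RRBS) CpG coverage tables: joint scoreability filtering of
    CpGs across samples, assembly of CpGs into regions by 50-bp proximity
    chaining, effect-size-threshold calling of differentially methylated
    regions, priority genomic-context annotation (TSS, promoter, exon,
    intron, intergenic) with distance to the nearest transcription start
    site, and cross-comparison region conservation. Includes a synthetic
    methylome generator with clustered CpG positions, negative-binomial
    read coverage, beta-binomial methylation counts and planted
    differentially methylated regions with a ground-truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
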