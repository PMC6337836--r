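Package: pstmap
Title: Peptide Sequence Tag Mapping for Proteogenomic Genome Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps de novo peptide sequence tags (short amino-acid tags
    flanked by N- and C-terminal fragment-ion masses) onto the six-frame
    translation of a genome, verifying both flanking masses under tryptic
    constraints and allowed modifications. Nearby hits are clustered into
    candidate coding regions, qualified against an existing GFF3 gene
    annotation (annotation status, confidence, consistency, and
    exon-mapping category), and exported as viewer-ready GFF3. Includes a
    synthetic proteogenome and tag simulator with ground truth, and
    sensitivity/selectivity evaluation of the mapping and clustering
    stages, so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
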