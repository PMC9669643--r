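Package: plastr
Title: Plastome Assembly Standardization and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-assembly toolchain for circular plastid genomes: detection
    of inverted repeats and resolution of the quadripartite LSC-IRb-SSC-IRa
    structure, standardization of assemblies into the canonical orientation
    against an annotated reference, selection among flip-flop isomer
    candidates, read-based correction of ambiguous bases, reference-based
    annotation transfer with a multi-round identity schedule (including
    intron/exon reconstruction and trans-spliced genes such as rps12),
    internal stop codon quality checks, GenBank flat-file and NCBI feature
    table (.tbl) output, and batch orchestration over many samples.  A
    ground-truthed synthetic plastome generator (genomes, annotations,
    isomer transformations, mutations, ambiguous bases and paired-end
    reads) makes the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
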