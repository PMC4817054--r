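Package: grannot
Title: Annotation and Classification of Insect Gustatory Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising an insect gustatory receptor (GR) gene
    repertoire from genome scaffolds: a tblastn-like six-frame translated
    homology screen against reference GR proteins, gene-model construction
    from GFF3, distance-based (neighbor-joining) subfamily assignment against
    reference anchor proteins with bootstrap support, structural typing of
    bitter receptors by intron content and polypeptide length, tandem
    gene-array detection on scaffolds, presence/absence expression profiling
    from read-count matrices, and Kyte-Doolittle transmembrane-topology
    prediction. Includes a synthetic-repertoire generator that emits
    ground-truthed genomes, count matrices and membrane proteins for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
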