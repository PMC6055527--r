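Package: crypticsplice
Title: Discovery of Splice-Site-Creating Mutations from RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects somatic mutations that create or strengthen cryptic
    splice sites by pairing a somatic mutation table with spliced RNA-seq
    alignments. Candidate alternative junctions are extracted from CIGAR
    N operations near each mutation, filtered against annotated introns,
    HLA loci and a mutation-free control cohort, scored with a
    maximum-entropy splice-site model for reference and mutant alleles,
    and quantified by junction allele fraction. Passing events are
    classified, aggregated by gene recurrence, and translated into
    candidate neoepitope peptides. A synthetic-fixtures module generates
    fully self-contained mini-genome test worlds with declared truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    rtracklayer,
    withr
Config/testthat/edition: 3
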