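Package: arffam
Title: Genome-Wide Characterization of Auxin Response Factor Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for genome-wide characterization of auxin
    response factor (ARF) transcription-factor families: candidate
    selection from Pfam-style domain annotations, protein
    characterization (deduced length, molecular weight, isoelectric
    point), middle-region composition-based activator/repressor
    classification, exon-intron gene structure, neighbor-joining
    phylogeny with bootstrap support and cross-species sister-pair
    detection, IUPAC-degenerate auxin response element (AuxRE) promoter
    scanning, and 2^-ddCt qRT-PCR expression profiling.  A seeded,
    manifest-backed synthetic-data generator makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    phangorn,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
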