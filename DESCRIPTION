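Package: nacfam
Title: Genome-Wide Cataloguing of NAC Transcription-Factor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing a transcription-factor gene family in a
    plant genome, modelled on the comparative-genomics workflow used for the
    sunflower NAC family: translated-search locus mining, orthogroup
    assignment by best-hit consensus against a labelled reference database,
    progressive multiple alignment with conserved-block cleaning, iterative
    distance-based phylogenetic refinement of divergent clusters, tandem and
    whole-genome-duplication paralog detection, exon/intron architecture
    typing, ZOOPS EM protein-motif discovery with motif-architecture
    classification, position-weight-matrix promoter scanning, and
    senescence-candidate calling from a differential-expression table. A
    seeded synthetic-data generator produces a toy genome with full planted
    truth so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    GenomicRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
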