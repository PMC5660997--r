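Package: aranevir
Title: RNA Virome Discovery and Characterization from Transcriptome Assemblies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering and characterizing
    RNA virus genomes in de novo transcriptome assemblies, modelled on
    arthropod (orb-weaver spider) virome workflows: six-frame translated
    homology search of transcripts against a viral protein reference with
    E-value filtering, ORF and polyprotein annotation under a stop-inclusive
    coordinate convention, detection of -1 programmed ribosomal frameshift
    signals (slippery heptamer plus H-type pseudoknot), scoring of
    complementary panhandle genome termini, grouping of multipartite genome
    segments by presence patterns and co-expression, screening against the
    host genome and DNA reads for endogenous viral elements (EVE), and
    host-normalized FPKM quantification per tissue library. Includes a
    fully specified synthetic-data generator with machine-readable ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
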