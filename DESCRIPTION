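Package: panmarker
Title: Pan-Genome Discovery of Species-Specific Marker Genes and qPCR Assay Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers species-unique marker genes from a pan-genome of closely
    related bacterial genomes and turns them into a quantitative real-time PCR
    assay. Genes from all genomes are clustered into orthologous families by a
    deterministic greedy centroid algorithm at a sequence-identity cutoff; the
    resulting presence/absence matrix is partitioned into core, accessory and
    singleton genes and summarised as gene-content and core-gene
    neighbor-joining trees. A clade-specificity screen finds clusters present
    in every genome of a target species and absent (or too divergent) in all
    others, ranks candidates by primer-design suitability, designs a specific
    primer pair inside the selected marker, validates it by in-silico PCR
    against every genome, and models the resulting assay by standard-curve
    regression (slope, R-squared, amplification efficiency). A synthetic
    community generator with full ground truth makes every stage testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    jsonlite
Config/testthat/edition: 3
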