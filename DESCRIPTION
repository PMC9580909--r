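Package: traitguilds
Title: Trait-Based Representation of Microbial Genomes and Data-Driven
    Functional Guilds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps microbial genome sequences into a hierarchical trait
    space. Gene families are detected with profile hidden Markov models
    (via HMMER) filtered at per-model trusted bit-score cutoffs chosen by
    F-score maximisation on labelled benchmark scores; Boolean
    predicate-logic rules roll gene presence up into binary traits and
    substrate-class-resolved complex counts, which are normalised by
    genome size into per-base-pair genomic investments. Life-history
    traits (minimum doubling time, optimal growth temperature) are
    predicted from codon-usage bias of ribosomal proteins and from
    genome/proteome compositional features through pluggable linear
    models. Functional guilds are discovered from the mixed-type trait
    matrix with a variance-weighted (Wishart) distance, complete-linkage
    hierarchical clustering and distance-based variance partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
SystemRequirements: HMMER3 (hmmsearch, hmmbuild), Prodigal
Config/testthat/edition: 3
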