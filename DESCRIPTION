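Package: ednapipe
Title: Environmental DNA Metabarcoding from Tagged COI Amplicons to
    Habitat Signatures
Version: 0.1.0
Authors@R:
    person("Mei", "Tan", email = "mei.tan@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for environmental DNA (eDNA)
    metabarcoding of the 313-bp mitochondrial COI fragment: simulation of
    tagged amplicon sequencing runs with known ground truth, demultiplexing
    by 9-bp primer tags, degenerate-primer trimming, error pruning,
    reference-identity and mitochondrial-translation filtering, a
    PCR-replicate consistency rule, single-linkage MOTU delimitation at an
    uncorrected p-distance threshold, identity-band taxonomic assignment,
    incidence-based richness estimation (Chao2, ICE), community
    dissimilarities (Jaccard, Morisita-Horn, Renkonen), NMDS ordination,
    habitat-signature classification of samples from presence-absence
    profiles, and comparison of eDNA detections against conventional
    survey checklists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
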