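Package: copresnet
Title: Co-Prescription Pattern Mining and Network-Proximity Drug Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrative analysis of longitudinal drug co-prescription
    records against a molecular disease network, developed around the
    pharmacotherapy of chronic peritoneal dialysis. Provides drug-name
    harmonization by Jaro-Winkler string clustering, patient-time Jaccard
    co-prescription mining with prevalence-based pattern classification,
    five drug-drug similarity metrics (mechanism, target, pathway,
    structure, ATC class), disease-module extraction from a
    protein-protein interaction network around differentially expressed
    genes, network-proximity screening of drug-target clusters with a
    degree-preserving randomization null model, and multi-criteria
    prioritization of candidate drug combinations. A seeded synthetic-data
    generator emulates the clinical and molecular inputs so the full
    pipeline is testable without access to clinical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
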