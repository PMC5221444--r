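Package: propsyn
Title: Thermodynamics and Clone-Library Community Analysis of Syntrophic
    Propionate Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying syntrophic propionate-degrading microbial
    consortia from anaerobic digesters. Evaluates Gibbs free energies of the
    anaerobic reactions linking propionate oxidation, methanogenesis,
    syntrophic acetate oxidation and autotrophic homoacetogenesis across
    hydrogen partial pressures, locates thermodynamic crossover points and
    feasibility windows, and reconstructs community composition from 16S rRNA
    clone libraries: in-silico PCR with degenerate primers, restriction
    (ARDRA) fingerprint grouping, identity/coverage sequence clustering,
    taxonomy assignment, dominance filtering, functional-guild summaries and
    succession trends. A seeded synthetic-data generator produces mock marker
    genes, clone libraries and substrate-decay curves so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
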