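Package: ecodiverge
Title: Forward-Time Simulation of Bacterial Ecological Divergence with Gene Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based Wright-Fisher simulation of two bacterial
    subpopulations adapting to opposite phenotypic optima while connected by
    DNA flow through homologous recombination. Models an additive quantitative
    trait with fixed or freely evolving allele effect sizes, gene conversion
    from global or niche-local allele pools, and flexible genome evolution via
    gene loss and gain. Includes the per-locus leading-allele divergence and
    genome-content summary statistics used to quantify divergence-with-gene-flow
    genetic architecture, a factorial experiment driver with replicate seed
    management, configuration and snapshot input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
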