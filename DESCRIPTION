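Package: episelect
Title: Selection Strategy Evaluation for Epigenetic Field Trials in Sorghum
Version: 0.1.0
Authors@R: person("EpiSelect", "Maintainers", email = "episelect@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate percentile-truncation selection strategies on
    epigenetically diversified but genetically isogenic crop populations.
    Implements two-level (family mean plus individual plant) percentile
    classification against wild-type check yields, retroactive comparison of
    unselected, line-mean and line-plus-individual selection strategies with
    mixed-model least-squares means, genotype-by-environment resilience metrics
    (yield differential and stable/dynamic calls), area-under-the-plant-
    emergence-curve (AUPEC) analysis of cold-stress germination trials, and
    Fisher's exact testing of reversion-frequency tables. A synthetic
    field-trial generator emulates the augmented-lattice, multi-location
    designs the analysis assumes, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
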