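Package: amfassembly
Title: Community Assembly Analysis for Soil Fungal OTU Tables Under Pollution Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify deterministic versus stochastic assembly of
    soil microbial (notably arbuscular mycorrhizal fungal) communities along
    urban heavy-metal pollution gradients. Implements Levins' niche breadth
    with a permutation null to classify OTUs as habitat generalists or
    specialists, abundance-weighted beta mean nearest taxon distance (betaMNTD)
    with a tip-shuffling null yielding the beta nearest taxon index (betaNTI),
    Sloan's neutral community model fit (migration rate, goodness of fit,
    95% prediction bands, neutral partition), single-factor and Nemerow
    composite pollution indices, and the supporting correlation and
    regression layer (Bray-Curtis, Mantel, Spearman, OLS, Venn partitions).
    A synthetic-data module generates OTU tables, phylogenies and metadata
    with known assembly processes so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
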