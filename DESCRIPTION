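Package: pahnet
Title: Toxicity, Diversity and Co-Occurrence Networks for PAH-Polluted Saline Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for aged, PAH-contaminated saline soils sampled
    along a salinity gradient with paired vegetated and bare plots. Summarizes
    16-congener PAH profiles into molecular-weight fractions, benzo[a]pyrene
    toxic equivalents (TEQ) and contamination classes; computes genus-level
    alpha diversity (Chao1, Shannon), Bray-Curtis dissimilarity and NMDS
    ordination; performs absolute qPCR quantification of 16S rRNA and
    PAH-degradation genes from standard curves; relates communities to soil
    physicochemistry via Spearman correlation, Mantel tests, redundancy
    analysis and Tukey HSD letter displays; and builds Spearman co-occurrence
    networks with Erdos-Renyi null ensembles, Louvain modules, small-world
    assessment and betweenness-centrality keystone ranking. A synthetic study
    generator emulating the 3-region x 2-cover design makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
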