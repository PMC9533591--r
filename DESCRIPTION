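Package: saratools
Title: SARA Susceptibility Classification and Fecal Microbiome Analytics
    for Transition Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for subacute ruminal acidosis (SARA) monitoring in
    periparturient dairy cattle. Converts irregular reticular pH bolus
    traces into daily time-below-threshold and area-under-the-curve
    statistics and classifies cows into four SARA-susceptibility groups;
    processes fecal 16S amplicon sequence variant (ASV) count tables
    (low-abundance filtering, rarefaction, taxonomic collapse, alpha
    diversity including Faith's phylogenetic diversity, Bray-Curtis
    dissimilarity, principal-coordinate analysis, PERMANOVA, hierarchical
    clustering); tests differential abundance with ANCOM plus post-hoc
    Wilcoxon letters; dispatches scalar phenotypes to ANOVA/Tukey or
    Kruskal-Wallis/Wilcoxon paths; and quantifies qPCR and
    gas-chromatography assays. A synthetic cohort generator produces pH
    traces, ASV tables, phylogenies and assay tables with known ground
    truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
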