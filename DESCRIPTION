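Package: swabshade
Title: Colorimetric Swab Scoring and Darkness-Stratified Rumen Microbiome
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing how well oral swabs recapitulate the rumen
    microbiome of dairy cattle as a function of swab color. Provides
    colorimetric darkness scoring of swab photographs (center crop,
    grayscale conversion, mean-pixel darkness), ASV count-table
    normalization (rarefaction, minimum-abundance filtering, relative
    abundance, taxonomic aggregation), darkness-based sample grouping
    (deciles and extremes), alpha and beta diversity (Chao1, Shannon,
    inverse Simpson; Bray-Curtis, Jaccard, unweighted UniFrac), principal
    coordinates analysis with PERMANOVA and darkness-vs-axes regression,
    SIMPER decomposition with Kruskal-Wallis/FDR differential ASV calling,
    prevalence-based core-microbiome capture statistics, and a
    Dirichlet-multinomial synthetic-study generator with a planted
    darkness-to-rumen-content link for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    png,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
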