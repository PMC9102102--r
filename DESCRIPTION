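Package: demsa
Title: Niche-Segmentation Analysis of Biolog EcoPlate Community-Level
    Physiological Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for community-level physiological profiling (CLPP) of soil
    microbial communities assayed on 96-well Biolog EcoPlates. Beyond the
    conventional metrics (total activity, average well colour development,
    Shannon and Simpson diversity, PCA ordination, one-way ANOVA with LSD
    letter displays), the package implements the DEMSA model: each sample's
    31-substrate utilisation profile is decomposed against the control
    community's per-substrate niche range (minimum, mean, maximum) into four
    complementary segments - intensification and expansion above the control
    mean, narrowing and contraction below it - which are aggregated into
    functional-guild matrices, percent synthetic indices, guild and
    functional-group dominance-codominance associations, a signed functional
    alteration index, and within- and between-community functional
    resemblance. A seeded synthetic EcoPlate generator with guild-structured
    treatment effects supports testing and method evaluation without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
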