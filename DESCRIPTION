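Package: nullcomm
Title: Rank-Abundance-Matched Null Models for Hemiparasite Associations
    with Plant Community Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a focal guild of plants (root
    hemiparasites) is associated with higher community evenness or species
    richness beyond what is expected for equally uncommon plants. Implements
    per-plot community metrics (richness, Shannon evenness, summed cover by
    growth form), a global rank-abundance framework that draws rank-matched
    null focal-species sets, mutual-nearest-neighbour plot pairing within
    ecoregions for presence contrasts, linear mixed models with empirical
    null coefficient distributions and delta-AIC screening, and a synthetic
    community generator with a known, tunable focal-guild effect for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
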