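Package: plclock
Title: Placental Epigenetic Clocks for Gestational Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and applying placental epigenetic clocks:
    quality control and harmonization of Illumina methylation beta matrices,
    elastic-net gestational-age clock training and prediction, gestational-age
    acceleration, a DNA-methylation fetal-sex classifier, and a stratified
    epigenome-wide association study based on the biweight midcorrelation with
    weighted Stouffer meta-analysis. Includes a synthetic placental-methylome
    simulator with ground-truth emission for validating every step of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
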