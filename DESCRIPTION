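Package: terrasoc
Title: Terracing-Induced Soil Organic Carbon Change: Stocks, Monte Carlo
    Imputation, FTIR Chemistry and Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for quantifying and attributing changes in
    soil organic carbon (SOC) stocks caused by agricultural terracing.
    Computes depth-explicit SOC stocks from soil-horizon records (measured or
    pedotransfer bulk density, gravel correction, gridded-product depth
    harmonization); imputes non-terraced controls from gridded soil products
    through a Monte Carlo bias-calibration framework with full uncertainty
    propagation into credible intervals and SOC-aridity regressions;
    semi-quantifies organic-matter chemistry from FTIR spectra (aliphatic,
    carboxylic and aromatic band heights and their ratios); and attributes
    SOC change to climate, soil geochemistry and plant productivity via
    rotated principal components, linear mixed models, variation
    partitioning, random-forest cross-validation and composite path models.
    A seeded synthetic-world generator with known ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    randomForest,
    signal,
    vegan,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
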