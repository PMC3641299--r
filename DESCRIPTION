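Package: degrisk
Title: Vegetation-Trend Detection and Spatial Logistic Risk Mapping of
    Cropland Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage analysis of cropland degradation in irrigated
    drylands. Stage one screens, gap-fills and smooths 16-day vegetation
    index composites with a quality-weighted adaptive Savitzky-Golay
    filter, sums them over the growing season, fits per-pixel linear
    trends of the seasonal sum, and classifies significant negative
    trends as degraded land. Stage two assembles environmental and
    management factor grids (distances, line densities, kriged
    groundwater surfaces, land-use flags), draws a spatially thinned
    sample, screens multicollinearity by variance inflation factors,
    fits a spatial logistic regression of degradation on the factors,
    validates it by ROC and percent correctly predicted, and maps
    decile classes of degradation risk. A seeded synthetic-scenario
    generator provides a complete artificial study region with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
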