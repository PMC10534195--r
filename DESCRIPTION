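Package: bcvcalc
Title: Multi-Scheme Calculation and Comparison of Bioclimatic Variables
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the 19 standard bioclimatic variables (BIO1-BIO19) from
    gridded minimum/mean/maximum temperature and precipitation time series
    while making every calculation-scheme choice explicit: climatological
    (CLIM) versus year-by-year (BIO) selection of the period of interest,
    absolute versus mean monthly temperature extremes, the source of mean
    temperature, and the convention used for three-month quarters that cross
    the December/January boundary.  Includes shift and agreement diagnostics
    that quantify how scheme choices move the selected month or quarter,
    Taylor statistics (normalized standard deviation, centered RMSE,
    correlation) for comparing variable fields against a reference, a seeded
    synthetic gridded-climate generator for controlled experiments, CF NetCDF
    and ESRI ASCII grid input/output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
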