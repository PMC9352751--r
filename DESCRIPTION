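Package: vegindex
Title: Near-Real-Time Vegetation Index Composites and Drought Anomaly Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Production pipeline for satellite vegetation-condition monitoring:
    computes daily NDVI from RED/NIR surface-reflectance rasters in the MOD09GQ
    convention, builds weekly and biweekly maximum-value composites on an
    ISO-8601 calendar, maintains per-pixel multi-year climatologies
    (min/max/mean/median), derives the anomaly indices VCI, MVCI, RMVCI and
    RVCI, and encodes every product to the operational 8-bit format
    (valid 0-250, no-data 255) with its layer-naming convention. Includes a
    seed-reproducible synthetic scene generator for end-to-end testing and a
    minimal GeoTIFF reader/writer for unsigned 8-bit and signed 16-bit
    single-band rasters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
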