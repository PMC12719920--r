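Package: wepmap
Title: Stepwise Juniper Distribution Modeling and Woody-Encroachment
    Vulnerability Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A raster pipeline for mapping evergreen juniper encroachment on
    rangelands from co-registered open remote-sensing inputs. Implements
    multi-source exclusion masking (water/crop land cover, category-buffered
    road corridors, sub-acre urban parcels), canopy-height filtering, dual
    NDVI/EVI tree-cover classification from leaf-on imagery, leaf-off winter
    compositing and NDVI thresholding to isolate evergreen juniper, buffer
    based woody-encroachment vulnerability staging, zonal attribute summaries
    per parcel or administrative unit, and segmented error-matrix accuracy
    assessment with Cohen's kappa and paired map comparison. Ships a synthetic
    landscape generator with known ground truth so the full pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
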