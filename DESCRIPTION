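Package: habfoot
Title: Cumulative-Impact Habitat Modelling for the Black-Throated Finch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for assessing cumulative impacts of extractive
    and exploratory mining tenure on an endangered bird. Fits a presence-background
    maximum-entropy climate envelope with a target-group background, refines it
    into a habitat model using vegetation-class selection and metric buffering,
    overlays dated tenure polygons, and produces tenure-free, priority-zone and
    biodiversity-offset sufficiency accounting. Ships a synthetic-landscape
    generator with known ground truth so every stage is testable without any
    proprietary spatial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
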