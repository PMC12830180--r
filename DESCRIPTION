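Package: iristiles
Title: RESTful Tile Server and Tile-Source Client for Pyramidal Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight slide-serving microservice for digital pathology and
    its companion tile-source client. Stores multi-resolution pyramids of
    JPEG-compressed 256x256 tiles in a validated single-file binary container,
    streams tiles and slide metadata over two HTTP GET dialects (a native
    RESTful grammar and a DICOMweb WADO-RS compatible mapping), and keeps a
    reference-counted cache of open slide handles shared between client
    sessions. Includes strict request parsing with a plain-text error taxonomy,
    a restricted static-file mode, CORS support, self-signed RSA certificate
    generation, deterministic synthetic-slide generators for testing, DeepZoom
    (DZI) export for cross-format comparison, and a ramped virtual-user load
    harness reporting latency percentiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    curl,
    digest,
    ggplot2,
    jpeg,
    jsonlite,
    openssl,
    optparse,
    parallel,
    png,
    tibble,
    tools,
    utils,
    stats,
    xml2
Suggests:
    callr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
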