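Package: ekmanbloom
Title: Wind-Driven Upwelling and Summer Phytoplankton Bloom Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wind-driven coastal upwelling and summer
    phytoplankton blooms on gridded satellite-style fields. Computes surface
    wind stress from 10-m winds by a bulk formula, Ekman pumping velocity from
    the wind-stress curl and coast-parallel offshore Ekman transport, builds
    seasonal, fifteen-day and climatological composites, decomposes anomaly
    fields into empirical orthogonal functions (EOF), and links box-averaged
    chlorophyll-a to upwelling forcing through multiple and partial
    correlations computed from correlation-matrix cofactors. Ships a seeded
    synthetic-field generator emulating a monsoon wind with an abrupt
    late-summer intensification, upwelling-cooled sea surface temperature and
    lagged chlorophyll blooms, with known ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    jsonlite,
    yaml,
    stats,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
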