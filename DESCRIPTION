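Package: caudseg
Title: Break-Point Analysis of Caudal Vertebral Measurement Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial measurements along vertebrate tails,
    built around segmented (broken-stick) regression of centrum length on
    vertebra number. Provides a Davies test gate for the existence of a break
    point, iterative-linearization segmented fitting with bootstrap restarting
    for 1-4 break points, AIC-based model selection with a discontinuous
    two-regime fallback, a randomization test for the proximity of fitted
    break points to the anatomical transition point of the lateral processes,
    femur-scaled allometric regression of snout-sacrum length on tail length,
    and a synthetic-data generator emulating dinosaurian caudal series and
    allometric cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
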