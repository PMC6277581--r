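Package: fxscreen
Title: Single-Step FMR1 CGG-Repeat Expansion Screening by Melt Curve
    Analysis with Reflex Capillary-Electrophoresis Sizing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a two-tier fragile X syndrome screening
    workflow from dried-blood-spot DNA. Tier one is triplet-primed PCR melt
    curve analysis: melt traces are transformed to -dF/dT profiles, the
    last-peak melting temperature is called with sub-grid refinement, and
    samples are classified as expanded or non-expanded relative to an
    intermediate/gray-zone boundary calibrated from four 46-54-repeat control
    DNAs, with a retest-at-higher-template policy for flat profiles. Tier two
    is reflex capillary-electrophoresis sizing of screen-positive and
    indeterminate samples: triplet-primed PCR ladder peak counting with
    full-mutation and mosaicism detection, and repeat-spanning PCR amplicon
    conversion with GC mobility correction. A synthetic-signal generator
    emulates repeat-length-dependent melt transitions, concentration-dependent
    Tm jitter and amplitude, 3-bp electrophoretic ladders, biallelic female
    superposition and full-mutation dropout, so the whole pipeline is testable
    without instrument data. Ships the 151-sample reference cohort used to
    validate the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
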