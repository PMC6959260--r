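Package: cotswatch
Title: Citizen-Science Surveillance and Triage of Crown-of-Thorns Starfish Outbreaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for running a citizen-science surveillance workflow for
    crown-of-thorns starfish (COTS, Acanthaster spp.) outbreaks: ingestion and
    validation of standardized observation reports (CSV or GeoJSON), a
    four-level semi-quantitative abundance scale with two-level management
    triage, 5 km x 5 km quadrat occupancy and range-size analysis contrasting
    professional and non-professional observers, conversion and three-level
    outbreak classification of verification surveys (belt transects and timed
    swims), and a seeded simulator of patchy reef populations, observer
    behaviour and underwater visual census sampling so the whole pipeline can
    be exercised and tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
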