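Package: palsim
Title: Modular Pasture and Livestock Agroecosystem Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular, spatially explicit simulator of pasture growth,
    livestock grazing and the soil nitrogen cycle at a daily timestep.
    Component models for climate limiting factors (temperature, radiation,
    soil moisture), vegetation life cycle (potential and actual growth,
    senescence, litterfall, harvest), livestock (intake, digestion, weight
    change, excretion) and nitrogen cycling (mineralization, uptake,
    reabsorption, leaching) are wired together by a concept-based dataflow
    engine that resolves a queried concept into a directed acyclic graph of
    components, executes it over a user-chosen grid and timeline, and emits
    provenance (DOT dataflow graph and a structured report). A seeded
    synthetic-landscape generator produces all required inputs so every
    component is runnable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
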