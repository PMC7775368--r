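Package: mofs
Title: Spatio-Temporal Analysis of Behavioral Dynamics in a Modified
    Open-Field System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rodent movement in a modified open-field
    arena with a floor-level water dispenser delivered on fixed-time or
    variable-time schedules. Provides arena and zone-grid geometry,
    trajectory and delivery-log input/output, grid occupancy maps,
    relative distance-to-dispenser series with moving-average smoothing,
    delivery-moment localization, categorical recurrence plots, Shannon
    entropy of spatial occupancy, Kullback-Leibler divergence between
    sessions, path length, a seeded correlated-random-walk simulator of
    rat agents with thigmotaxis and across-session learning, and a
    reproducible simulate-analyse-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
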