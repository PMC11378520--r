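Package: screenflow
Title: Resource-Needs Modelling for Cancer Screening Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models a cancer screening program as a probabilistic task graph
    (process map) in which each step consumes fixed per-patient minutes of
    named human resources and routes patients onward with stated
    probabilities. Propagates expected patient counts through the graph,
    aggregates per-resource minutes, and converts totals to full-time
    equivalents (FTEs). Includes one-way sensitivity analysis over
    population, branch probabilities and task durations with exact crossover
    detection, a patient-level Monte Carlo simulator for verification, and a
    staffing-capacity inversion that finds the maximum screenable population
    and the bottleneck resource. Ships the demonstrative Veterans Affairs
    lung-cancer-screening model as a built-in fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
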