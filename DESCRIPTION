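Package: dopaflow
Title: Knowledge-Driven Design-Build-Test-Learn Analysis for a Two-Enzyme
    Dopamine Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rational balancing of the bi-cistronic
    HpaBC/Ddc dopamine pathway in Escherichia coli. Simulates the in vitro
    crude-lysate ratio titration as a two-step Michaelis-Menten cascade
    (l-tyrosine to l-DOPA to dopamine, with an optional first-order l-DOPA
    oxidation sink), translates an optimal enzyme ratio into bi-cistronic
    ribosome-binding-site designs by translation-initiation-rate ratio
    matching over the 6-nt Shine-Dalgarno space, and analyses strain cohorts:
    build-success accounting, titre and yield benchmarking, and GC-content
    stratified trend analysis. A synthetic-data module generates RBS
    characterization libraries, strain cohorts from a planted response
    surface, and build logs, so the whole pipeline is testable without
    wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
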