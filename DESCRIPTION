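Package: shiftpdc
Title: Permutation Distribution Clustering of Shift-Work Rosters and
    Sickness-Absence Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cleans payroll shift logs into per-employee working-hour time
    series (shift length, between-shift rest, start hour), clusters
    employees by permutation distribution clustering with complete-linkage
    agglomeration and BIC model selection, assigns new series to reference
    clusters by nearest-neighbour codebook distance, scores shift
    ergonomics (long work spells, night-shift load, quick returns), and
    models sickness-absence rates with offset Poisson regression. Ships a
    synthetic roster generator for eight working-hour archetypes so the
    whole pipeline can be exercised without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
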