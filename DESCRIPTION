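Package: hypoxphys
Title: Hypoxia-Acclimation Physiology: Respirometry, Hemoglobin-Oxygen
    Equilibria, qPCR Expression and Gill Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-animal and blood-level hypoxia
    physiology in fishes. Converts intermittent-flow respirometry oxygen
    traces into oxygen uptake rates, standard metabolic rate (lowest-decile
    estimator) and critical oxygen tension (Pcrit, SMR-crossing rule with
    interpolated breakpoint); fits Hill plots to hemoglobin-oxygen
    equilibrium curves to obtain P50, Hill coefficients and Bohr
    coefficients; computes efficiency-corrected relative qPCR expression
    (Pfaffl-style delta-delta Ct and anchored within-sample relative
    abundance of hemoglobin subunit isoforms); and estimates mass-specific
    gill surface area by the Hughes A = LfB method. A synthetic-data
    generator produces oxygen traces, oxygen-equilibrium plates, Ct tables
    and gill morphometry with known ground truth, so every estimator is
    testable by parameter recovery. Includes the group-comparison layer
    (Welch/pooled t tests, paired one-tailed t, two-way ANOVA with Type-II
    sums of squares for unbalanced designs) and a desk-scale study
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
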