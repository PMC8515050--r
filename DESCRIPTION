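Package: pgpscreen
Title: Screening, Scoring and Diversity Analysis of Plant-Growth-Promoting Endophytic Bacteria
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for culturable endophyte screening studies: converts raw
    colorimetric assay readings (CAS siderophore, Salkowski IAA, molybdate
    phosphate, Nessler ammonia, crystal-violet biofilm, chlorophyll extraction)
    into quantified traits via standard curves; holds the per-isolate trait
    matrix and computes prevalence, tissue breakdowns and trait-set
    intersections; ranks isolates on an additive 13-point bonitur scale;
    computes alpha-diversity profiles (Shannon, bias-corrected Simpson
    dominance, Berger-Parker, Margalef, Menhinick, Pielou/Hill evenness) from
    genus count tables; and analyses nursery growth trials with balanced
    two-way ANOVA, correlation-matrix PCA and treatment-versus-control fold
    change. A seeded synthetic-data generator emulates the statistical
    structure of a full screening campaign so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
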