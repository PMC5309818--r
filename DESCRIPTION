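Package: timbr
Title: Transcriptionally Inferred Metabolic Biomarker Response for
    Constraint-Based Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic networks
    with an emphasis on comparative biomarker prediction. Provides a data
    model for compartmentalized metabolic networks with boolean
    gene-protein-reaction (GPR) rules, SBML (Level 3 + FBC) and tabular
    model I/O, flux balance and flux variability analysis, metabolic-task
    feasibility testing, consensus orthology filtering and GPR translation
    between species, flux-variability-based biomarker prediction for
    inborn errors of metabolism, and the TIMBR algorithm: weighted
    parsimonious flux minimization that scores each exchangeable
    metabolite by the relative network demand of its production under
    treatment versus control gene expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
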