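Package: proflux
Title: Proteome-Constrained Flux Balance Analysis of Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models with
    quantitative proteome integration. Reads and writes metabolic models
    (JSON, SBML with fbc-style gene associations, TSV), parses and evaluates
    gene-protein-reaction Boolean rules under min/max semantics, derives
    E-flux expression bounds from replicate proteome intensities with Welch
    t-test differential-expression selection, solves the two-stage linear
    program (biomass maximization followed by total-absolute-flux
    minimization), simulates in silico reaction knockouts and
    overexpression, and performs comparative flux classification with
    data-driven fold-change cut-offs, pathway summaries and KEGG Mapper
    colour export. Includes generators for small stoichiometrically
    consistent test networks with analytically known optima and synthetic
    replicate proteomes with injected differential expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    withr,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
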