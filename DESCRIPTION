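Package: domainflux
Title: Correlated Domain Motions and Partial Steering in Coarse-Grained
    Trimeric Transporter Models
Version: 1.0.0
Authors@R:
    person("Domainflux", "Developers", email = "domainflux@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for studying correlated domain motions in
    trimeric multi-domain transporters on coarse (C-alpha bead) models.
    Generates synthetic trimers with planted rigid-body subdomain motions,
    linear correlation blocks and phase-coupled (nonlinear) pairs; runs
    overdamped Langevin dynamics on an elastic network with a targeted-MD
    (RMSD steering) biasing potential over configurable steering selections;
    computes per-residue RMSF, Pearson and generalized (k-nearest-neighbour
    mutual-information based) correlation matrices with RMSF/correlation
    filtering, block summaries and structure mapping; and analyses subdomain
    RMSD-to-target, centre-of-mass displacement and principal-axis
    orientation angles. Reads and writes multi-model PDB and XYZ text
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
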