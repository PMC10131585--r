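Package: georoute
Title: Geometric-Route Binding Free Energies, PMF Estimation, and
    MM-GBSA Screening for Cyclic Peptide Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for absolute binding free energy
    calculations of peptide:protein complexes by the staged "geometric
    route": harmonic-restraint free energies from potentials of mean
    force, an analytic orientational-restraint term, the separation
    (standard-state) term, and assembly of the nine-stage total with
    quadrature uncertainty propagation and conversion to a dissociation
    constant.  Includes estimators for potentials of mean force from
    biased sampling (weighted histogram analysis of umbrella-sampling
    windows, replica exchange between windows, integration of adaptive
    biasing force gradient streams, window-overlap diagnostics, and a
    half-split uncertainty rule), single-trajectory MM-GBSA scoring
    (OBC generalized Born, Shrake-Rupley surface area, Coulomb and
    Lennard-Jones interaction terms) with a bound-time stopping metric,
    structure and trajectory geometry (superposition RMSD, interface
    residues, contact distances and occupancies, head-to-tail peptide
    cyclization), screening analytics for candidate peptide tables, and
    seeded synthetic-data generators that emulate all of these inputs
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
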