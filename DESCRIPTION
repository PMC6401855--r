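Package: brushscft
Title: Self-Consistent Field Theory for Ion Binding in Grafted ssDNA Brushes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: One-dimensional self-consistent field theory (SCFT) for short
    single-stranded DNA oligomers end-grafted to a planar surface in mixed
    NaCl/MgCl2 electrolyte. Chains of adenine and guanine monomers are sampled
    with a rotational isomeric state (RIS) model; protonation, Na+ binding and
    Mg2+ binding on each monomer are treated as local chemical equilibria
    coupled to a lateral packing (incompressibility) field and the Poisson
    equation for the electrostatic potential. The package computes polymer,
    ion and water volume-fraction profiles, local pH, per-chain bound-ion
    counts and brush heights across grafting densities and salt
    concentrations, and ships small-scale independent oracles (analytic mass
    action, brute-force free-energy extremization) for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
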