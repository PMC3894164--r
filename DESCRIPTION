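Package: gophos
Title: Coarse-Grained Go-Model Simulation of Receptor Tyrosine Kinase
    Multi-Site Autophosphorylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained (one-bead-per-residue) Go-type structural
    and energetic models of dimeric receptor tyrosine kinases, propagates them
    with implicit-solvent Brownian dynamics between membrane planes, and runs
    first-passage campaigns in which disordered C-terminal tails carrying
    multiple tyrosine phosphorylation sites (P-sites) search for the catalytic
    site of the activated kinase dimer.  Includes conformation-randomization
    ensembles, cis/trans binding-event tabulation and exact multinomial tests,
    charge-stripped and phosphorylation-mimicking protocol variants, relative
    phosphorylation-rate prediction from binding frequencies and peptide
    kinetics, and deterministic synthetic toy dimers for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
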