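Package: scratchCA
Title: Cellular Automaton Digital Twin of the In Vitro Wound-Healing Scratch Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic lattice (cellular automaton) model of the in vitro
    wound-healing ("scratch") assay. Cells on a square lattice migrate or
    proliferate into empty neighboring sites with probabilities set by the
    characteristic migration time Tm and doubling time Td, are contact-inhibited
    (quiescent) when fully surrounded, and are resupplied at the lateral
    reservoir boundaries to mimic an unbounded monolayer. The package tracks
    the cell-free area A(t)/A0, extracts wound-closure kinetics (closure rate
    alpha, half-closure and closure times, front velocity), performs Latin
    hypercube global sensitivity analysis with regression-coefficient ranking
    (ANOVA + Tukey), and fits the power-law scaling of the closure rate against
    the migration/proliferation time ratio Phi = Tm/Td, including the critical
    Phi below which proliferation is negligible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
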