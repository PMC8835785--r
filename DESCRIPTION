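Package: codonevol
Title: Simulating the Evolution of Genetic Code Structure under Competing Codon Reading Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evolutionary-algorithm simulator of genetic code emergence.
    Candidate coding systems are pairs of row-stochastic matrices: a 64 x 21
    codon-to-label assignment matrix and a 21 x 3 matrix of reading-system
    choice (wobble-like M1, first/second-position M2, any-position M3).
    Populations of such systems evolve under Dirichlet row mutation and
    tournament selection on a coding-strength fitness that rewards
    unambiguous, block-concentrated codes, converging to low-entropy codes
    whose codon block structure resembles the standard genetic code. Includes
    entropy and block-structure observables, a hard-coded standard genetic
    code reference spectrum, TSV/JSON serialization and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
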