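Package: qphi
Title: Mechanism Integrated Information for Quantum Logic Gates
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Computes the integrated information (phi) of mechanisms within
    small quantum systems evolving under unitary dynamics. Implements
    density-matrix cause and effect repertoires with causal
    marginalization, factorization over the entanglement structure of a
    state (Peres-Horodecki based separability analysis), the quantum
    intrinsic difference measure built on the quantum relative entropy,
    exhaustive minimum-information-partition search, and compositional
    unfolding of a system's cause-effect structure. Includes a classical
    reference engine for reversible logic gates against which the quantum
    analysis converges exactly for computational-basis inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
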