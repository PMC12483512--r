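Package: idrsearch
Title: Binding Affinity and Target-Search Kinetics of Transcription
    Factors with Intrinsically Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how an intrinsically disordered region (IDR)
    changes the DNA-binding affinity and the target-search time of a
    transcription factor.  The transcription factor is modelled as an ideal
    bead-spring chain carrying one DNA-binding-domain (DBD) site and several
    IDR binding sites; its DNA targets sit on a straight "antenna" segment.
    The package computes the equilibrium binding probability by exact
    enumeration of all multivalent binding configurations (with a Metropolis
    Monte Carlo cross-check), simulates the overdamped Langevin search of the
    chain for a central absorbing target inside a reflecting sphere, fits the
    semi-analytic two-term (3D capture + 1D sliding) search-time formula,
    optimises the antenna length, converts search times into biochemical
    on/off rates, and quantifies the "octopusing" one-dimensional walk from
    simulated trajectories.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
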