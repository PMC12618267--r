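Package: tfsearch
Title: Single-Molecule Analysis of Transcription-Factor Target Search on DNA and Nucleosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis tools for single-molecule studies of how a
    sequence-specific transcription factor finds its cognate motif by combined
    one-dimensional sliding and three-dimensional diffusion. Provides DNA and
    nucleosome template models with superhelical-location (SHL) coordinates and
    a solvent-accessibility rule; a continuous-time (Gillespie) simulator of
    binding, sliding and motif trapping rendered into multicolor smFRET
    intensity traces and confocal kymographs; hidden-Markov-model (Baum-Welch
    plus Viterbi) and relative-intensity binding-site assignment; dwell-time
    survival (1-CDF) exponential fitting, binding-frequency and equilibrium
    kinetics, event categorization and rebinding statistics; kymograph
    single-particle tracking with MSD-based diffusion-coefficient estimation and
    mobility classification; and closed-form facilitated-diffusion calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    methods,
    Rcpp,
    Biostrings,
    minpack.lm,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
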