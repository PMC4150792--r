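Package: rhoterm
Title: Kinetics and Sequence Analysis of Rho-Dependent Transcription
    Termination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying Rho-dependent transcription termination in
    bacteria. Implements a continuous-time Markov chain model of Rho
    recruitment (reversible rut-site binding, open-to-closed hexamer
    isomerization accelerated by NusG, ATP-driven translocation and
    dislodging of the elongation complex) with analytic and stochastic
    solvers for RNA-release and ATP-hydrolysis kinetics; empirical
    exponential-rise and sigmoid fitting of release time courses with
    information-criterion model selection and tangent-intercept lag
    estimation; rut-site scanning of untranslated regions by C/G
    composition and a self-contained folding-energy dynamic program;
    terminator-strength metrics based on the distance between the rut site
    and the termination zone, with inversion to a commitment time; fold
    change thresholding, overlay classification and 2^-ddCt quantification
    for expression tables; and seeded synthetic-data generators that
    emulate each of the above inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deSolve,
    graphics,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
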