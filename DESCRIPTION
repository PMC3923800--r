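Package: ReactionSpectra
Title: Identification of Co-Occurring Chemical Reaction Types from 1H NMR
    Difference Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encodes chemical reactions and simulated two-reaction mixtures as
    binned 1H NMR difference spectra ("reaction spectra"): stick spectra of
    reactants and products are fuzzified with triangular functions, binned over
    0-12 ppm in 0.1 ppm intervals, and subtracted.  Provides exhaustive
    enumeration of cross-type reaction mixtures with yield, molar-ratio and
    normalization perturbations, and three classifiers for assigning the pair
    of reaction types present in a mixture: toroidal Kohonen self-organizing
    maps with majority-vote ensembles, counter-propagation neural networks
    with a two-types-above-threshold decision rule, and random forests with
    vote-fraction probabilities and reliability filtering.  A synthetic
    reaction generator emulating six photocycloaddition families supports
    end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    randomForest,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
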