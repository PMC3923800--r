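#' @import methods
NULL

#' Stick spectrum of a single compound
#'
#' A `ShiftList` holds a predicted or measured 1H NMR stick spectrum as
#' parallel vectors of chemical shifts (ppm) and integration weights
#' (number of protons giving rise to each signal).  It may be empty.
#'
#' @slot shift numeric, chemical shifts in ppm.
#' @slot protons numeric, positive proton counts (integration weights).
#' @exportClass ShiftList
setClass("ShiftList",
    slots = c(shift = "numeric", protons = "numeric"),
    prototype = prototype(shift = numeric(0), protons = numeric(0)))

setValidity("ShiftList", function(object) {
    if (length(object@shift) != length(object@protons))
        return("shift and protons must have equal length")
    if (length(object@shift) && any(!is.finite(object@shift)))
        return("all shifts must be finite")
    if (length(object@protons) &&
        (any(!is.finite(object@protons)) || any(object@protons <= 0)))
        return("all proton counts must be finite and > 0")
    TRUE
})

#' Fuzzified spectrum: a sum of triangular peaks
#'
#' Each stick peak becomes an isoceles triangle centred at its shift with a
#' given half width; the triangle's integral equals the peak's proton count
#' (so the apex height is `area / halfWidth`).
#'
#' @slot center numeric, triangle centres in ppm.
#' @slot halfWidth numeric, half widths in ppm (support is
#'   `center +/- halfWidth`).
#' @slot area numeric, integral of each triangle in proton units.
#' @exportClass FuzzySpectrum
setClass("FuzzySpectrum",
    slots = c(center = "numeric", halfWidth = "numeric", area = "numeric"))

setValidity("FuzzySpectrum", function(object) {
    n <- length(object@center)
    if (length(object@halfWidth) != n || length(object@area) != n)
        return("center, halfWidth and area must have equal length")
    if (n && any(object@halfWidth <= 0))
        return("halfWidth must be > 0")
    TRUE
})

#' Binned spectrum over a fixed ppm grid
#'
#' A vector of per-bin integrals over half-open intervals
#' `[lo + (k-1) * binWidth, lo + k * binWidth)`.  Values may be negative for
#' difference spectra.  The default grid (0-12 ppm, 0.1 ppm bins) has 120
#' variables.  `clipped` records fuzzified mass falling outside `[lo, hi]`
#' that was dropped during binning.
#'
#' @slot values numeric vector of bin integrals.
#' @slot lo,hi numeric, grid limits in ppm.
#' @slot binWidth numeric, bin width in ppm.
#' @slot clipped numeric, total mass outside the grid.
#' @exportClass BinnedSpectrum
setClass("BinnedSpectrum",
    slots = c(values = "numeric", lo = "numeric", hi = "numeric",
              binWidth = "numeric", clipped = "numeric"),
    prototype = prototype(clipped = 0))

setValidity("BinnedSpectrum", function(object) {
    n <- round((object@hi - object@lo) / object@binWidth)
    if (object@hi <= object@lo) return("hi must exceed lo")
    if (abs(n * object@binWidth - (object@hi - object@lo)) > 1e-8)
        return("(hi - lo) must be an integral number of bin widths")
    if (length(object@values) != n)
        return(sprintf("values has length %d, grid implies %d",
                       length(object@values), n))
    TRUE
})

#' A single reaction: reactant spectra, product spectrum and a type label
#'
#' @slot id character identifier.
#' @slot rtype character, the reaction-type label.
#' @slot reactants list of [ShiftList-class] (at least one).
#' @slot product [ShiftList-class]; must contain at least one peak.
#' @exportClass ReactionRecord
setClass("ReactionRecord",
    slots = c(id = "character", rtype = "character",
              reactants = "list", product = "ShiftList"))

setValidity("ReactionRecord", function(object) {
    if (length(object@id) != 1L || length(object@rtype) != 1L)
        return("id and rtype must be single strings")
    if (!length(object@reactants))
        return("at least one reactant spectrum is required")
    if (!all(vapply(object@reactants, is, logical(1), "ShiftList")))
        return("reactants must be a list of ShiftList objects")
    if (!length(object@product@shift))
        return("product spectrum must contain at least one peak")
    TRUE
})

#' A set of reactions with a fixed type registry
#'
#' The ordered `typeLevels` registry determines mixture-class labels, so its
#' order is part of the data model.
#'
#' @slot reactions list of [ReactionRecord-class].
#' @slot typeLevels character, the ordered reaction-type registry.
#' @exportClass ReactionSet
setClass("ReactionSet",
    slots = c(reactions = "list", typeLevels = "character"))

setValidity("ReactionSet", function(object) {
    if (!all(vapply(object@reactions, is, logical(1), "ReactionRecord")))
        return("reactions must be a list of ReactionRecord objects")
    types <- vapply(object@reactions, slot, character(1), "rtype")
    if (length(types) && !all(types %in% object@typeLevels))
        return("every reaction type must appear in typeLevels")
    ids <- vapply(object@reactions, slot, character(1), "id")
    if (anyDuplicated(ids)) return("reaction ids must be unique")
    TRUE
})

#' A set of simulated two-reaction mixtures
#'
#' Holds the mixture manifest (constituent reaction ids, mixture class and
#' the perturbation parameters ratio / norm / yields), the descriptor matrix
#' (one binned difference spectrum per mixture) and the per-reaction
#' descriptor matrix the mixtures were combined from, so perturbed variants
#' can be regenerated without re-binning.
#'
#' @slot manifest data.frame with columns id, rxnA, rxnB, typeA, typeB,
#'   mclass, ratio, norm, yieldA, yieldB.
#' @slot descriptors numeric matrix, one row per mixture.
#' @slot rxnDescriptors numeric matrix, one row per reaction (rownames are
#'   reaction ids), at full conversion.
#' @slot typeLevels character, ordered reaction-type registry.
#' @slot binning list with elements lo, hi, binWidth.
#' @exportClass MixtureSet
setClass("MixtureSet",
    slots = c(manifest = "data.frame", descriptors = "matrix",
              rxnDescriptors = "matrix", typeLevels = "character",
              binning = "list"))

setValidity("MixtureSet", function(object) {
    need <- c("id", "rxnA", "rxnB", "typeA", "typeB", "mclass",
              "ratio", "norm", "yieldA", "yieldB")
    if (!all(need %in% names(object@manifest)))
        return(paste("manifest must contain columns:",
                     paste(need, collapse = ", ")))
    if (nrow(object@manifest) != nrow(object@descriptors))
        return("manifest and descriptor matrix disagree in size")
    if (!all(object@manifest$rxnA %in% rownames(object@rxnDescriptors)) ||
        !all(object@manifest$rxnB %in% rownames(object@rxnDescriptors)))
        return("manifest reaction ids missing from rxnDescriptors")
    TRUE
})

#' Trained toroidal self-organizing map
#'
#' @slot weights numeric matrix (`rows * cols`) x p; neuron index is
#'   row-major, i.e. neuron (r, c) is row `(r - 1) * cols + c`.
#' @slot rows,cols integer grid dimensions.
#' @slot config list of training settings (epochs, lr0, span0, seed).
#' @slot classLevels character, class registry used at labeling time.
#' @slot labelMap data.frame (neuron, row, col, status, label, effective);
#'   empty until [labelNeurons()] is called.
#' @slot classCounts numeric matrix of per-neuron training-class counts.
#' @exportClass SOMModel
setClass("SOMModel",
    slots = c(weights = "matrix", rows = "integer", cols = "integer",
              config = "list", classLevels = "character",
              labelMap = "data.frame", classCounts = "matrix"),
    prototype = prototype(labelMap = data.frame(),
                          classCounts = matrix(numeric(0), 0, 0)))

setValidity("SOMModel", function(object) {
    if (nrow(object@weights) != object@rows * object@cols)
        return("weights must have rows * cols rows")
    if (any(!is.finite(object@weights)))
        return("all weights must be finite")
    if (object@rows < 2L || object@cols < 2L)
        return("grid must be at least 2 x 2")
    TRUE
})

#' Trained counter-propagation network
#'
#' A [SOMModel-class] input layer plus an output layer storing, for each
#' neuron, a vector of one value per reaction type.
#'
#' @slot outputWeights numeric matrix (`rows * cols`) x nTypes.
#' @slot typeLevels character, ordered reaction-type registry (length = the
#'   output dimension).
#' @exportClass CPNNModel
setClass("CPNNModel", contains = "SOMModel",
    slots = c(outputWeights = "matrix", typeLevels = "character"))

setValidity("CPNNModel", function(object) {
    if (nrow(object@outputWeights) != object@rows * object@cols)
        return("outputWeights must have rows * cols rows")
    if (ncol(object@outputWeights) != length(object@typeLevels))
        return("output dimension must equal the number of reaction types")
    if (any(!is.finite(object@outputWeights)))
        return("all output weights must be finite")
    TRUE
})

#' Random-forest mixture classifier
#'
#' Wraps a fitted `randomForest` ensemble together with the class registry
#' and the out-of-bag accuracy computed from the OOB vote matrix with
#' deterministic (class-order) tie-breaking.
#'
#' @slot fit the underlying `randomForest` object.
#' @slot classLevels character, mixture-class registry.
#' @slot config list (nTrees, mtry, seed).
#' @slot oobAccuracy numeric, OOB percent correct.
#' @exportClass MixtureRF
setClass("MixtureRF",
    slots = c(fit = "ANY", classLevels = "character", config = "list",
              oobAccuracy = "numeric"))
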