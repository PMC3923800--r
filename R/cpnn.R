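#' Binary target vector for a mixture class
#'
#' Encodes a two-reaction mixture class as a vector with one component per
#' reaction type: the two components corresponding to the types present in
#' the mixture are 1, the others 0.
#'
#' @param mclass mixture-class label (A-O for six types).
#' @param typeLevels ordered reaction-type registry.
#' @return Numeric 0/1 vector of length `length(typeLevels)` summing to 2.
#' @examples
#' encodeTarget("A", paste0("t", 1:6))  # 1 1 0 0 0 0
#' @export
encodeTarget <- function(mclass, typeLevels) {
    out <- numeric(length(typeLevels))
    out[match(classTypes(mclass, typeLevels), typeLevels)] <- 1
    out
}

#' Train a counter-propagation network
#'
#' The input layer is a toroidal Kohonen map trained exactly as in
#' [trainSOM()]; winners are determined from the input layer alone.  At
#' every update the output weights of the winner's neighbourhood also move
#' toward the object's binary type-target vector with the same learning
#' factor (semi-supervised learning).  Output weights initialize to the
#' uninformative midpoint 0.5 and, with binary targets, remain in [0, 1]
#' because every update is a convex combination.
#'
#' @inheritParams trainSOM
#' @param mclasses character vector of mixture-class labels, one per row
#'   of `x`.
#' @param typeLevels ordered reaction-type registry (determines the output
#'   dimension).
#' @return A [CPNNModel-class].
#' @export
trainCPNN <- function(x, mclasses, typeLevels, rows = 49, cols = 49,
                      epochs = 75, lr0 = 0.1, span0 = NULL, seed = NULL) {
    x <- as.matrix(x)
    stopifnot(rows >= 2, cols >= 2, epochs >= 1,
              length(mclasses) == nrow(x))
    .assertScalarNumber(lr0, "lr0", lower = 0, upper = 1)
    if (is.null(span0)) span0 <- floor(min(rows, cols) / 2)
    mclasses <- as.character(mclasses)
    uc <- unique(mclasses)
    enc <- t(vapply(uc, encodeTarget, numeric(length(typeLevels)),
                    typeLevels = typeLevels))
    targets <- enc[match(mclasses, uc), , drop = FALSE]
    fit <- .withSeed(seed, .somFit(x, rows, cols, epochs, lr0, span0,
                                   targets = targets))
    new("CPNNModel", weights = fit$weights, rows = as.integer(rows),
        cols = as.integer(cols),
        config = list(epochs = epochs, lr0 = lr0, span0 = span0, seed = seed),
        outputWeights = fit$output, typeLevels = typeLevels)
}

#' Raw CPNN output for new objects
#'
#' For each input the winner is found in the input layer and the winner's
#' output weights (one value per reaction type) are returned as the
#' prediction.
#'
#' @param model a [CPNNModel-class].
#' @param x numeric vector or matrix of inputs.
#' @return Numeric matrix (objects x types) of output values.
#' @export
cpnnPredict <- function(model, x) {
    stopifnot(is(model, "CPNNModel"))
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    out <- model@outputWeights[findWinner(model@weights, x), , drop = FALSE]
    colnames(out) <- model@typeLevels
    rownames(out) <- rownames(x)
    out
}

#' Two-types-above-threshold mixture decision
#'
#' A mixture class is predicted only if exactly two of the output values
#' are strictly higher than the threshold (the class combining those two
#' reaction types); otherwise the mixture is undecided (NA).  Values equal
#' to the threshold do not count as above it.  Raising the threshold never
#' converts an undecided output into a decided one when two or fewer values
#' are above it, and may only remove decisions.
#'
#' @param output numeric vector of one value per reaction type.
#' @param threshold decision threshold (default 0.5).
#' @param typeLevels ordered reaction-type registry.
#' @return Mixture-class label, or NA if undecided.
#' @examples
#' decideMixture(c(0.9, 0.8, 0.1, 0, 0.2, 0), 0.5, paste0("t", 1:6))  # "A"
#' @export
decideMixture <- function(output, threshold = 0.5, typeLevels) {
    stopifnot(length(output) == length(typeLevels))
    hi <- which(output > threshold)
    if (length(hi) != 2L) return(NA_character_)
    mixtureClass(typeLevels[hi[1]], typeLevels[hi[2]], typeLevels)
}

#' Classify objects with a CPNN
#'
#' Applies [decideMixture()] to the raw output of every object.
#'
#' @inheritParams cpnnPredict
#' @param threshold decision threshold (default 0.5).
#' @return Character vector of mixture classes (NA = undecided).
#' @export
cpnnClassify <- function(model, x, threshold = 0.5) {
    out <- cpnnPredict(model, x)
    apply(out, 1, decideMixture, threshold = threshold,
          typeLevels = model@typeLevels)
}

#' Train an ensemble of independent CPNNs
#'
#' @inheritParams trainCPNN
#' @param nModels ensemble size (typically 5 or 10).
#' @return List of [CPNNModel-class] objects; combine their predictions
#'   with [ensembleClassify()].
#' @export
cpnnEnsemble <- function(x, mclasses, typeLevels, nModels = 5, rows = 49,
                         cols = 49, epochs = 75, lr0 = 0.1, span0 = NULL,
                         seed = NULL) {
    seeds <- .subSeeds(seed, nModels)
    lapply(seq_len(nModels), function(k)
        trainCPNN(x, mclasses, typeLevels, rows, cols, epochs, lr0, span0,
                  seed = seeds[k]))
}
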