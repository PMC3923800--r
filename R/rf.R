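#' Train a random forest of mixture classifiers
#'
#' Grows an ensemble of unpruned classification trees on bootstrap samples,
#' testing a random subset of variables at each split, to classify mixture
#' descriptors into the 15 mixture classes.  Delegates tree growing to the
#' \pkg{randomForest} package; out-of-bag (OOB) accuracy and all
#' predictions are computed in this package from the vote matrices with a
#' deterministic class-order tie-break.
#'
#' @param x numeric descriptor matrix (mixtures x variables).
#' @param classes character vector of mixture-class labels.
#' @param nTrees number of trees (default 1000).
#' @param mtry variables tested per split (default `floor(sqrt(p))`).
#' @param classLevels optional ordered class registry.
#' @param seed integer seed (NULL: current RNG stream).
#' @return A [MixtureRF-class].
#' @export
trainRF <- function(x, classes, nTrees = 1000, mtry = NULL,
                    classLevels = NULL, seed = NULL) {
    x <- as.matrix(x)
    stopifnot(nrow(x) == length(classes), nTrees >= 1)
    if (is.null(classLevels)) classLevels <- sort(unique(as.character(classes)))
    if (length(classLevels) < 2L)
        stop("at least two distinct classes are required")
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
    y <- factor(as.character(classes), levels = classLevels)
    fit <- .withSeed(seed, randomForest::randomForest(
        x = x, y = y, ntree = nTrees, mtry = mtry))
    oobPred <- .voteDecision(fit$votes, classLevels)
    new("MixtureRF", fit = fit, classLevels = classLevels,
        config = list(nTrees = nTrees, mtry = mtry, seed = seed),
        oobAccuracy = 100 * mean(oobPred$class == as.character(y)))
}

# winning class and vote fraction from a (normalized) vote matrix;
# ties broken by class-registry order and flagged
.voteDecision <- function(votes, classLevels) {
    votes <- votes[, classLevels, drop = FALSE]
    top <- max.col(votes, ties.method = "first")
    prob <- votes[cbind(seq_len(nrow(votes)), top)]
    tie <- rowSums(votes == prob) > 1L
    list(class = classLevels[top], probability = as.numeric(prob), tie = tie)
}

setMethod("show", "MixtureRF", function(object) {
    cat(sprintf("MixtureRF: %d trees, mtry %d, %d class(es)\n",
                object@config$nTrees, object@config$mtry,
                length(object@classLevels)))
    cat(sprintf("  OOB accuracy: %.1f%%\n", object@oobAccuracy))
})

#' Out-of-bag accuracy of a trained forest
#'
#' @param model a [MixtureRF-class].
#' @return Percent of training objects correctly classified by the trees
#'   that did not sample them.
#' @export
oobAccuracy <- function(model) {
    stopifnot(is(model, "MixtureRF"))
    model@oobAccuracy
}

#' Predict mixture classes with vote-fraction probabilities
#'
#' For each object the majority-vote class and the fraction of trees voting
#' for it (the prediction's probability, used as a reliability measure).
#' Exact vote ties are broken by class-registry order and flagged.
#'
#' @param model a [MixtureRF-class].
#' @param x numeric descriptor matrix.
#' @return data.frame with columns id, predicted, probability, tie.
#' @export
rfPredict <- function(model, x) {
    stopifnot(is(model, "MixtureRF"))
    x <- as.matrix(x)
    if (ncol(x) != length(model@fit$forest$xlevels))
        stop("input dimension does not match the trained forest")
    votes <- stats::predict(model@fit, x, type = "vote", norm.votes = TRUE)
    dec <- .voteDecision(votes, model@classLevels)
    data.frame(id = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
               predicted = dec$class, probability = dec$probability,
               tie = dec$tie, stringsAsFactors = FALSE, row.names = NULL)
}

#' y-randomization validation
#'
#' Retrains the forest `nRepeats` times on label-scrambled training data
#' (the descriptor matrix untouched) and evaluates each scrambled model on
#' the untouched test set.  Genuine structure in the original model implies
#' scrambled accuracies near the no-information rate.
#'
#' @param x,classes training descriptors and labels.
#' @param xTest,classesTest test descriptors and labels.
#' @param nRepeats number of scrambles (default 5).
#' @param nTrees,mtry forest settings (see [trainRF()]).
#' @param seed integer seed (NULL: current RNG stream).
#' @param permutations optional list of explicit permutations of
#'   `seq_along(classes)` overriding the random scrambles (e.g. the
#'   identity permutation reproduces the unscrambled accuracy).
#' @return Numeric vector of test accuracies (percent), one per repeat.
#' @export
yRandomize <- function(x, classes, xTest, classesTest, nRepeats = 5,
                       nTrees = 1000, mtry = NULL, seed = NULL,
                       permutations = NULL) {
    stopifnot(nRepeats >= 1)
    classLevels <- sort(unique(as.character(classes)))
    seeds <- .subSeeds(seed, 2L * nRepeats)
    if (is.null(permutations))
        permutations <- lapply(seq_len(nRepeats), function(k)
            .withSeed(seeds[k], sample.int(length(classes))))
    vapply(seq_along(permutations), function(k) {
        m <- trainRF(x, classes[permutations[[k]]], nTrees = nTrees,
                     mtry = mtry, classLevels = classLevels,
                     seed = seeds[nRepeats + k])
        pred <- rfPredict(m, xTest)
        100 * mean(pred$predicted == as.character(classesTest))
    }, numeric(1))
}

#' Reliability table: accuracy stratified by prediction probability
#'
#' For each class and probability threshold, the number of objects
#' predicted to belong to that class with probability at or above the
#' threshold, and the percentage of true positives among them; plus a Total
#' row.  Threshold 0 reproduces the unfiltered counts.
#'
#' @param predictions data.frame from [rfPredict()] (columns predicted,
#'   probability).
#' @param truths character vector of true classes, aligned with
#'   `predictions`.
#' @param thresholds numeric vector of probability cut-offs
#'   (default `c(0, 0.5, 0.6, 0.8)`).
#' @param classLevels optional ordered class registry.
#' @return data.frame with columns class, threshold, nPredicted, nCorrect,
#'   pctCorrect.
#' @export
reliabilityTable <- function(predictions, truths,
                             thresholds = c(0, 0.5, 0.6, 0.8),
                             classLevels = NULL) {
    stopifnot(nrow(predictions) == length(truths))
    if (is.null(classLevels))
        classLevels <- sort(unique(c(predictions$predicted,
                                     as.character(truths))))
    rows <- list()
    for (th in thresholds) {
        keep <- predictions$probability >= th
        for (cl in c(classLevels, "Total")) {
            sel <- keep & (if (cl == "Total") TRUE
                           else predictions$predicted == cl)
            n <- sum(sel)
            ok <- sum(sel & predictions$predicted == as.character(truths))
            rows[[length(rows) + 1L]] <- data.frame(
                class = cl, threshold = th, nPredicted = n, nCorrect = ok,
                pctCorrect = if (n) 100 * ok / n else NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
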