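#' Classification accuracy with an undecided policy
#'
#' @param predictions character vector of predicted classes; NA marks
#'   undecided objects.
#' @param truths character vector of true classes, same length.
#' @param undecided `"as_error"` counts undecided objects as wrong
#'   (correct / total); `"exclude"` restricts to assigned objects
#'   (correct / assigned).
#' @return Percent correct.
#' @export
mixtureAccuracy <- function(predictions, truths,
                            undecided = c("as_error", "exclude")) {
    undecided <- match.arg(undecided)
    if (!length(predictions)) stop("empty prediction vector")
    stopifnot(length(predictions) == length(truths))
    correct <- !is.na(predictions) & predictions == as.character(truths)
    if (undecided == "as_error") return(100 * mean(correct))
    assigned <- !is.na(predictions)
    if (!any(assigned))
        stop("all predictions are undecided; accuracy over assigned objects is undefined")
    100 * sum(correct) / sum(assigned)
}

#' Confusion matrix with per-class recall
#'
#' Rows are true classes, columns predicted classes; the last column gives
#' the per-class recall in percent.  Undecided predictions (NA) occupy an
#' explicit `undecided` column when `includeUndecided = TRUE` (they always
#' count against recall), or are dropped from the counts otherwise.
#'
#' @param predictions character vector of predicted classes (NA =
#'   undecided).
#' @param truths character vector of true classes.
#' @param classLevels ordered class registry (default: sorted union).
#' @param includeUndecided add an `undecided` column (default TRUE).
#' @return Numeric matrix of counts with a `pctCorrect` column.
#' @export
confusionMixtures <- function(predictions, truths, classLevels = NULL,
                              includeUndecided = TRUE) {
    stopifnot(length(predictions) == length(truths))
    if (is.null(classLevels))
        classLevels <- sort(unique(c(as.character(truths),
                                     predictions[!is.na(predictions)])))
    tr <- factor(as.character(truths), levels = classLevels)
    pr <- factor(predictions, levels = classLevels)
    m <- unclass(table(tr, pr))
    if (includeUndecided)
        m <- cbind(m, undecided = as.vector(table(tr[is.na(pr)])))
    total <- as.vector(table(tr))
    recall <- ifelse(total > 0,
                     100 * m[cbind(seq_along(classLevels),
                                   seq_along(classLevels))] / total,
                     NA_real_)
    cbind(m, pctCorrect = recall)
}

#' Robustness battery for a trained mixture classifier
#'
#' Re-predicts a base test set under simulated experimental imperfections,
#' with the model left untouched: (i) partial conversion -- both reactions
#' at each given yield; (ii) unequal molar ratios -- each RATIO value at
#' NORM = 1; (iii) the same RATIO values with the integration
#' normalization NORM drawn uniformly from `normRange`.
#'
#' @param model a [MixtureRF-class].
#' @param ms the base test [MixtureSet-class] (unperturbed).
#' @param yields numeric vector of conversion yields (default
#'   `c(0.7, 0.8, 0.9, 1)`).
#' @param ratios numeric vector of RATIO values (default `c(1, 2, 5)`).
#' @param normRange length-2 range for random NORM (default `c(0.2, 1)`);
#'   NULL skips the random-NORM arm.
#' @param seed integer seed for the NORM draws.
#' @return data.frame with columns experiment, parameter, n, accuracy.
#' @export
runBattery <- function(model, ms, yields = c(0.7, 0.8, 0.9, 1),
                       ratios = c(1, 2, 5), normRange = c(0.2, 1),
                       seed = NULL) {
    stopifnot(is(model, "MixtureRF"), is(ms, "MixtureSet"))
    truths <- mixtureClasses(ms)
    seeds <- .subSeeds(seed, length(ratios))
    acc <- function(X, tr) {
        pred <- rfPredict(model, X)
        100 * mean(pred$predicted == tr)
    }
    rows <- list()
    addRow <- function(experiment, parameter, n, accuracy)
        rows[[length(rows) + 1L]] <<- data.frame(
            experiment = experiment, parameter = parameter, n = n,
            accuracy = accuracy, stringsAsFactors = FALSE)
    for (y in yields)  # yield scales the difference spectrum linearly
        addRow("yield", y, length(ms), acc(y * descriptors(ms), truths))
    for (r in ratios) {
        pm <- perturbMixtures(ms, ratios = r)
        addRow("ratio", r, length(pm), acc(descriptors(pm),
                                           mixtureClasses(pm)))
    }
    if (!is.null(normRange)) {
        for (k in seq_along(ratios)) {
            pm <- perturbMixtures(ms, ratios = ratios[k],
                                  normRange = normRange, seed = seeds[k])
            addRow("ratio.randomNorm", ratios[k], length(pm),
                   acc(descriptors(pm), mixtureClasses(pm)))
        }
    }
    do.call(rbind, rows)
}
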