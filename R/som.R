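#' @useDynLib ReactionSpectra, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Toroidal Chebyshev distance between grid positions
#'
#' On a torus every neuron has 8 immediate neighbours, so the topological
#' metric is the Chebyshev distance with per-axis wraparound:
#' `max(min(|dr|, rows - |dr|), min(|dc|, cols - |dc|))`.
#'
#' @param p1,p2 integer coordinates `c(row, col)`, 1-based.
#' @param rows,cols grid dimensions.
#' @return Integer distance.
#' @examples
#' toroidalDistance(c(1, 1), c(49, 49), 49, 49)  # 1: corners wrap
#' @export
toroidalDistance <- function(p1, p2, rows, cols) {
    p1 <- as.integer(p1); p2 <- as.integer(p2)
    if (any(c(p1, p2) < 1L) || p1[1] > rows || p2[1] > rows ||
        p1[2] > cols || p2[2] > cols)
        stop("coordinates must lie inside the grid")
    rows <- as.integer(rows); cols <- as.integer(cols)
    dr <- abs(p1[1] - p2[1]); dc <- abs(p1[2] - p2[2])
    max(min(dr, rows - dr), min(dc, cols - dc))
}

# 1-based row-major neuron index <-> (row, col)
.neuronCoords <- function(idx, cols) {
    cbind(row = (idx - 1L) %/% cols + 1L, col = (idx - 1L) %% cols + 1L)
}

#' Best-matching unit(s) for input vectors
#'
#' Returns, for each row of `x`, the 1-based row-major index of the neuron
#' with minimum Euclidean distance to it; exact ties go to the smallest
#' index.
#'
#' @param weights a weight matrix (neurons x variables) or a
#'   [SOMModel-class].
#' @param x numeric vector or matrix of inputs.
#' @return Integer vector of neuron indices.
#' @export
findWinner <- function(weights, x) {
    if (is(weights, "SOMModel")) weights <- weights@weights
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != ncol(weights))
        stop("input dimension does not match the weights")
    # squared distances via ||w||^2 - 2 w.x (+ ||x||^2, constant per input)
    d2 <- rowSums(weights^2) - 2 * tcrossprod(weights, x)
    max.col(-t(d2), ties.method = "first")
}

#' Train a toroidal Kohonen self-organizing map
#'
#' Competitive learning on a `rows x cols` toroidal grid.  Weights are
#' initialized componentwise from Normal(mean_j, sd_j) of each input
#' variable.  For epoch t of T the learning rate is `lr0 * (1 - t/T)` and
#' the neighbourhood span `round(span0 * (1 - t/T))`; every neuron at
#' toroidal Chebyshev distance d <= span of the winner is moved toward the
#' input with the triangular factor `lr * (1 - d / (span + 1))` (the
#' farthest included neuron still updates).  Sample order is reshuffled
#' every epoch.  Training is bitwise deterministic under a fixed seed.
#'
#' @param x numeric matrix of inputs (objects x variables).
#' @param rows,cols grid dimensions (default 49 x 49).
#' @param epochs training cycles (default 75, the midpoint of the usual
#'   50-100 range).
#' @param lr0 initial learning rate in (0, 1] (default 0.1).
#' @param span0 initial neighbourhood span; default half the smaller grid
#'   dimension.
#' @param seed integer seed (NULL: current RNG stream).
#' @return An unlabeled [SOMModel-class].
#' @export
trainSOM <- function(x, rows = 49, cols = 49, epochs = 75, lr0 = 0.1,
                     span0 = NULL, seed = NULL) {
    x <- as.matrix(x)
    stopifnot(rows >= 2, cols >= 2, epochs >= 1)
    .assertScalarNumber(lr0, "lr0", lower = 0, upper = 1)
    if (is.null(span0)) span0 <- floor(min(rows, cols) / 2)
    if (nrow(x) < 2 * rows * cols)
        warning(sprintf("only %d objects for %d neurons; at least two objects per neuron are recommended",
                        nrow(x), rows * cols))
    fit <- .withSeed(seed, .somFit(x, rows, cols, epochs, lr0, span0))
    new("SOMModel", weights = fit$weights, rows = as.integer(rows),
        cols = as.integer(cols),
        config = list(epochs = epochs, lr0 = lr0, span0 = span0, seed = seed))
}

# shared RNG-consuming core of trainSOM / trainCPNN: init + shuffles + C
# loop; the C kernel works on variable-major (transposed) matrices so each
# neuron's weight vector is contiguous
.somFit <- function(x, rows, cols, epochs, lr0, span0, targets = NULL) {
    p <- ncol(x); n <- nrow(x); nNeurons <- rows * cols
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[!is.finite(sdv)] <- 0
    W0 <- matrix(stats::rnorm(nNeurons * p, mean = rep(mu, each = nNeurons),
                              sd = rep(sdv, each = nNeurons)), nNeurons, p)
    orders <- matrix(0L, epochs, n)
    for (t in seq_len(epochs)) orders[t, ] <- sample.int(n) - 1L
    out0 <- if (is.null(targets)) NULL else
        t(matrix(0.5, nNeurons, ncol(targets)))
    fit <- .som_train_cpp(t(W0), t(x), orders, as.integer(rows),
                          as.integer(cols), lr0, as.integer(span0),
                          if (is.null(targets)) NULL else t(targets), out0)
    list(weights = t(fit$weightsT),
         output = if (is.null(targets)) NULL else t(fit$outputT))
}

setMethod("show", "SOMModel", function(object) {
    cat(sprintf("%s: %d x %d toroidal grid, %d input variable(s)\n",
                class(object), object@rows, object@cols,
                ncol(object@weights)))
    cat(sprintf("  epochs %s, lr0 %s, span0 %s\n",
                format(object@config$epochs), format(object@config$lr0),
                format(object@config$span0)))
    if (nrow(object@labelMap)) {
        tab <- table(object@labelMap$status)
        cat(sprintf("  labeled neurons: %d class, %d conflict, %d empty\n",
                    sum(object@labelMap$status == "label"),
                    sum(object@labelMap$status == "conflict"),
                    sum(object@labelMap$status == "empty")))
    } else cat("  (not yet labeled)\n")
})

#' Label the neurons of a trained map
#'
#' Maps the training objects onto the grid and assigns each neuron a
#' status: `empty` (no objects), `label` (all objects one class) or
#' `conflict` (several classes).  Conflict neurons retain their plurality
#' class internally (NA on an exact tie) so they can still classify;
#' empty neurons receive as fallback the label of the nearest neuron (by
#' toroidal distance, ties to the smallest row-major index) that has a
#' defined label.
#'
#' @param model a trained [SOMModel-class].
#' @param x training descriptor matrix.
#' @param classes character vector of training class labels.
#' @param classLevels optional ordered class registry (default: sorted
#'   unique classes).
#' @return The model with `labelMap`, `classCounts` and `classLevels`
#'   filled in.
#' @export
labelNeurons <- function(model, x, classes, classLevels = NULL) {
    stopifnot(is(model, "SOMModel"))
    x <- as.matrix(x)
    if (is.null(classLevels)) classLevels <- sort(unique(as.character(classes)))
    cls <- factor(as.character(classes), levels = classLevels)
    if (anyNA(cls)) stop("all classes must appear in classLevels")
    nNeurons <- model@rows * model@cols
    win <- findWinner(model@weights, x)
    counts <- unclass(table(factor(win, levels = seq_len(nNeurons)), cls))
    nz <- rowSums(counts > 0)
    status <- ifelse(nz == 0L, "empty", ifelse(nz == 1L, "label", "conflict"))
    label <- rep(NA_character_, nNeurons)
    hit <- nz > 0L
    sub <- counts[hit, , drop = FALSE]
    top <- max.col(sub, ties.method = "first")
    maxv <- sub[cbind(seq_len(nrow(sub)), top)]
    uniqueTop <- rowSums(sub == matrix(maxv, nrow(sub), ncol(sub))) == 1L
    label[hit] <- ifelse(uniqueTop, classLevels[top], NA_character_)
    effective <- label
    defined <- which(!is.na(label))
    if (!length(defined))
        warning("no neuron received a defined label")
    emptyIdx <- which(status == "empty")
    if (length(emptyIdx) && length(defined)) {
        co <- .neuronCoords(seq_len(nNeurons), model@cols)
        for (e in emptyIdx) {
            dr <- abs(co[defined, "row"] - co[e, "row"])
            dc <- abs(co[defined, "col"] - co[e, "col"])
            d <- pmax(pmin(dr, model@rows - dr), pmin(dc, model@cols - dc))
            effective[e] <- label[defined[which.min(d)]]  # first min: smallest index
        }
    }
    co <- .neuronCoords(seq_len(nNeurons), model@cols)
    model@labelMap <- data.frame(neuron = seq_len(nNeurons),
                                 row = co[, "row"], col = co[, "col"],
                                 status = status, label = label,
                                 effective = effective,
                                 stringsAsFactors = FALSE)
    model@classCounts <- counts
    model@classLevels <- classLevels
    model
}

#' Classify new objects with a labeled map
#'
#' Each object is assigned the label of its best-matching unit: a
#' single-class neuron gives its class, a conflict neuron its plurality
#' class (NA, i.e. undecided, on an exact tie), and an empty neuron falls
#' back to the nearest neuron with a defined label.
#'
#' @param model a labeled [SOMModel-class] (see [labelNeurons()]).
#' @param x numeric vector or matrix of inputs.
#' @return Character vector of class labels; NA marks undecided objects.
#' @export
somClassify <- function(model, x) {
    stopifnot(is(model, "SOMModel"))
    if (!nrow(model@labelMap))
        stop("model has not been labeled; call labelNeurons() first")
    if (all(is.na(model@labelMap$effective)))
        stop("model has no labeled neurons")
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    model@labelMap$effective[findWinner(model@weights, x)]
}

#' Majority vote over classifier outputs
#'
#' Plurality class over the member votes of an ensemble; undecided (NA)
#' votes are excluded, and an exact tie (or all votes undecided) yields NA.
#'
#' @param votes character matrix, one row per ensemble member, one column
#'   per object (a vector is treated as votes for a single object).
#' @return Character vector of ensemble decisions, NA for undecided.
#' @export
majorityVote <- function(votes) {
    if (is.null(dim(votes))) votes <- matrix(votes, ncol = 1)
    apply(votes, 2, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_character_)
        tab <- sort(table(v), decreasing = TRUE)
        if (length(tab) > 1L && tab[1L] == tab[2L]) NA_character_
        else names(tab)[1L]
    })
}

#' Train an ensemble of independent SOMs
#'
#' Trains `nModels` maps on the same data with independent random
#' initializations and presentation orders (sub-seeds derived from `seed`),
#' then labels each with the training classes.  Ensemble predictions are
#' obtained with [ensembleClassify()].
#'
#' @inheritParams trainSOM
#' @param classes training class labels used to label each member map.
#' @param nModels ensemble size (typically 5 or 10).
#' @param classLevels optional ordered class registry.
#' @return List of labeled [SOMModel-class] objects.
#' @export
somEnsemble <- function(x, classes, nModels = 5, rows = 49, cols = 49,
                        epochs = 75, lr0 = 0.1, span0 = NULL, seed = NULL,
                        classLevels = NULL) {
    seeds <- .subSeeds(seed, nModels)
    lapply(seq_len(nModels), function(k) {
        m <- trainSOM(x, rows, cols, epochs, lr0, span0, seed = seeds[k])
        labelNeurons(m, x, classes, classLevels)
    })
}

#' Ensemble classification by majority vote
#'
#' @param models list of labeled [SOMModel-class] (or [CPNNModel-class])
#'   objects.
#' @param x input matrix.
#' @param threshold decision threshold forwarded to [cpnnClassify()] for
#'   CPNN members; ignored for plain SOMs.
#' @return Character vector of ensemble decisions (NA = undecided).
#' @export
ensembleClassify <- function(models, x, threshold = 0.5) {
    stopifnot(length(models) >= 1L)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    votes <- t(vapply(models, function(m) {
        if (is(m, "CPNNModel")) cpnnClassify(m, x, threshold)
        else somClassify(m, x)
    }, character(nrow(x))))
    majorityVote(votes)
}

#' Export the neuron label map
#'
#' Writes the per-neuron label map as CSV with columns row, col, status and
#' label, supporting class-filtered map views.
#'
#' @param model a labeled [SOMModel-class].
#' @param file path to a CSV file.
#' @return `file`, invisibly.
#' @export
exportLabelMap <- function(model, file) {
    stopifnot(is(model, "SOMModel"))
    if (!nrow(model@labelMap))
        stop("model has not been labeled")
    utils::write.csv(model@labelMap[, c("row", "col", "status", "label")],
                     file, row.names = FALSE, na = "")
    invisible(file)
}
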