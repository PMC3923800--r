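#' Mixture-class label for a pair of reaction types
#'
#' The 15 unordered pairs of 6 reaction types are labelled A-O in
#' lexicographic order over the type registry: (1,2) -> A, (1,3) -> B, ...,
#' (5,6) -> O.  The mapping is symmetric in its arguments.
#'
#' @param typeA,typeB distinct reaction-type labels from `typeLevels`.
#' @param typeLevels ordered character registry of reaction types.
#' @return Single character class label.
#' @examples
#' reg <- paste0("t", 1:6)
#' mixtureClass("t1", "t2", reg)  # "A"
#' mixtureClass("t6", "t5", reg)  # "O"
#' @export
mixtureClass <- function(typeA, typeB, typeLevels) {
    i <- match(typeA, typeLevels)
    j <- match(typeB, typeLevels)
    if (anyNA(i) || anyNA(j))
        stop("both types must belong to the registry")
    if (any(i == j))
        stop("a mixture requires two reactions of distinct types")
    lo <- pmin(i, j); hi <- pmax(i, j)
    k <- length(typeLevels)
    idx <- (lo - 1L) * k - (lo * (lo - 1L)) %/% 2L + (hi - lo)
    LETTERS[idx]
}

#' Table of all mixture classes for a type registry
#'
#' @param typeLevels ordered character registry of reaction types.
#' @return data.frame with columns mclass, typeA, typeB (typeA earlier in
#'   the registry), one row per unordered type pair in label order.
#' @export
mixtureClassTable <- function(typeLevels) {
    k <- length(typeLevels)
    pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
    data.frame(mclass = LETTERS[seq_len(nrow(pairs))],
               typeA = typeLevels[pairs[, "row"]],
               typeB = typeLevels[pairs[, "col"]],
               stringsAsFactors = FALSE)
}

#' The two reaction types composing a mixture class
#'
#' @param mclass a mixture-class label (A-O for six types).
#' @param typeLevels ordered character registry of reaction types.
#' @return Character vector of the two type labels, registry order.
#' @export
classTypes <- function(mclass, typeLevels) {
    tab <- mixtureClassTable(typeLevels)
    row <- tab[tab$mclass == mclass, ]
    if (nrow(row) != 1L) stop(sprintf("unknown mixture class '%s'", mclass))
    c(row$typeA, row$typeB)
}

#' Enumerate all two-reaction cross-type mixtures
#'
#' Produces exactly one mixture per unordered pair of reactions of distinct
#' types (the count is therefore the sum over type pairs i < j of
#' `n_i * n_j`).  The first-listed reaction of each pair is the one whose
#' type comes earlier in the registry; the molar RATIO perturbation applies
#' to it.  Mixture descriptors default to the plain sum of the two reaction
#' spectra (1:1 ratio, unit normalization, full conversion).
#'
#' @param rs a [ReactionSet-class] with at least two types present.
#' @param halfWidth,lo,hi,binWidth fuzzification / binning parameters
#'   forwarded to [descriptorMatrix()].
#' @return A [MixtureSet-class].
#' @export
enumerateMixtures <- function(rs, halfWidth = 0.1, lo = 0, hi = 12,
                              binWidth = 0.1) {
    stopifnot(is(rs, "ReactionSet"))
    types <- reactionTypes(rs)
    ids <- reactionIds(rs)
    D <- descriptorMatrix(rs, 1, halfWidth, lo, hi, binWidth)
    ti <- match(types, rs@typeLevels)
    ord <- order(ti, seq_along(ids))
    n <- length(ord)
    if (n < 2L || length(unique(ti)) < 2L) {
        aIdx <- bIdx <- integer(0)
    } else {
        # all position pairs u < v over the type-sorted order, then drop
        # same-type pairs; rxnA is always the earlier-registry type
        pu <- rep.int(seq_len(n - 1L), (n - 1L):1L)
        pv <- sequence((n - 1L):1L) + pu
        keep <- ti[ord[pu]] != ti[ord[pv]]
        aIdx <- ord[pu[keep]]; bIdx <- ord[pv[keep]]
    }
    .buildMixtureSet(rs@typeLevels, D, ids[aIdx], ids[bIdx],
                     types[aIdx], types[bIdx],
                     list(lo = lo, hi = hi, binWidth = binWidth))
}

.buildMixtureSet <- function(typeLevels, D, rxnA, rxnB, typeA, typeB,
                             binning, ratio = 1, norm = 1,
                             yieldA = 1, yieldB = 1, ids = NULL) {
    n <- length(rxnA)
    man <- data.frame(
        id = if (is.null(ids)) sprintf("M%05d", seq_len(n)) else ids,
        rxnA = rxnA, rxnB = rxnB, typeA = typeA, typeB = typeB,
        mclass = if (n) mixtureClass(typeA, typeB, typeLevels) else character(0),
        ratio = rep_len(ratio, n), norm = rep_len(norm, n),
        yieldA = rep_len(yieldA, n), yieldB = rep_len(yieldB, n),
        stringsAsFactors = FALSE)
    X <- .mixtureMatrix(D, man)
    rownames(X) <- man$id
    new("MixtureSet", manifest = man, descriptors = X, rxnDescriptors = D,
        typeLevels = typeLevels, binning = binning)
}

# MIXTURE = NORM * (RATIO * yieldA * A + yieldB * B), rowwise
.mixtureMatrix <- function(D, man) {
    if (!nrow(man)) return(matrix(0, 0, ncol(D)))
    A <- D[man$rxnA, , drop = FALSE]
    B <- D[man$rxnB, , drop = FALSE]
    man$norm * (man$ratio * man$yieldA * A + man$yieldB * B)
}

#' Combine two reaction descriptors into a mixture descriptor
#'
#' Implements `NORM * (RATIO * a + b)` on binned spectra: the difference
#' spectrum of a mixture in which reaction `a` is present at molar ratio
#' `ratio` relative to `b`, with a global integration-normalization factor
#' `norm`.  Conversion yields are assumed already folded into `a` and `b`
#' (see [reactionSpectrum()]).
#'
#' @param a,b [BinnedSpectrum-class] objects on the same grid.
#' @param ratio,norm positive reals (defaults 1: plain sum).
#' @return A [BinnedSpectrum-class].
#' @export
mixtureDescriptor <- function(a, b, ratio = 1, norm = 1) {
    .assertScalarNumber(ratio, "ratio", lower = 0, strict = TRUE)
    .assertScalarNumber(norm, "norm", lower = 0, strict = TRUE)
    combineBinned(list(a, b), c(norm * ratio, norm))
}

setMethod("length", "MixtureSet", function(x) nrow(x@manifest))

setMethod("[", "MixtureSet", function(x, i, j, ..., drop = TRUE) {
    new("MixtureSet", manifest = x@manifest[i, , drop = FALSE],
        descriptors = x@descriptors[i, , drop = FALSE],
        rxnDescriptors = x@rxnDescriptors, typeLevels = x@typeLevels,
        binning = x@binning)
})

setMethod("show", "MixtureSet", function(object) {
    cat(sprintf("MixtureSet with %d mixture(s) over %d reaction type(s), %d descriptor bin(s)\n",
                nrow(object@manifest), length(object@typeLevels),
                ncol(object@descriptors)))
    tab <- table(factor(object@manifest$mclass,
                        levels = mixtureClassTable(object@typeLevels)$mclass))
    cat("  classes:", paste(sprintf("%s:%d", names(tab), tab),
                            collapse = " "), "\n")
})

#' Mixture-set accessors
#'
#' @param x a [MixtureSet-class].
#' @return `descriptors`: the mixture descriptor matrix; `manifest`: the
#'   mixture manifest data.frame; `mixtureClasses`: character vector of
#'   class labels.
#' @export
descriptors <- function(x) {
    stopifnot(is(x, "MixtureSet"))
    x@descriptors
}

#' @rdname descriptors
#' @export
manifest <- function(x) {
    stopifnot(is(x, "MixtureSet"))
    x@manifest
}

#' @rdname descriptors
#' @export
mixtureClasses <- function(x) {
    stopifnot(is(x, "MixtureSet"))
    x@manifest$mclass
}

#' Random mixture-level train/test partition
#'
#' Splits the mixtures themselves at random (the same reaction may then
#' appear in mixtures on both sides, combined with different partners).
#'
#' @param ms a [MixtureSet-class].
#' @param trainSize number of mixtures assigned to the training side;
#'   must satisfy `0 < trainSize < length(ms)`.
#' @param seed integer seed for reproducibility (NULL: current RNG stream).
#' @return list with [MixtureSet-class] elements `train` and `test`.
#' @export
partitionMixtures <- function(ms, trainSize, seed = NULL) {
    stopifnot(is(ms, "MixtureSet"))
    n <- length(ms)
    if (!(trainSize > 0 && trainSize < n))
        stop("'trainSize' must be strictly between 0 and the number of mixtures")
    idx <- .withSeed(seed, sample.int(n, trainSize))
    list(train = ms[sort(idx)], test = ms[setdiff(seq_len(n), idx)])
}

#' Reaction-level train/test partition
#'
#' Splits the reactions (not the mixtures) into train/test subsets with
#' given per-type training counts, then enumerates mixtures within each
#' subset.  No reaction id appears on both sides, making the test set
#' genuinely independent of the training set.
#'
#' @param rs a [ReactionSet-class].
#' @param trainCounts integer vector of per-type training counts in
#'   registry order (each at most the type's size).
#' @param seed integer seed (NULL: current RNG stream).
#' @param ... binning parameters forwarded to [enumerateMixtures()].
#' @return list with elements `train` and `test` ([MixtureSet-class]) and
#'   `trainIds` / `testIds` (character vectors of reaction ids).
#' @export
partitionReactions <- function(rs, trainCounts, seed = NULL, ...) {
    stopifnot(is(rs, "ReactionSet"))
    types <- reactionTypes(rs)
    ids <- reactionIds(rs)
    if (length(trainCounts) != length(rs@typeLevels))
        stop("'trainCounts' must give one count per registry type")
    sizes <- as.vector(table(factor(types, levels = rs@typeLevels)))
    if (any(trainCounts < 0) || any(trainCounts > sizes))
        stop("per-type training counts must lie between 0 and the type sizes")
    trainIds <- .withSeed(seed, {
        unlist(lapply(seq_along(rs@typeLevels), function(k) {
            pool <- ids[types == rs@typeLevels[k]]
            pool[sample.int(length(pool), trainCounts[k])]
        }))
    })
    testIds <- setdiff(ids, trainIds)
    list(train = enumerateMixtures(rs[match(trainIds, ids)], ...),
         test = enumerateMixtures(rs[match(testIds, ids)], ...),
         trainIds = trainIds, testIds = testIds)
}

#' Perturbed variants of a mixture set
#'
#' Rebuilds mixture descriptors as `NORM * (RATIO * yieldA * A + yieldB * B)`
#' under either (i) a battery of fixed RATIO values -- one record per
#' (mixture, ratio) -- or (ii) `replicates` records per mixture with yields,
#' NORM and RATIO sampled uniformly from given ranges.  Degenerate ranges
#' (`c(v, v)`) pin a parameter.
#'
#' @param ms a [MixtureSet-class].
#' @param ratios numeric vector of fixed RATIO values (mode i); ignored if
#'   `ratioRange` is given.
#' @param yieldRange,normRange,ratioRange length-2 numeric ranges (mode ii);
#'   unspecified ranges default to the constant 1.
#' @param replicates records per mixture in mode ii.
#' @param seed integer seed (NULL: current RNG stream).
#' @return A [MixtureSet-class] whose manifest records the parameters used.
#' @export
perturbMixtures <- function(ms, ratios = NULL, yieldRange = NULL,
                            normRange = NULL, ratioRange = NULL,
                            replicates = 1, seed = NULL) {
    stopifnot(is(ms, "MixtureSet"))
    man <- ms@manifest
    if (!nrow(man)) stop("empty mixture set")
    if (is.null(ratios) && is.null(yieldRange) && is.null(normRange) &&
        is.null(ratioRange))
        stop("empty battery: specify fixed 'ratios' or at least one parameter range")
    if (!is.null(ratios) && !is.null(ratioRange))
        stop("give either fixed 'ratios' or a 'ratioRange', not both")
    reps <- as.integer(replicates)
    stopifnot(reps >= 1L)
    .withSeed(seed, {
        if (!is.null(ratios)) {
            big <- man[rep(seq_len(nrow(man)), times = length(ratios) * reps), ]
            big$ratio <- rep(ratios, each = nrow(man) * reps)
        } else {
            big <- man[rep(seq_len(nrow(man)), times = reps), ]
            if (!is.null(ratioRange))
                big$ratio <- stats::runif(nrow(big), ratioRange[1],
                                          ratioRange[2])
        }
        n <- nrow(big)
        if (!is.null(yieldRange)) {
            big$yieldA <- stats::runif(n, yieldRange[1], yieldRange[2])
            big$yieldB <- stats::runif(n, yieldRange[1], yieldRange[2])
        }
        if (!is.null(normRange))
            big$norm <- stats::runif(n, normRange[1], normRange[2])
        big$id <- sprintf("%s.p%03d", big$id,
                          stats::ave(seq_len(n), big$id, FUN = seq_along))
        X <- .mixtureMatrix(ms@rxnDescriptors, big)
        rownames(X) <- big$id
        rownames(big) <- NULL
        new("MixtureSet", manifest = big, descriptors = X,
            rxnDescriptors = ms@rxnDescriptors, typeLevels = ms@typeLevels,
            binning = ms@binning)
    })
}
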