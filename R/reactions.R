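#' Construct a reaction record
#'
#' @param id single character identifier.
#' @param rtype reaction-type label.
#' @param reactants list of [ShiftList-class] objects (one per reactant).
#' @param product a [ShiftList-class] with at least one peak.
#' @return A [ReactionRecord-class].
#' @export
ReactionRecord <- function(id, rtype, reactants, product) {
    if (is(reactants, "ShiftList")) reactants <- list(reactants)
    new("ReactionRecord", id = as.character(id), rtype = as.character(rtype),
        reactants = reactants, product = product)
}

setMethod("show", "ReactionRecord", function(object) {
    cat(sprintf("ReactionRecord '%s' (type %s): %d reactant spectra (%g H) -> product (%g H)\n",
                object@id, object@rtype, length(object@reactants),
                sum(vapply(object@reactants, totalProtons, numeric(1))),
                totalProtons(object@product)))
})

#' Construct a reaction set
#'
#' @param reactions list of [ReactionRecord-class] objects.
#' @param typeLevels ordered character registry of reaction types; defaults
#'   to the unique types in order of first appearance.  The order matters:
#'   mixture-class labels are derived from it.
#' @return A [ReactionSet-class].
#' @export
ReactionSet <- function(reactions, typeLevels = NULL) {
    if (is.null(typeLevels))
        typeLevels <- unique(vapply(reactions, slot, character(1), "rtype"))
    new("ReactionSet", reactions = reactions,
        typeLevels = as.character(typeLevels))
}

setMethod("length", "ReactionSet", function(x) length(x@reactions))

setMethod("[[", "ReactionSet", function(x, i) x@reactions[[i]])

setMethod("[", "ReactionSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, reactionIds(x))
    new("ReactionSet", reactions = x@reactions[i], typeLevels = x@typeLevels)
})

setMethod("show", "ReactionSet", function(object) {
    types <- reactionTypes(object)
    cat(sprintf("ReactionSet with %d reaction(s), %d type(s)\n",
                length(object@reactions), length(object@typeLevels)))
    tab <- table(factor(types, levels = object@typeLevels))
    for (i in seq_along(tab))
        cat(sprintf("  %-22s %d\n", names(tab)[i], tab[i]))
})

#' Reaction-level accessors
#'
#' @param x a [ReactionSet-class].
#' @return `reactionIds`: character vector of ids; `reactionTypes`:
#'   character vector of type labels; `typeLevels`: the ordered type
#'   registry.
#' @export
reactionIds <- function(x) {
    stopifnot(is(x, "ReactionSet"))
    vapply(x@reactions, slot, character(1), "id")
}

#' @rdname reactionIds
#' @export
reactionTypes <- function(x) {
    stopifnot(is(x, "ReactionSet"))
    vapply(x@reactions, slot, character(1), "rtype")
}

#' @rdname reactionIds
#' @export
typeLevels <- function(x) {
    if (is(x, "ReactionSet") || is(x, "MixtureSet")) return(x@typeLevels)
    stop("no type registry for this object")
}

# pool several stick spectra by concatenation (1:1 stoichiometry)
.poolShiftLists <- function(lists) {
    ShiftList(unlist(lapply(lists, slot, "shift")),
              unlist(lapply(lists, slot, "protons")))
}

#' Reaction spectrum: binned difference between product and reactants
#'
#' Builds the reaction descriptor: all reactant signals are pooled
#' (integrating proportionally to proton counts), both sides are fuzzified
#' and binned, and the reactant spectrum is subtracted from the product
#' spectrum.  At conversion `yield_` the difference between the mixture
#' after and before the reaction is `yield_ * (product - reactants)`, since
#' unreacted material cancels.
#'
#' @param rxn a [ReactionRecord-class].
#' @param yield_ conversion fraction in (0, 1]; default 1 (full conversion).
#' @param halfWidth fuzzification half width in ppm.
#' @param lo,hi,binWidth binning grid (defaults 0-12 ppm, 0.1 ppm).
#' @return A [BinnedSpectrum-class] with signed values.
#' @export
reactionSpectrum <- function(rxn, yield_ = 1, halfWidth = 0.1,
                             lo = 0, hi = 12, binWidth = 0.1) {
    stopifnot(is(rxn, "ReactionRecord"))
    .assertScalarNumber(yield_, "yield_", lower = 0, upper = 1, strict = FALSE)
    if (yield_ <= 0) stop("'yield_' must be in (0, 1]")
    if (!length(rxn@product@shift))
        stop(sprintf("reaction '%s' has an empty product spectrum", rxn@id))
    prod <- binSpectrum(fuzzify(rxn@product, halfWidth), lo, hi, binWidth)
    reac <- binSpectrum(fuzzify(.poolShiftLists(rxn@reactants), halfWidth),
                        lo, hi, binWidth)
    combineBinned(list(prod, reac), c(yield_, -yield_))
}

#' Descriptor matrix for a reaction set
#'
#' One reaction spectrum per row, at the given conversion.
#'
#' @inheritParams reactionSpectrum
#' @param rs a [ReactionSet-class].
#' @return Numeric matrix (reactions x bins) with reaction ids as rownames.
#' @export
descriptorMatrix <- function(rs, yield_ = 1, halfWidth = 0.1,
                             lo = 0, hi = 12, binWidth = 0.1) {
    stopifnot(is(rs, "ReactionSet"))
    nBins <- round((hi - lo) / binWidth)
    out <- matrix(0, length(rs), nBins,
                  dimnames = list(reactionIds(rs), NULL))
    for (i in seq_len(length(rs)))
        out[i, ] <- binValues(reactionSpectrum(rs[[i]], yield_, halfWidth,
                                               lo, hi, binWidth))
    out
}

#' Read and write reaction sets as JSON
#'
#' The on-disk format is a JSON object with a `typeLevels` array and a
#' `reactions` array of records `{id, type, reactants, product}`, where each
#' spectrum is an array of `[shift, protons]` pairs and `reactants` is an
#' array of such spectra.
#'
#' @param rs a [ReactionSet-class].
#' @param file path to a JSON file.
#' @return `readReactions` returns a [ReactionSet-class]; `writeReactions`
#'   returns `file` invisibly.
#' @export
writeReactions <- function(rs, file) {
    stopifnot(is(rs, "ReactionSet"))
    asPairs <- function(sl) unname(Map(function(s, p) c(s, p),
                                       sl@shift, sl@protons))
    recs <- lapply(rs@reactions, function(r) list(
        id = r@id, type = r@rtype,
        reactants = lapply(r@reactants, asPairs),
        product = asPairs(r@product)))
    jsonlite::write_json(list(typeLevels = rs@typeLevels, reactions = recs),
                         file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' @rdname writeReactions
#' @export
readReactions <- function(file) {
    doc <- jsonlite::read_json(file, simplifyVector = FALSE)
    fromPairs <- function(pairs) ShiftList(
        vapply(pairs, function(p) as.numeric(p[[1]]), numeric(1)),
        vapply(pairs, function(p) as.numeric(p[[2]]), numeric(1)))
    recs <- lapply(doc$reactions, function(r) ReactionRecord(
        r$id, r$type,
        reactants = lapply(r$reactants, fromPairs),
        product = fromPairs(r$product)))
    ReactionSet(recs, typeLevels = unlist(doc$typeLevels))
}
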