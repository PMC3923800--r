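#' Construct a stick spectrum
#'
#' @param shift numeric vector of chemical shifts (ppm).
#' @param protons numeric vector of positive integration weights (proton
#'   counts), recycled against `shift`.
#' @return A [ShiftList-class].
#' @examples
#' ShiftList(c(3.0, 7.2), c(2, 1))
#' @export
ShiftList <- function(shift = numeric(0), protons = numeric(0)) {
    if (length(shift) && length(protons) == 1L)
        protons <- rep(protons, length(shift))
    new("ShiftList", shift = as.numeric(shift), protons = as.numeric(protons))
}

#' @describeIn ShiftList total integration (sum of proton counts).
#' @param x a `ShiftList`.
#' @export
totalProtons <- function(x) {
    stopifnot(is(x, "ShiftList"))
    sum(x@protons)
}

setMethod("length", "ShiftList", function(x) length(x@shift))

setMethod("show", "ShiftList", function(object) {
    cat(sprintf("ShiftList with %d peak(s), %.3g protons total\n",
                length(object@shift), sum(object@protons)))
    if (length(object@shift)) {
        n <- min(length(object@shift), 6L)
        cat(paste(sprintf("  %.3f ppm (%gH)", object@shift[seq_len(n)],
                          object@protons[seq_len(n)]), collapse = "\n"), "\n")
        if (length(object@shift) > n) cat("  ...\n")
    }
})

#' Fuzzify a stick spectrum with triangular functions
#'
#' Each peak becomes a triangle centred at its chemical shift with support
#' `shift +/- halfWidth` and integral equal to its proton count (apex height
#' `protons / halfWidth`).  The triangular profile tolerates small errors in
#' predicted chemical shifts.
#'
#' @param peaks a [ShiftList-class].
#' @param halfWidth half width of the triangle in ppm (default 0.1, i.e.
#'   0.1 ppm on each side of the shift).
#' @return A [FuzzySpectrum-class].
#' @examples
#' fuzzify(ShiftList(3.05, 2))  # apex height 20 at 3.05 ppm, area 2
#' @export
fuzzify <- function(peaks, halfWidth = 0.1) {
    stopifnot(is(peaks, "ShiftList"))
    .assertScalarNumber(halfWidth, "halfWidth", lower = 0, strict = TRUE)
    new("FuzzySpectrum", center = peaks@shift,
        halfWidth = rep(halfWidth, length(peaks@shift)),
        area = peaks@protons)
}

setMethod("show", "FuzzySpectrum", function(object) {
    cat(sprintf("FuzzySpectrum with %d triangle(s), total area %.4g\n",
                length(object@center), sum(object@area)))
})

#' Evaluate a fuzzified spectrum pointwise
#'
#' Intensity of the piecewise-linear (sum of triangles) spectrum at given
#' ppm positions.  Mostly useful for plotting and as a quadrature check.
#'
#' @param spec a [FuzzySpectrum-class].
#' @param at numeric vector of ppm positions.
#' @return Numeric vector of intensities.
#' @export
fuzzyIntensity <- function(spec, at) {
    stopifnot(is(spec, "FuzzySpectrum"))
    out <- numeric(length(at))
    for (i in seq_along(spec@center)) {
        w <- spec@halfWidth[i]
        h <- spec@area[i] / w
        u <- abs(at - spec@center[i]) / w
        out <- out + h * pmax(0, 1 - u)
    }
    out
}

# CDF of a unit-area triangle centred at 0 with half width 1,
# evaluated at (possibly out-of-support) t.
.triangleCdf <- function(t) {
    t <- pmin(pmax(t, -1), 1)
    ifelse(t <= 0, (t + 1)^2 / 2, 1 - (1 - t)^2 / 2)
}

#' Bin a fuzzified spectrum on a regular ppm grid
#'
#' Integrates the piecewise-linear spectrum analytically over half-open bins
#' `[lo + (k-1) * binWidth, lo + k * binWidth)`.  The default grid spans
#' 0-12 ppm in 0.1 ppm intervals, giving 120 variables.  Mass outside
#' `[lo, hi]` is dropped; its total is stored in the `clipped` slot and a
#' warning is issued.
#'
#' @param spec a [FuzzySpectrum-class].
#' @param lo,hi grid limits in ppm.
#' @param binWidth bin width in ppm; `(hi - lo) / binWidth` must be integral.
#' @return A [BinnedSpectrum-class].
#' @examples
#' bs <- binSpectrum(fuzzify(ShiftList(3.05, 1)))
#' binValues(bs)[30:32]  # 0.125, 0.75, 0.125
#' @export
binSpectrum <- function(spec, lo = 0, hi = 12, binWidth = 0.1) {
    stopifnot(is(spec, "FuzzySpectrum"))
    if (hi <= lo) stop("'hi' must exceed 'lo'")
    nBins <- round((hi - lo) / binWidth)
    if (abs(nBins * binWidth - (hi - lo)) > 1e-8)
        stop("(hi - lo) must be an integral number of bin widths")
    edges <- lo + binWidth * (0:nBins)
    values <- numeric(nBins)
    for (i in seq_along(spec@center)) {
        cdf <- spec@area[i] *
            .triangleCdf((edges - spec@center[i]) / spec@halfWidth[i])
        values <- values + diff(cdf)
    }
    clipped <- sum(spec@area) - sum(values)
    if (clipped > 1e-9)
        warning(sprintf("%.4g proton-units of fuzzified mass fall outside [%g, %g] ppm and were dropped",
                        clipped, lo, hi))
    new("BinnedSpectrum", values = values, lo = lo, hi = hi,
        binWidth = binWidth, clipped = max(clipped, 0))
}

#' Accessors for binned spectra
#'
#' `binValues` returns the per-bin integrals, `binGrid` the grid parameters
#' and `clippedMass` the out-of-range mass dropped during binning.
#'
#' @param x a [BinnedSpectrum-class].
#' @return `binValues`: numeric vector; `binGrid`: named list (lo, hi,
#'   binWidth, nBins); `clippedMass`: numeric.
#' @export
binValues <- function(x) {
    stopifnot(is(x, "BinnedSpectrum"))
    x@values
}

#' @rdname binValues
#' @export
binGrid <- function(x) {
    stopifnot(is(x, "BinnedSpectrum"))
    list(lo = x@lo, hi = x@hi, binWidth = x@binWidth,
         nBins = length(x@values))
}

#' @rdname binValues
#' @export
clippedMass <- function(x) {
    stopifnot(is(x, "BinnedSpectrum"))
    x@clipped
}

setMethod("show", "BinnedSpectrum", function(object) {
    cat(sprintf("BinnedSpectrum: %d bins of %g ppm over [%g, %g] ppm\n",
                length(object@values), object@binWidth, object@lo, object@hi))
    cat(sprintf("  integral %.4g, %d non-zero bin(s)",
                sum(object@values), sum(object@values != 0)))
    if (object@clipped > 0)
        cat(sprintf(", %.3g clipped", object@clipped))
    cat("\n")
})

.sameGrid <- function(a, b) {
    isTRUE(all.equal(c(a@lo, a@hi, a@binWidth), c(b@lo, b@hi, b@binWidth),
                     tolerance = 1e-12))
}

#' Linear combination of binned spectra
#'
#' @param spectra list of [BinnedSpectrum-class] objects sharing one grid.
#' @param coefficients numeric vector, one per spectrum.
#' @return A [BinnedSpectrum-class] holding the elementwise combination.
#' @export
combineBinned <- function(spectra, coefficients) {
    stopifnot(length(spectra) == length(coefficients), length(spectra) >= 1L)
    ref <- spectra[[1L]]
    for (s in spectra)
        if (!.sameGrid(ref, s))
            stop("all spectra must share lo/hi/binWidth")
    values <- Reduce(`+`, Map(function(s, a) a * s@values,
                              spectra, coefficients))
    new("BinnedSpectrum", values = values, lo = ref@lo, hi = ref@hi,
        binWidth = ref@binWidth, clipped = 0)
}
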