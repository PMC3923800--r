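# Independent numerical oracles used across test files.

# Midpoint-quadrature binning of a fuzzified spectrum on a fine ppm grid;
# independent of the analytic integration in binSpectrum().
gridBinOracle <- function(fs, lo = 0, hi = 12, binWidth = 0.1, dx = 1e-4) {
    xs <- seq(lo + dx / 2, hi - dx / 2, by = dx)
    val <- fuzzyIntensity(fs, xs)
    bin <- pmin(floor((xs - lo) / binWidth) + 1L, round((hi - lo) / binWidth))
    as.numeric(rowsum(val * dx, bin)[, 1])
}

# Brute-force winner search: plain R loop over neurons.
bruteWinner <- function(weights, x) {
    d2 <- apply(weights, 1, function(w) sum((w - x)^2))
    which.min(d2)
}

# Brute-force cross-type pair count from a vector of type labels.
brutePairCount <- function(types) {
    n <- 0L
    for (u in seq_along(types)) {
        for (v in seq_along(types)) {
            if (v > u && types[u] != types[v]) n <- n + 1L
        }
    }
    n
}

# A tiny deterministic reaction set exercising all six synthetic templates.
tinyReactionSet <- function(perType = 2, seed = 11) {
    generateReactions(counts = rep(perType, 6), seed = seed)
}
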