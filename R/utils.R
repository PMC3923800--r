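# Run code under a temporary RNG seed (restoring the caller's RNG state);
# NULL means "use the current RNG stream".
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    withr::with_seed(seed, code)
}

# Derive a reproducible sub-seed stream from a master seed (kept < 2^31).
.subSeeds <- function(seed, n) {
    .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
        (if (strict) x > lower && x < upper else x >= lower && x <= upper)
    if (!ok)
        stop(sprintf("'%s' must be a single finite number in %s%s, %s%s",
                     name, if (strict) "(" else "[", format(lower),
                     format(upper), if (strict) ")" else "]"), call. = FALSE)
    invisible(x)
}
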