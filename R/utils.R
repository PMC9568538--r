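## Classed conditions used across the package so callers (and the CLI) can
## distinguish validation problems (bad values), I/O problems, and contract
## violations (a pluggable component breaking its advertised interface).

validationError <- function(fmt, ...) {
    stop(structure(
        class = c("painstrips_validation_error", "error", "condition"),
        list(message = sprintf(fmt, ...), call = sys.call(-1))
    ))
}

ioError <- function(fmt, ...) {
    stop(structure(
        class = c("painstrips_io_error", "error", "condition"),
        list(message = sprintf(fmt, ...), call = sys.call(-1))
    ))
}

contractError <- function(fmt, ...) {
    stop(structure(
        class = c("painstrips_contract_error", "error", "condition"),
        list(message = sprintf(fmt, ...), call = sys.call(-1))
    ))
}

## Run code under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        validationError("'seed' must be a single finite number")
    withr::with_seed(as.integer(seed), code)
}

assertCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
        validationError("'%s' must be a single integer >= %d", name, min)
    as.integer(x)
}

assertIntensity <- function(x, name, max) {
    if (!is.numeric(x) || anyNA(x) || any(x != round(x)))
        validationError("'%s' must be integer-valued with no missing entries", name)
    if (any(x < 0 | x > max))
        validationError("'%s' out of range: intensities must lie in 0..%d", name, max)
    as.integer(x)
}

## Round half away from zero (presentation-layer rounding for percentages).
roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}
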