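# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so callers can demand determinism without disturbing
#' the session stream. `seed = NULL` evaluates `code` against the current
#' stream (used when a caller has already seeded an enclosing scope).
#'
#' @param seed Integer scalar or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (had)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Derive `n` reproducible sub-seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(2147483646L, n, replace = FALSE))
}

# Scalar type checks used by validity methods and argument checking.
isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
isScalarFlag   <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# GRanges strand as BED text: "*" (unknown) becomes ".".
strandToBed <- function(s) {
    s <- as.character(s)
    s[s == "*"] <- "."
    s
}

# BED strand text to GRanges strand: "." becomes "*".
strandFromBed <- function(s) {
    s[s == "."] <- "*"
    s
}
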