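# internal helpers shared across modules

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All seeded operations in the package go
# through this so that user-level RNG state is never disturbed.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single non-missing number")
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# stopifnot with sprintf-style message
assertThat <- function(ok, fmt, ...) {
    if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
    invisible(TRUE)
}

# z-standardize a numeric vector; constant vectors are an error by default
zstd <- function(x, what = "variable") {
    s <- stats::sd(x, na.rm = TRUE)
    assertThat(is.finite(s) && s > 0, "%s has zero variance", what)
    (x - mean(x, na.rm = TRUE)) / s
}

# collapse a character set to a single comma-separated token ("" when empty)
joinCodes <- function(x) vapply(x, function(v) paste(v, collapse = ","),
                                character(1))

splitCodes <- function(x) {
    strsplit(ifelse(is.na(x) | x == "", "", x), "[,;] *")
}
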