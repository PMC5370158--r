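# Small shared helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || is.na(seed))
        stop("'seed' must be a number")
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hasSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# One random base different from each element of `base` (recycled to n).
randomOtherBase <- function(base, n = length(base)) {
    base <- rep_len(base, n)
    vapply(base, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "",
        USE.NAMES = FALSE)
}

complementBase <- function(base) {
    c(A = "T", C = "G", G = "C", T = "A")[base]
}
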