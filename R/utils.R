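#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, then restores the caller's RNG state, so
#' seeded internals never perturb the global random stream.
#' @noRd
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}
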