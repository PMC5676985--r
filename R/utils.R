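## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards so library code never perturbs user
## simulations.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopIfNotFinite <- function(x, what) {
    if (any(!is.finite(x)))
        stop(what, " must be finite", call. = FALSE)
    invisible(x)
}

## Reflection (symmetric, edge-inclusive) index vector of length n + 2r:
## for n = 4, r = 2 gives 2 1 1 2 3 4 4 3.
reflectIndex <- function(n, r) {
    if (r >= n)
        stop("padding radius must be smaller than the image dimension",
             call. = FALSE)
    c(rev(seq_len(r)), seq_len(n), seq(n, n - r + 1L))
}

## Pad a matrix by reflection with radius r on all sides.
padReflect <- function(m, r) {
    m[reflectIndex(nrow(m), r), reflectIndex(ncol(m), r), drop = FALSE]
}

## Extract a numeric matrix from a ThermalFrame or pass a matrix through.
asPixelMatrix <- function(x) {
    if (is(x, "ThermalFrame")) x@pixels
    else if (is.matrix(x)) x
    else stop("expected a ThermalFrame or a numeric matrix", call. = FALSE)
}
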