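# internal helpers shared across modules

# run expr under a local RNG seed without disturbing the caller's stream
withLocalSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# derive a child seed < 2^31 from a base seed and an index
childSeed <- function(seed, index) {
    as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483647)
}

# integer pixel offsets (dr, dc) within radius r of the origin
diskOffsets <- function(r) {
    g <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
    g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# offsets with inner < d <= outer (background annulus)
annulusOffsets <- function(inner, outer) {
    g <- expand.grid(dr = -ceiling(outer):ceiling(outer),
                     dc = -ceiling(outer):ceiling(outer))
    d2 <- g$dr^2 + g$dc^2
    g[d2 > inner^2 & d2 <= outer^2, , drop = FALSE]
}

# robust per-frame noise sd from first differences of a trace
robustNoiseSd <- function(y) {
    if (length(y) < 3L) return(0)
    stats::mad(diff(y)) / sqrt(2)
}

emptySpotTable <- function() {
    data.frame(field = integer(), channel = character(),
               x_px = numeric(), y_px = numeric(),
               intensity = numeric(), peak = numeric(),
               stringsAsFactors = FALSE)
}
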