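# internal helpers

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    code
}

# stable numeric formatting for writers: 6 significant digits, scientific
# notation for very large/small magnitudes so output is locale-independent
.fmtNum <- function(x) {
    out <- formatC(x, digits = 6, format = "g")
    gsub("^\\s+", "", out)
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
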