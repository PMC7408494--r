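## internal helpers shared across modules

.assertCount <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
        x != as.integer(x))
        stop(sprintf("'%s' must be a single integer >= %d", name, min),
             call. = FALSE)
    as.integer(x)
}

## row medians without a matrixStats dependency; matrices here are modest
.rowMedians <- function(m) {
    if (is.null(dim(m))) return(stats::median(m))
    apply(m, 1L, stats::median)
}

## run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

.writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
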