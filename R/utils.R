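# Internal helpers shared across modules.

# Evaluate expr under a fixed Mersenne-Twister seed, restoring the caller's
# RNG state afterwards. All randomness in the package funnels through this.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    expr
}

# Stable per-iteration seed: a fixed linear hash of (seed, j) modulo 2^31-1,
# so iteration j's subsample does not depend on execution order.
iterationSeed <- function(seed, j) {
    h <- ((as.numeric(seed) %% 2147483647) * 69069 + as.numeric(j) * 1234567) %% 2147483647
    as.integer(h) + 1L
}

# Shared retention boundary: a clade passes with presence count k iff
# k > p * i (strict). The 1e-9 guard protects integer p*i against binary
# rounding (e.g. 0.8 * 50).
presenceCutoff <- function(p, i) floor(p * i + 1e-9)

passesPresenceThreshold <- function(k, p, i) k > presenceCutoff(p, i)

isGzPath <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

clamp01 <- function(x) pmin(1, pmax(0, x))

usageError <- function(...) {
    stop(structure(class = c("microcensus_usage_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}
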