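#' @include AllClasses.R utils.R
NULL

# The design calculator works under the perfect-alignment model: every
# sampled read maps to its true source taxon, so the number of taxon reads
# in one iteration is Binomial(m, q) and per-iteration presence (>= 1 read)
# is Bernoulli with probability 1 - (1 - q)^m. Cross-clade misalignment is
# deliberately outside this model.

#' Per-iteration presence probability
#'
#' Probability that a taxon at true proportion `q` contributes at least one
#' read to a subsample of `m` reads: `1 - (1 - q)^m`.
#'
#' @param q true taxon proportion in \[0, 1\].
#' @param m subsample size (>= 1).
#' @return numeric in \[0, 1\] (vectorized over `q` and `m`).
#' @examples
#' presenceProbability(0.5, 2)  # 0.75
#' @export
presenceProbability <- function(q, m) {
    if (any(q < 0 | q > 1)) stop("q must be in [0, 1]")
    if (any(m < 1)) stop("m must be >= 1")
    1 - (1 - q)^m
}

#' Exact detection power of the census filter
#'
#' Probability that a taxon at proportion `q` passes the retention rule —
#' presence in strictly more than `p * i` of the `i` iterations — under the
#' perfect-alignment model: the exact binomial tail `P(X > p * i)` for
#' `X ~ Binomial(i, 1 - (1 - q)^m)`. The strict boundary is shared with the
#' census module.
#'
#' @param q true taxon proportion.
#' @param m subsample size per iteration.
#' @param i number of iterations.
#' @param p presence threshold (default 0.8).
#' @return a [PowerEstimate] with method `"exact"`.
#' @examples
#' detectionPower(q = 0.01, m = 250, i = 50)@power  # > 0.99
#' @export
detectionPower <- function(q, m, i, p = 0.8) {
    stopifnot(length(q) == 1, length(m) == 1, length(i) == 1, i >= 1,
              p >= 0, p <= 1)
    pi <- presenceProbability(q, m)
    pow <- 1 - pbinom(presenceCutoff(p, i), i, pi)
    new("PowerEstimate", q = as.numeric(q), m = as.integer(m),
        iterations = as.integer(i), p = as.numeric(p), presenceProb = pi,
        power = pow, mae = NA_real_, ciMargin = NA_real_, method = "exact",
        reps = NA_integer_, seed = NA_integer_)
}

#' Exact mean absolute error of the pooled abundance estimator
#'
#' The pooled estimator is the mean of per-iteration sample proportions,
#' i.e. total taxon reads over `N = m * i`. Under the perfect-alignment
#' model `T ~ Binomial(N, q)`, and this computes `E|T/N - q|` by full pmf
#' summation (in blocks, so `N` up to 1e7 stays memory-light).
#'
#' @param q true taxon proportion.
#' @param m subsample size per iteration.
#' @param i number of iterations.
#' @return numeric scalar, the exact mean absolute error.
#' @examples
#' estimationError(q = 0.1, m = 25, i = 50)   # ~0.007
#' estimationError(q = 0.1, m = 100, i = 50)  # ~0.003
#' @export
estimationError <- function(q, m, i) {
    if (q < 0 || q > 1) stop("q must be in [0, 1]")
    N <- as.numeric(m) * as.numeric(i)
    if (N < 1) stop("m * i must be >= 1")
    if (N > 1e7)
        stop("m * i = ", format(N), " exceeds 1e7; exact summation is ",
             "impractical, use simulateDesign() (Monte Carlo) instead")
    total <- 0
    block <- 1e6
    lo <- 0
    while (lo <= N) {
        t <- lo:min(N, lo + block - 1)
        total <- total + sum(abs(t / N - q) * dbinom(t, N, q))
        lo <- lo + block
    }
    total
}

#' Monte-Carlo power, estimation error and interval margin
#'
#' Simulates `reps` independent censuses under the perfect-alignment model:
#' each census draws `i` iteration counts from Binomial(m, q), applies the
#' presence rule (count >= 1) and the strict retention threshold, and pools
#' the per-iteration proportions. Besides power and mean absolute error it
#' reports the expected half-width of the census module's implemented
#' interval (1.96 times the across-iteration sd).
#'
#' @param q true taxon proportion.
#' @param m subsample size per iteration.
#' @param i number of iterations.
#' @param p presence threshold (default 0.8).
#' @param reps Monte Carlo replicates (>= 1).
#' @param seed RNG seed (reproducible).
#' @return a [PowerEstimate] with method `"monte_carlo"`.
#' @export
simulateDesign <- function(q, m, i, p = 0.8, reps = 10000L, seed = 1L) {
    stopifnot(reps >= 1, q >= 0, q <= 1, m >= 1, i >= 1)
    counts <- withSeed(seed,
        matrix(rbinom(as.numeric(reps) * i, m, q), nrow = reps, ncol = i))
    presence <- rowSums(counts > 0)
    pow <- mean(passesPresenceThreshold(presence, p, i))
    frac <- counts / m
    est <- rowMeans(frac)
    mae <- mean(abs(est - q))
    sdRow <- if (i > 1)
        sqrt(pmax(0, (rowSums(frac^2) - i * est^2) / (i - 1)))
    else rep(0, reps)
    new("PowerEstimate", q = as.numeric(q), m = as.integer(m),
        iterations = as.integer(i), p = as.numeric(p),
        presenceProb = presenceProbability(q, m), power = pow, mae = mae,
        ciMargin = mean(1.96 * sdRow), method = "monte_carlo",
        reps = as.integer(reps), seed = as.integer(seed))
}

#' Smallest subsample size reaching a target detection power
#'
#' Finds the smallest `m` whose exact [detectionPower()] reaches
#' `targetPower`, by doubling followed by bisection (power is
#' non-decreasing in `m`).
#'
#' @param q true taxon proportion (> 0, else the target is unreachable).
#' @param i number of iterations.
#' @param p presence threshold.
#' @param targetPower required power, strictly between 0 and 1.
#' @return integer `m`.
#' @examples
#' recommendSubsampleSize(q = 0.001, i = 50, p = 0.8, targetPower = 0.99)
#' @export
recommendSubsampleSize <- function(q, i, p = 0.8, targetPower = 0.99) {
    stopifnot(targetPower > 0, targetPower < 1, i >= 1)
    if (q <= 0)
        stop("target power unreachable: a taxon at proportion 0 is never sampled")
    powAt <- function(m) detectionPower(q, m, i, p)@power
    hi <- 1L
    while (powAt(hi) < targetPower) {
        if (hi >= 2^30)
            stop("no subsample size below 2^30 reaches the target power")
        hi <- hi * 2L
    }
    lo <- max(1L, hi %/% 2L)
    while (lo < hi) {          # invariant: powAt(hi) >= target > powAt(lo - 1)
        mid <- (lo + hi) %/% 2L
        if (powAt(mid) >= targetPower) hi <- mid else lo <- mid + 1L
    }
    hi
}

#' Exact power/error table over a design grid
#'
#' One row per `(q, m)` cell with the exact presence probability, detection
#' power and mean absolute estimation error — the planning table behind the
#' recommended defaults (i = 50, p = 0.8).
#'
#' @param qs taxon proportions (non-empty).
#' @param ms subsample sizes (non-empty).
#' @param i number of iterations.
#' @param p presence threshold.
#' @param path optional CSV output path.
#' @return data.frame with columns `q`, `m`, `i`, `p`, `presence_prob`,
#'   `power`, `mae`.
#' @export
designTable <- function(qs, ms, i, p = 0.8, path = NULL) {
    stopifnot(length(qs) >= 1, length(ms) >= 1)
    grid <- expand.grid(q = qs, m = ms, KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(k) {
        q <- grid$q[k]; m <- grid$m[k]
        pe <- detectionPower(q, m, i, p)
        data.frame(q = q, m = m, i = i, p = p,
                   presence_prob = pe@presenceProb, power = pe@power,
                   mae = estimationError(q, m, i))
    })
    out <- do.call(rbind, rows)
    if (!is.null(path)) write.csv(out, path, row.names = FALSE)
    out
}
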