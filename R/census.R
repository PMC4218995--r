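#' @include AllClasses.R seqio.R taxonomy.R aligner.R
NULL

#' Run one census iteration
#'
#' Draws `m` reads (with the iteration's derived seed), computes best hits,
#' resolves subjects to taxids, projects them to the slim depth, and tallies
#' per-slim-node counts together with the unaligned and unresolved
#' categories. The conservation invariant `sum(counts) + unaligned +
#' unresolved == m` always holds.
#'
#' @param index a [ReadIndex] over the read pool.
#' @param reference named character vector of subject sequences.
#' @param tree a [TaxonomyTree].
#' @param map a [SubjectTaxMap].
#' @param config a [CensusConfig].
#' @param iterationIndex 1-based iteration number; the subsample seed is a
#'   stable hash of `(config seed, iterationIndex)`, so results do not
#'   depend on execution order.
#' @param params an [AlignerParams].
#' @param backend alignment backend (see [alignBestHit()]).
#' @return an [IterationProfile].
#' @export
runIteration <- function(index, reference, tree, map, config, iterationIndex,
                         params = alignerParams(),
                         backend = c("naive", "external")) {
    backend <- match.arg(backend)
    stopifnot(is(config, "CensusConfig"))
    reads <- pickReads(index, config@m, iterationSeed(config@seed, iterationIndex))
    hits <- alignBestHit(reads, reference, params, backend)
    taxid <- resolveSubject(map, hits$subject_id)
    unresolved <- sum(is.na(taxid))
    slim <- rep(NA_integer_, length(taxid))
    resolved <- !is.na(taxid)
    slim[resolved] <- slimProject(tree, taxid[resolved], config@depth)
    hits$taxid <- taxid
    hits$slim_taxid <- slim
    hits$iteration <- rep(iterationIndex, nrow(hits))
    counts <- table(slim[resolved])
    counts <- setNames(as.integer(counts), names(counts))
    new("IterationProfile", iteration = as.integer(iterationIndex),
        counts = counts, unaligned = as.integer(nrow(reads) - nrow(hits)),
        unresolved = as.integer(unresolved), m = config@m, hits = hits)
}

#' Aggregate iteration profiles into a census result
#'
#' Builds the per-taxon fraction matrix (zeros where a taxon was absent
#' from an iteration), applies the presence filter — a taxon is retained
#' iff it appears (count >= 1) in strictly more than `p * i` iterations —
#' and computes min/max/mean/median/sd and a normal-approximation interval
#' `mean +/- 1.96 * sd` (truncated to \[0, 1\]) over all `i` fractions.
#'
#' @param profiles list of [IterationProfile] sharing the same `m`.
#' @param p presence threshold in \[0, 1\].
#' @param tree optional [TaxonomyTree] supplying node names.
#' @param config optional [CensusConfig] echoed into the result.
#' @return a [CensusResult].
#' @export
aggregateProfiles <- function(profiles, p, tree = NULL, config = NULL) {
    i <- length(profiles)
    if (i < 1) stop("need at least one iteration profile")
    stopifnot(all(vapply(profiles, is, TRUE, "IterationProfile")))
    m <- unique(vapply(profiles, function(pr) pr@m, 1L))
    if (length(m) != 1) stop("profiles disagree on m: ", paste(m, collapse = ", "))
    if (is.null(config))
        config <- censusConfig(m = m, iterations = i, p = p, depth = 0L, seed = 0L)
    taxa <- sort(unique(as.integer(unlist(lapply(profiles,
                                                 function(pr) names(pr@counts))))))
    fr <- matrix(0, nrow = i, ncol = length(taxa),
                 dimnames = list(NULL, as.character(taxa)))
    for (j in seq_len(i)) {
        ct <- profiles[[j]]@counts
        if (length(ct)) fr[j, names(ct)] <- ct / m
    }
    presence <- as.integer(colSums(fr > 0))
    mu <- colMeans(fr)
    sdv <- apply(fr, 2, sd)
    if (i == 1) sdv[] <- 0
    tb <- data.frame(
        taxid = taxa,
        name = if (!is.null(tree)) taxName(tree, taxa) else as.character(taxa),
        presence_count = presence,
        mean = unname(mu),
        median = unname(apply(fr, 2, median)),
        min = unname(apply(fr, 2, min)),
        max = unname(apply(fr, 2, max)),
        sd = unname(sdv),
        ci_low = unname(clamp01(mu - 1.96 * sdv)),
        ci_high = unname(clamp01(mu + 1.96 * sdv)),
        retained = passesPresenceThreshold(presence, p, i),
        stringsAsFactors = FALSE)
    if (!nrow(tb)) tb$retained <- logical(0)
    hits <- do.call(rbind, lapply(profiles, function(pr) pr@hits))
    if (is.null(hits)) hits <- emptyHitFrame()
    new("CensusResult", table = tb, fractions = fr, config = config,
        unalignedFractions = vapply(profiles, function(pr) pr@unaligned / pr@m, 1),
        unresolvedFractions = vapply(profiles, function(pr) pr@unresolved / pr@m, 1),
        hits = hits)
}

asReference <- function(x) {
    if (is.character(x) && length(x) == 1 && is.null(names(x))) loadReference(x)
    else x
}

#' Run a full census
#'
#' The end-to-end profiler: optionally depletes host reads first (the
#' census then runs on the unaligned remainder only), then runs
#' `config@iterations` subsampled iterations and aggregates them. The whole
#' run is deterministic for a fixed config and seed.
#'
#' @param config a [CensusConfig].
#' @param readsPath FASTA/FASTQ read pool (optionally gzip-compressed).
#' @param reference named character vector of subject sequences or FASTA path.
#' @param tree a [TaxonomyTree].
#' @param map a [SubjectTaxMap].
#' @param hostReference optional host genome (named character vector or
#'   FASTA path); required when `config@hostFilter` is `TRUE`.
#' @param params an [AlignerParams].
#' @param backend alignment backend.
#' @param outdir optional directory; when given, [writeReports()] writes
#'   the four report files there.
#' @return a [CensusResult] (host-removed fraction, when host filtering is
#'   on, is attached as attribute `hostRemovedFraction`).
#' @export
runCensus <- function(config, readsPath, reference, tree, map,
                      hostReference = NULL, params = alignerParams(),
                      backend = c("naive", "external"), outdir = NULL) {
    backend <- match.arg(backend)
    stopifnot(is(config, "CensusConfig"), is(tree, "TaxonomyTree"),
              is(map, "SubjectTaxMap"))
    reference <- asReference(reference)
    index <- indexReads(readsPath)
    hostRemoved <- NA_real_
    if (config@hostFilter) {
        if (is.null(hostReference))
            stop("host filtering enabled but no host reference supplied")
        pool <- readRecordsAt(index, seq_len(nrecords(index)))
        parts <- hostFilter(pool, asReference(hostReference), backend = backend)
        hostRemoved <- nrow(parts$host) / max(1L, nrow(pool))
        if (nrow(parts$unaligned) < config@m)
            stop("only ", nrow(parts$unaligned), " reads remain after host ",
                 "filtering; choose a subsample size m smaller than that")
        tmp <- tempfile(fileext = paste0(".", readFormat(index)))
        writeReads(parts$unaligned, tmp, readFormat(index))
        index <- indexReads(tmp, readFormat(index))
    }
    profiles <- lapply(seq_len(config@iterations), function(j)
        runIteration(index, reference, tree, map, config, j, params, backend))
    result <- aggregateProfiles(profiles, config@p, tree, config)
    attr(result, "hostRemovedFraction") <- hostRemoved
    if (!is.null(outdir))
        writeReports(result, outdir,
                     logExtra = c(paste0("reads_file: ", readsPath),
                                  if (!is.na(hostRemoved))
                                      paste0("host_removed_fraction: ",
                                             format(hostRemoved, digits = 6))))
    result
}

fmtPct <- function(x) round(100 * x, 4)

#' Write the four census report files
#'
#' Writes `log.txt` (every parameter, seed, package version, interval
#' construction, host-filter summary), `gi_centric_table.csv` (per
#' reference subject, sorted by subject id), `tax_centric_table.csv` (per
#' leaf-most resolved taxid — the "organism" view before slim projection),
#' and `taxslim_centric_table.csv` (per slim node with presence counts and
#' abundance statistics, including unaligned/unresolved rows), plus a
#' machine-readable `taxslim_centric_table.json`.
#'
#' @param result a [CensusResult].
#' @param outdir output directory (created if needed).
#' @param hits accumulated hit records; defaults to the ones carried by
#'   `result`.
#' @param tree optional [TaxonomyTree] for naming leaf taxids.
#' @param logExtra extra character lines appended to `log.txt`.
#' @return invisible character vector of the file paths written.
#' @export
writeReports <- function(result, outdir, hits = NULL, tree = NULL,
                         logExtra = character()) {
    stopifnot(is(result, "CensusResult"))
    if (is.null(hits)) hits <- result@hits
    if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
        stop("cannot create output directory ", outdir)
    cfg <- result@config
    paths <- file.path(outdir, c("log.txt", "gi_centric_table.csv",
                                 "tax_centric_table.csv",
                                 "taxslim_centric_table.csv",
                                 "taxslim_centric_table.json"))
    logLines <- c(
        paste0("microcensus version: ", as.character(packageVersion("microcensus"))),
        paste0("generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
        paste0("reads_per_iteration_m: ", cfg@m),
        paste0("iterations_i: ", cfg@iterations),
        paste0("presence_threshold_p: ", cfg@p),
        paste0("taxonomy_slim_depth: ", cfg@depth),
        paste0("seed: ", cfg@seed),
        paste0("host_filter_enabled: ", cfg@hostFilter),
        "retention_rule: presence_count > p * i (strict)",
        "confidence_interval: mean +/- 1.96 * sd over iteration fractions, truncated to [0,1]",
        "fastq_placeholder_quality: 'I' when input records carry no qualities",
        paste0("mean_unaligned_fraction: ",
               format(mean(result@unalignedFractions), digits = 6)),
        paste0("mean_unresolved_fraction: ",
               format(mean(result@unresolvedFractions), digits = 6)),
        logExtra)
    tryCatch(writeLines(logLines, paths[1]),
             error = function(e) stop("cannot write ", paths[1], ": ",
                                      conditionMessage(e)))

    writeCsv <- function(df, path) {
        tryCatch(write.csv(df, path, row.names = FALSE, quote = TRUE),
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
    }

    if (nrow(hits)) {
        bySub <- split(hits, hits$subject_id)
        gi <- data.frame(
            subject_id = names(bySub),
            taxid = vapply(bySub, function(h) h$taxid[1], 1L),
            total_hits = vapply(bySub, nrow, 1L),
            iterations_hit = vapply(bySub, function(h)
                length(unique(h$iteration)), 1L),
            stringsAsFactors = FALSE)
        gi <- gi[order(gi$subject_id), , drop = FALSE]
    } else {
        gi <- data.frame(subject_id = character(0), taxid = integer(0),
                         total_hits = integer(0), iterations_hit = integer(0))
    }
    writeCsv(gi, paths[2])

    resolved <- hits[!is.na(hits$taxid), , drop = FALSE]
    if (nrow(resolved)) {
        byTax <- split(resolved, resolved$taxid)
        taxids <- as.integer(names(byTax))
        tax <- data.frame(
            taxid = taxids,
            name = if (!is.null(tree)) taxName(tree, taxids)
                   else as.character(taxids),
            total_hits = vapply(byTax, nrow, 1L),
            iterations_hit = vapply(byTax, function(h)
                length(unique(h$iteration)), 1L),
            stringsAsFactors = FALSE)
        tax <- tax[order(tax$taxid), , drop = FALSE]
    } else {
        tax <- data.frame(taxid = integer(0), name = character(0),
                          total_hits = integer(0), iterations_hit = integer(0))
    }
    writeCsv(tax, paths[3])

    tb <- result@table
    slim <- data.frame(
        slim_taxid = as.character(tb$taxid), name = tb$name,
        presence_count = tb$presence_count,
        mean_pct = fmtPct(tb$mean), median_pct = fmtPct(tb$median),
        min_pct = fmtPct(tb$min), max_pct = fmtPct(tb$max),
        sd_pct = fmtPct(tb$sd),
        ci_low_pct = fmtPct(tb$ci_low), ci_high_pct = fmtPct(tb$ci_high),
        retained = tb$retained, stringsAsFactors = FALSE)
    extraRow <- function(label, fracs) {
        i <- length(fracs)
        mu <- mean(fracs); sdv <- if (i > 1) sd(fracs) else 0
        data.frame(slim_taxid = label, name = label,
                   presence_count = sum(fracs > 0),
                   mean_pct = fmtPct(mu), median_pct = fmtPct(median(fracs)),
                   min_pct = fmtPct(min(fracs)), max_pct = fmtPct(max(fracs)),
                   sd_pct = fmtPct(sdv),
                   ci_low_pct = fmtPct(clamp01(mu - 1.96 * sdv)),
                   ci_high_pct = fmtPct(clamp01(mu + 1.96 * sdv)),
                   retained = NA, stringsAsFactors = FALSE)
    }
    if (length(result@unalignedFractions))
        slim <- rbind(slim, extraRow("unaligned", result@unalignedFractions),
                      extraRow("unresolved", result@unresolvedFractions))
    writeCsv(slim, paths[4])
    jsonlite::write_json(slim, paths[5], dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(paths)
}
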