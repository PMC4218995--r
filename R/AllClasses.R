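#' @include utils.R
NULL

#' ReadIndex: byte-offset index over a FASTA/FASTQ file
#'
#' Realizes the profiler's "array of pointers" over the read pool: one byte
#' offset and span per record, so subsamples can be materialized by seeking
#' rather than re-parsing the whole file. Created by [indexReads()].
#'
#' @slot path input path as given (possibly `.gz`).
#' @slot streamPath path actually indexed (a decompressed copy for gzip input).
#' @slot format `"fasta"` or `"fastq"`.
#' @slot offsets 0-based byte offset of each record start, strictly increasing.
#' @slot spans byte length of each record.
#' @slot nrecords total number of reads `n` in the pool.
#' @aliases ReadIndex
#' @exportClass ReadIndex
setClass("ReadIndex",
    representation(path = "character", streamPath = "character",
                   format = "character", offsets = "numeric",
                   spans = "numeric", nrecords = "integer"))

setValidity("ReadIndex", function(object) {
    msg <- character()
    if (!object@format %in% c("fasta", "fastq"))
        msg <- c(msg, "format must be 'fasta' or 'fastq'")
    if (length(object@offsets) != object@nrecords)
        msg <- c(msg, "length(offsets) must equal nrecords")
    if (length(object@offsets) != length(object@spans))
        msg <- c(msg, "offsets and spans must have equal length")
    if (object@nrecords > 1 && any(diff(object@offsets) <= 0))
        msg <- c(msg, "offsets must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' TaxonomyTree: rooted taxonomy with parent links, ranks, names and depths
#'
#' Loaded from NCBI taxdump-dialect `nodes.dmp`/`names.dmp` files by
#' [loadTaxonomy()], or built by [makeReferenceFixture()]. Depth counts
#' parent hops from the root (root depth 0); slim projection at depth `d`
#' reports every deeper node through its ancestor at exactly `d`.
#'
#' @slot nodes data.frame with columns `taxid`, `parent`, `rank`, `name`,
#'   `depth`, one row per node, sorted by `taxid`.
#' @slot rootTaxid taxid of the root (its own parent).
#' @aliases TaxonomyTree
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
    representation(nodes = "data.frame", rootTaxid = "integer"))

setValidity("TaxonomyTree", function(object) {
    nd <- object@nodes
    msg <- character()
    need <- c("taxid", "parent", "rank", "name", "depth")
    if (!all(need %in% names(nd)))
        return(paste("nodes must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(nd$taxid)) msg <- c(msg, "duplicated taxids")
    if (!object@rootTaxid %in% nd$taxid) msg <- c(msg, "root taxid absent")
    r <- nd[nd$taxid == object@rootTaxid, ]
    if (nrow(r) == 1 && (r$parent != r$taxid || r$depth != 0))
        msg <- c(msg, "root must be its own parent at depth 0")
    orphan <- setdiff(nd$parent, nd$taxid)
    if (length(orphan))
        msg <- c(msg, paste("orphan parents:", paste(orphan, collapse = ",")))
    nonroot <- nd$taxid != object@rootTaxid
    pd <- nd$depth[match(nd$parent, nd$taxid)]
    bad <- nonroot & (nd$depth != pd + 1)
    if (any(bad, na.rm = TRUE))
        msg <- c(msg, paste("depth inconsistent for taxids:",
                            paste(nd$taxid[which(bad)], collapse = ",")))
    if (length(msg)) msg else TRUE
})

#' SubjectTaxMap: reference subject id to taxid resolution table
#'
#' Local, offline stand-in for a live taxonomy-id lookup service: a plain
#' two-column mapping (accession2taxid dialect) loaded by [loadSubjectMap()].
#' Subjects absent from the map resolve to the `NA` sentinel and are counted
#' by the census as "unresolved".
#'
#' @slot map named integer vector, names are subject ids, values taxids.
#' @aliases SubjectTaxMap
#' @exportClass SubjectTaxMap
setClass("SubjectTaxMap", representation(map = "integer"))

setValidity("SubjectTaxMap", function(object) {
    if (length(object@map) && is.null(names(object@map)))
        "map must be named by subject id"
    else if (anyDuplicated(names(object@map)))
        "duplicated subject ids in map"
    else TRUE
})

#' AlignerParams: best-hit alignment thresholds
#'
#' Defaults mirror a stringent megablast-style search: minimum 90 percent
#' identity, e-value cutoff 1e-6, and a single target per read (best hit
#' only; `maxTargets` is fixed at 1).
#'
#' @slot minIdentity minimum percent identity in \[0, 100\].
#' @slot evalueCutoff maximum e-value for a reported hit.
#' @slot maxTargets fixed at 1L.
#' @aliases AlignerParams
#' @exportClass AlignerParams
setClass("AlignerParams",
    representation(minIdentity = "numeric", evalueCutoff = "numeric",
                   maxTargets = "integer"))

setValidity("AlignerParams", function(object) {
    msg <- character()
    if (object@minIdentity < 0 || object@minIdentity > 100)
        msg <- c(msg, "minIdentity must be in [0, 100]")
    if (object@evalueCutoff < 0) msg <- c(msg, "evalueCutoff must be >= 0")
    if (object@maxTargets != 1L) msg <- c(msg, "maxTargets is fixed at 1 (best hit only)")
    if (length(msg)) msg else TRUE
})

#' CensusConfig: parameters of one census run
#'
#' @slot m reads drawn per iteration (subsample size).
#' @slot iterations number of iterations `i`.
#' @slot p presence threshold in \[0, 1\]; a clade is retained iff it appears
#'   in strictly more than `p * i` iterations (default 0.8).
#' @slot depth taxonomy slim depth (default 3).
#' @slot seed master seed; each iteration derives its own subsample seed.
#' @slot hostFilter whether to deplete host reads before the census.
#' @aliases CensusConfig
#' @exportClass CensusConfig
setClass("CensusConfig",
    representation(m = "integer", iterations = "integer", p = "numeric",
                   depth = "integer", seed = "integer", hostFilter = "logical"))

setValidity("CensusConfig", function(object) {
    msg <- character()
    if (object@m < 1L) msg <- c(msg, "m must be >= 1")
    if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
    if (object@depth < 0L) msg <- c(msg, "depth must be >= 0")
    if (length(msg)) msg else TRUE
})

#' IterationProfile: tallies of one census iteration
#'
#' Counts of sampled reads per slim taxon plus the unaligned (no qualifying
#' hit) and unresolved (hit subject not in the taxid map) categories.
#' Conservation invariant: the three parts always sum to `m`.
#'
#' @slot iteration 1-based iteration index.
#' @slot counts named integer vector, names are slim taxids.
#' @slot unaligned reads with no qualifying best hit.
#' @slot unresolved reads whose hit subject has no taxid mapping.
#' @slot m subsample size of this iteration.
#' @slot hits the per-read best-hit table (kept for the report writer).
#' @aliases IterationProfile
#' @exportClass IterationProfile
setClass("IterationProfile",
    representation(iteration = "integer", counts = "integer",
                   unaligned = "integer", unresolved = "integer",
                   m = "integer", hits = "data.frame"))

setValidity("IterationProfile", function(object) {
    if (sum(object@counts) + object@unaligned + object@unresolved != object@m)
        "conservation violated: counts + unaligned + unresolved != m"
    else if (any(object@counts < 0) || object@unaligned < 0 || object@unresolved < 0)
        "negative tallies"
    else TRUE
})

#' CensusResult: aggregated abundance estimates of a census run
#'
#' One row per slim taxon with presence counts, abundance statistics over
#' the per-iteration fractions (zeros included for iterations where the
#' taxon was absent), a normal-approximation interval, and the retention
#' flag. Access with [censusTable()], [retainedTaxa()],
#' [unalignedMeanFraction()], [unresolvedMeanFraction()].
#'
#' @slot table data.frame: `taxid`, `name`, `presence_count`, `mean`,
#'   `median`, `min`, `max`, `sd`, `ci_low`, `ci_high`, `retained`
#'   (fractions on \[0, 1\]).
#' @slot fractions iterations x taxa matrix of per-iteration fractions.
#' @slot config the [CensusConfig] that produced the result.
#' @slot unalignedFractions per-iteration unaligned fraction.
#' @slot unresolvedFractions per-iteration unresolved fraction.
#' @slot hits accumulated best-hit records across iterations.
#' @aliases CensusResult
#' @exportClass CensusResult
setClass("CensusResult",
    representation(table = "data.frame", fractions = "matrix",
                   config = "CensusConfig", unalignedFractions = "numeric",
                   unresolvedFractions = "numeric", hits = "data.frame"))

setValidity("CensusResult", function(object) {
    tb <- object@table
    msg <- character()
    if (nrow(tb)) {
        if (any(tb$min > tb$median + 1e-12) || any(tb$median > tb$max + 1e-12))
            msg <- c(msg, "min <= median <= max violated")
        if (any(tb$min > tb$mean + 1e-12) || any(tb$mean > tb$max + 1e-12))
            msg <- c(msg, "min <= mean <= max violated")
        if (any(tb$ci_low > tb$mean + 1e-12) || any(tb$mean > tb$ci_high + 1e-12))
            msg <- c(msg, "ci_low <= mean <= ci_high violated")
    }
    if (length(msg)) msg else TRUE
})

#' PowerEstimate: detection power and estimation error at one design point
#'
#' Produced by [detectionPower()] (exact binomial tail) or [simulateDesign()]
#' (Monte Carlo under the perfect-alignment model). `presenceProb` is the
#' per-iteration presence probability 1 - (1 - q)^m.
#'
#' @slot q true taxon proportion.
#' @slot m subsample size.
#' @slot iterations number of iterations.
#' @slot p presence threshold.
#' @slot presenceProb per-iteration presence probability.
#' @slot power probability the taxon passes the retention filter.
#' @slot mae mean absolute error of the pooled abundance estimator
#'   (`NA` when not computed).
#' @slot ciMargin expected half-width of the implemented interval
#'   (Monte Carlo only; `NA` otherwise).
#' @slot method `"exact"` or `"monte_carlo"`.
#' @slot reps Monte Carlo replicates (`NA` for exact).
#' @slot seed Monte Carlo seed (`NA` for exact).
#' @aliases PowerEstimate
#' @exportClass PowerEstimate
setClass("PowerEstimate",
    representation(q = "numeric", m = "integer", iterations = "integer",
                   p = "numeric", presenceProb = "numeric", power = "numeric",
                   mae = "numeric", ciMargin = "numeric", method = "character",
                   reps = "integer", seed = "integer"))

setValidity("PowerEstimate", function(object) {
    msg <- character()
    if (object@power < 0 || object@power > 1) msg <- c(msg, "power outside [0, 1]")
    if (object@presenceProb < 0 || object@presenceProb > 1)
        msg <- c(msg, "presenceProb outside [0, 1]")
    if (!object@method %in% c("exact", "monte_carlo"))
        msg <- c(msg, "method must be 'exact' or 'monte_carlo'")
    if (object@method == "monte_carlo" && (is.na(object@reps) || is.na(object@seed)))
        msg <- c(msg, "monte_carlo estimates must carry reps and seed")
    if (length(msg)) msg else TRUE
})

#' CommunitySpec: design of a synthetic metagenomic community
#'
#' Describes a mixture of reference organisms at fixed proportions from
#' which labelled, error-bearing short reads are simulated. The default,
#' built by [communitySpec()], is a six-organism community at proportions
#' 0.50/0.20/0.20/0.07/0.02/0.01 with 50 bp reads and 1 percent
#' substitution error.
#'
#' @slot components data.frame: `subject_id`, `taxid`, `proportion`
#'   (proportions sum to 1).
#' @slot nReads number of reads to simulate.
#' @slot readLength read length in bases (>= 20).
#' @slot errorRate per-base substitution probability in \[0, 1).
#' @slot seed simulation seed.
#' @aliases CommunitySpec
#' @exportClass CommunitySpec
setClass("CommunitySpec",
    representation(components = "data.frame", nReads = "integer",
                   readLength = "integer", errorRate = "numeric",
                   seed = "integer"))

setValidity("CommunitySpec", function(object) {
    cp <- object@components
    msg <- character()
    if (!all(c("subject_id", "taxid", "proportion") %in% names(cp)))
        return("components needs columns subject_id, taxid, proportion")
    if (abs(sum(cp$proportion) - 1) > 1e-9)
        msg <- c(msg, "proportions must sum to 1")
    if (any(cp$proportion <= 0)) msg <- c(msg, "proportions must be positive")
    if (anyDuplicated(cp$subject_id)) msg <- c(msg, "subject ids must be unique")
    if (object@readLength < 20L) msg <- c(msg, "readLength must be >= 20")
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "errorRate must be in [0, 1)")
    if (object@nReads < 1L) msg <- c(msg, "nReads must be >= 1")
    if (length(msg)) msg else TRUE
})
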