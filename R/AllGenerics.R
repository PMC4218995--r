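#' @include AllClasses.R
NULL

#' Number of reads in a ReadIndex
#' @param x a [ReadIndex].
#' @return integer record count.
#' @export
setGeneric("nrecords", function(x) standardGeneric("nrecords"))

#' @rdname nrecords
#' @export
setMethod("nrecords", "ReadIndex", function(x) x@nrecords)

#' File format of a ReadIndex
#' @param x a [ReadIndex].
#' @return `"fasta"` or `"fastq"`.
#' @export
setGeneric("readFormat", function(x) standardGeneric("readFormat"))

#' @rdname readFormat
#' @export
setMethod("readFormat", "ReadIndex", function(x) x@format)

#' Taxon ids of a taxonomy tree
#' @param x a [TaxonomyTree].
#' @return integer vector of all taxids.
#' @export
setGeneric("taxIds", function(x) standardGeneric("taxIds"))

#' @rdname taxIds
#' @export
setMethod("taxIds", "TaxonomyTree", function(x) x@nodes$taxid)

#' Root taxid of a taxonomy tree
#' @param x a [TaxonomyTree].
#' @return integer root taxid.
#' @export
setGeneric("rootTaxid", function(x) standardGeneric("rootTaxid"))

#' @rdname rootTaxid
#' @export
setMethod("rootTaxid", "TaxonomyTree", function(x) x@rootTaxid)

#' Node depth(s) in a taxonomy tree
#'
#' Depth is the number of parent hops from the root (root depth 0).
#' @param x a [TaxonomyTree].
#' @param taxid integer vector of taxids.
#' @return integer vector of depths.
#' @export
setGeneric("taxDepth", function(x, taxid) standardGeneric("taxDepth"))

#' @rdname taxDepth
#' @export
setMethod("taxDepth", "TaxonomyTree", function(x, taxid) {
    idx <- match(taxid, x@nodes$taxid)
    if (anyNA(idx))
        stop("unknown taxid(s): ", paste(taxid[is.na(idx)], collapse = ", "))
    x@nodes$depth[idx]
})

#' Scientific name(s) of taxonomy nodes
#' @param x a [TaxonomyTree].
#' @param taxid integer vector of taxids.
#' @return character vector of names.
#' @export
setGeneric("taxName", function(x, taxid) standardGeneric("taxName"))

#' @rdname taxName
#' @export
setMethod("taxName", "TaxonomyTree", function(x, taxid) {
    idx <- match(taxid, x@nodes$taxid)
    if (anyNA(idx))
        stop("unknown taxid(s): ", paste(taxid[is.na(idx)], collapse = ", "))
    x@nodes$name[idx]
})

#' Per-taxon abundance table of a census
#' @param x a [CensusResult].
#' @return data.frame with per-slim-taxon presence counts, abundance
#'   statistics (fractions on \[0, 1\]) and the retention flag.
#' @export
setGeneric("censusTable", function(x) standardGeneric("censusTable"))

#' @rdname censusTable
#' @export
setMethod("censusTable", "CensusResult", function(x) x@table)

#' Taxa passing the presence filter
#' @param x a [CensusResult].
#' @return integer vector of retained slim taxids.
#' @export
setGeneric("retainedTaxa", function(x) standardGeneric("retainedTaxa"))

#' @rdname retainedTaxa
#' @export
setMethod("retainedTaxa", "CensusResult", function(x)
    x@table$taxid[x@table$retained])

#' Mean unaligned fraction across iterations
#' @param x a [CensusResult].
#' @return numeric scalar.
#' @export
setGeneric("unalignedMeanFraction",
           function(x) standardGeneric("unalignedMeanFraction"))

#' @rdname unalignedMeanFraction
#' @export
setMethod("unalignedMeanFraction", "CensusResult",
          function(x) mean(x@unalignedFractions))

#' Mean unresolved fraction across iterations
#' @param x a [CensusResult].
#' @return numeric scalar.
#' @export
setGeneric("unresolvedMeanFraction",
           function(x) standardGeneric("unresolvedMeanFraction"))

#' @rdname unresolvedMeanFraction
#' @export
setMethod("unresolvedMeanFraction", "CensusResult",
          function(x) mean(x@unresolvedFractions))

setMethod("show", "ReadIndex", function(object) {
    cat("ReadIndex over", object@path, "\n  format:", object@format,
        " reads:", object@nrecords, "\n")
})

setMethod("show", "TaxonomyTree", function(object) {
    cat("TaxonomyTree with", nrow(object@nodes), "nodes\n  root:",
        object@rootTaxid, " max depth:", max(object@nodes$depth), "\n")
})

setMethod("show", "CensusConfig", function(object) {
    cat("CensusConfig: m =", object@m, " iterations =", object@iterations,
        " p =", object@p, " depth =", object@depth, " seed =", object@seed,
        " hostFilter =", object@hostFilter, "\n")
})

setMethod("show", "CensusResult", function(object) {
    cfg <- object@config
    cat("CensusResult (m =", cfg@m, ", i =", cfg@iterations, ", p =", cfg@p,
        ", depth =", cfg@depth, ")\n")
    tb <- object@table
    cat(" ", nrow(tb), "slim taxa observed,", sum(tb$retained), "retained\n")
    cat("  mean unaligned fraction:",
        format(mean(object@unalignedFractions), digits = 4),
        " unresolved:", format(mean(object@unresolvedFractions), digits = 4), "\n")
    if (nrow(tb)) {
        shown <- tb[order(-tb$mean), , drop = FALSE]
        print(head(shown[, c("taxid", "name", "presence_count", "mean",
                             "sd", "retained")], 10), row.names = FALSE)
    }
})

setMethod("show", "PowerEstimate", function(object) {
    cat("PowerEstimate (", object@method, "): q =", object@q, " m =", object@m,
        " i =", object@iterations, " p =", object@p, "\n  presenceProb =",
        format(object@presenceProb, digits = 6), " power =",
        format(object@power, digits = 6), "\n")
    if (!is.na(object@mae))
        cat("  mae =", format(object@mae, digits = 4), "\n")
    if (!is.na(object@ciMargin))
        cat("  expected CI margin =", format(object@ciMargin, digits = 4), "\n")
})

setMethod("show", "CommunitySpec", function(object) {
    cat("CommunitySpec:", nrow(object@components), "components,",
        object@nReads, "reads of", object@readLength, "bp, error rate",
        object@errorRate, "\n")
})

#' Construct a CensusConfig
#'
#' @param m reads per iteration (subsample size).
#' @param iterations number of iterations `i` (at least 50 is a sensible
#'   default together with `p = 0.8`).
#' @param p presence threshold; retention requires presence in strictly more
#'   than `p * iterations` iterations.
#' @param depth taxonomy slim depth.
#' @param seed master seed for the subsample draws.
#' @param hostFilter deplete host reads before profiling.
#' @return a [CensusConfig].
#' @examples
#' censusConfig(m = 250, iterations = 50)
#' @export
censusConfig <- function(m, iterations, p = 0.8, depth = 3L, seed = 1L,
                         hostFilter = FALSE) {
    new("CensusConfig", m = as.integer(m), iterations = as.integer(iterations),
        p = as.numeric(p), depth = as.integer(depth), seed = as.integer(seed),
        hostFilter = isTRUE(hostFilter))
}

#' Construct AlignerParams
#'
#' @param minIdentity minimum percent identity (default 90).
#' @param evalueCutoff e-value cutoff (default 1e-6).
#' @return an [AlignerParams].
#' @export
alignerParams <- function(minIdentity = 90, evalueCutoff = 1e-6) {
    new("AlignerParams", minIdentity = as.numeric(minIdentity),
        evalueCutoff = as.numeric(evalueCutoff), maxTargets = 1L)
}
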