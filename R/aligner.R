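#' @include AllClasses.R seqio.R
NULL

emptyHitFrame <- function() {
    data.frame(read_id = character(0), subject_id = character(0),
               percent_identity = numeric(0), aligned_length = integer(0),
               mismatches = integer(0), evalue = numeric(0),
               bitscore = numeric(0), strand = integer(0),
               subject_start = integer(0), stringsAsFactors = FALSE)
}

# Monotone e-value surrogate for the naive backend: decreasing in score,
# adequate only for thresholding (never comparable to an external tool's
# e-values).
naiveEvalue <- function(bitscore, totalBases) totalBases * 2^(-bitscore)

naiveScanHits <- function(reads, reference, maxMismatch) {
    ord <- order(names(reference))          # lex-smallest subject wins ties
    subjects <- unname(reference[ord])
    subjectIds <- names(reference)[ord]
    res <- cpp_best_hits(toupper(reads$sequence), subjects,
                         as.integer(maxMismatch))
    hit <- res$subject > 0L
    len <- nchar(reads$sequence)
    mm <- res$mismatches
    matches <- len - mm
    bits <- 2 * matches - 3 * mm
    data.frame(read_id = reads$read_id[hit],
               subject_id = subjectIds[res$subject[hit]],
               percent_identity = 100 * matches[hit] / len[hit],
               aligned_length = len[hit],
               mismatches = mm[hit],
               evalue = naiveEvalue(bits[hit], sum(nchar(reference))),
               bitscore = bits[hit],
               strand = res$strand[hit],
               subject_start = res$position[hit],
               stringsAsFactors = FALSE)
}

#' Naive best hit for a single read
#'
#' Exhaustive ungapped scan: the placement of the full read (both strands)
#' with the minimum number of mismatches over all subjects and offsets.
#' Ties are broken toward the lexicographically smallest subject id, then
#' the forward strand, then the leftmost offset. The reported e-value is a
#' monotone surrogate of the score, adequate only for thresholding.
#'
#' @param read a one-row record frame (see [pickReads()]).
#' @param reference named character vector of subject sequences.
#' @param params an [AlignerParams].
#' @return a 0- or 1-row hit frame (columns `read_id`, `subject_id`,
#'   `percent_identity`, `aligned_length`, `mismatches`, `evalue`,
#'   `bitscore`, `strand`, `subject_start`).
#' @export
naiveBestHit <- function(read, reference, params = alignerParams()) {
    stopifnot(nrow(read) == 1)
    alignBestHit(read, reference, params, backend = "naive")
}

bestHitExternal <- function(reads, reference, params) {
    blastn <- Sys.which("blastn")
    makedb <- Sys.which("makeblastdb")
    if (blastn == "" || makedb == "")
        stop("external alignment backend unavailable (blastn/makeblastdb ",
             "not on PATH); use backend = 'naive'")
    wd <- tempfile("blastdb")
    dir.create(wd)
    on.exit(unlink(wd, recursive = TRUE))
    refPath <- file.path(wd, "reference.fasta")
    writeReads(data.frame(read_id = names(reference),
                          sequence = unname(reference),
                          stringsAsFactors = FALSE), refPath, "fasta")
    qryPath <- file.path(wd, "query.fasta")
    writeReads(reads[, c("read_id", "sequence")], qryPath, "fasta")
    dbPath <- file.path(wd, "refdb")
    outPath <- file.path(wd, "hits.tsv")
    st <- system2(makedb, c("-in", refPath, "-dbtype", "nucl", "-out", dbPath),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0) stop("makeblastdb failed with status ", st)
    st <- system2(blastn, c("-task", "megablast",
                            "-evalue", format(params@evalueCutoff),
                            "-max_target_seqs", "1",
                            "-best_hit_score_edge", "0.05",
                            "-best_hit_overhang", "0.05",
                            "-window_size", "0",
                            "-perc_identity", format(params@minIdentity),
                            "-query", qryPath, "-db", dbPath,
                            "-outfmt", "6", "-out", outPath),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0) stop("blastn failed with status ", st)
    if (file.size(outPath) == 0) return(emptyHitFrame())
    tb <- read.table(outPath, sep = "\t", stringsAsFactors = FALSE,
                     col.names = c("qseqid", "sseqid", "pident", "length",
                                   "mismatch", "gapopen", "qstart", "qend",
                                   "sstart", "send", "evalue", "bitscore"))
    # one best HSP per read: bitscore desc, identity desc, subject id asc
    tb <- tb[order(tb$qseqid, -tb$bitscore, -tb$pident, tb$sseqid, tb$sstart), ]
    tb <- tb[!duplicated(tb$qseqid), ]
    data.frame(read_id = tb$qseqid, subject_id = tb$sseqid,
               percent_identity = tb$pident, aligned_length = tb$length,
               mismatches = tb$mismatch, evalue = tb$evalue,
               bitscore = tb$bitscore,
               strand = ifelse(tb$send >= tb$sstart, 1L, -1L),
               subject_start = pmin(tb$sstart, tb$send),
               stringsAsFactors = FALSE)
}

#' Best-hit alignment of reads against a reference collection
#'
#' The pluggable best-hit contract of the profiler: at most one hit per
#' read, reported only if identity and e-value pass the thresholds in
#' `params`; everything else is a no-hit. The `"naive"` backend is the
#' built-in hermetic exhaustive ungapped scanner ([naiveBestHit()]); the
#' `"external"` backend shells out to a megablast-compatible search on PATH
#' and parses its 12-column tabular output.
#'
#' @param reads record frame (see [pickReads()]).
#' @param reference named character vector of subject sequences, or a FASTA
#'   path (loaded with [loadReference()]).
#' @param params an [AlignerParams].
#' @param backend `"naive"` or `"external"`.
#' @return hit frame with one row per read that has a qualifying hit.
#' @examples
#' ref <- c(refA = paste(rep("ACGT", 30), collapse = ""))
#' reads <- data.frame(read_id = "r1", sequence = substr(ref[[1]], 11, 60))
#' alignBestHit(reads, ref)$percent_identity
#' @export
alignBestHit <- function(reads, reference, params = alignerParams(),
                         backend = c("naive", "external")) {
    backend <- match.arg(backend)
    if (is.character(reference) && length(reference) == 1 &&
        is.null(names(reference)) && file.exists(reference))
        reference <- loadReference(reference)
    if (!length(reference)) stop("reference collection is empty")
    if (!nrow(reads)) return(emptyHitFrame())
    hits <- if (backend == "naive") {
        maxmm <- floor((1 - params@minIdentity / 100) *
                       nchar(reads$sequence) + 1e-9)
        naiveScanHits(reads, reference, maxmm)
    } else {
        bestHitExternal(reads, reference, params)
    }
    hits[hits$percent_identity >= params@minIdentity - 1e-9 &
         hits$evalue <= params@evalueCutoff, , drop = FALSE]
}

#' Partition reads into host-derived and remainder
#'
#' Host-depletion pre-filter for samples dominated by one organism (e.g.
#' clinical samples and the human genome): a read is host if some alignment
#' to the host reference covers at least `minMatchFraction` of its length
#' with at most `maxMismatchFraction` mismatches relative to the aligned
#' length. The naive backend aligns the full read ungapped (coverage 1), so
#' there the rule reduces to a mismatch budget of
#' `floor(maxMismatchFraction * read length)`.
#'
#' @param reads record frame.
#' @param hostReference named character vector or FASTA path; an empty host
#'   reference returns all reads as unaligned, with a warning.
#' @param minMatchFraction minimum aligned fraction of the read (default 0.8).
#' @param maxMismatchFraction maximum mismatch fraction of the aligned
#'   length (default 0.1).
#' @param backend `"naive"` or `"external"`.
#' @return list with record frames `host` and `unaligned`; the partition is
#'   exhaustive, disjoint, and order-preserving.
#' @export
hostFilter <- function(reads, hostReference, minMatchFraction = 0.8,
                       maxMismatchFraction = 0.1,
                       backend = c("naive", "external")) {
    backend <- match.arg(backend)
    stopifnot(minMatchFraction > 0, minMatchFraction <= 1,
              maxMismatchFraction > 0, maxMismatchFraction <= 1)
    if (is.character(hostReference) && length(hostReference) == 1 &&
        is.null(names(hostReference)) && file.exists(hostReference))
        hostReference <- loadReference(hostReference)
    if (!length(hostReference) || !nrow(reads)) {
        if (!length(hostReference))
            warning("empty host reference; returning all reads as unaligned")
        return(list(host = reads[integer(0), , drop = FALSE], unaligned = reads))
    }
    if (backend == "naive") {
        maxmm <- floor(maxMismatchFraction * nchar(reads$sequence) + 1e-9)
        hits <- naiveScanHits(reads, hostReference, maxmm)
        isHost <- reads$read_id %in% hits$read_id
    } else {
        # permissive search, then apply the coverage/mismatch rule per HSP
        loose <- alignerParams(minIdentity = 100 * (1 - maxMismatchFraction),
                               evalueCutoff = 10)
        hits <- bestHitExternal(reads, hostReference, loose)
        len <- nchar(reads$sequence)[match(hits$read_id, reads$read_id)]
        ok <- hits$aligned_length >= minMatchFraction * len &
              hits$mismatches <= maxMismatchFraction * hits$aligned_length
        isHost <- reads$read_id %in% hits$read_id[ok]
    }
    list(host = reads[isHost, , drop = FALSE],
         unaligned = reads[!isHost, , drop = FALSE])
}
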