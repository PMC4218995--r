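#' @include AllClasses.R
NULL

# Split a file into lines while tracking the 0-based byte offset of each
# line start. Assumes LF or CRLF endings; the trailing CR is stripped from
# line content but counted in the offsets.
scanLines <- function(path) {
    size <- file.size(path)
    if (size == 0)
        return(list(lines = character(0), starts = numeric(0), size = 0))
    raw <- readBin(path, "raw", n = size)
    nl <- which(raw == as.raw(10L))
    starts <- c(0, nl)
    if (length(starts) && starts[length(starts)] >= size)
        starts <- starts[-length(starts)]
    lines <- strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1]]
    lines <- sub("\r$", "", lines)
    list(lines = lines, starts = starts, size = size)
}

emptyReadFrame <- function() {
    data.frame(read_id = character(0), sequence = character(0),
               qualities = character(0), source_label = character(0),
               stringsAsFactors = FALSE)
}

guessFormat <- function(path) {
    base <- sub("\\.gz$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    if (ext %in% c("fq", "fastq")) return("fastq")
    if (ext %in% c("fa", "fasta", "fna", "ffn")) return("fasta")
    # fall back to the first byte
    con <- if (isGzPath(path)) gzfile(path, "r") else file(path, "r")
    on.exit(close(con))
    first <- readLines(con, n = 1)
    if (!length(first)) return("fasta")
    if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Index the reads of a FASTA/FASTQ file by byte offset
#'
#' Builds the pointer array over the read pool that the random picker
#' samples from: one byte offset per record, so a subsample of `m` reads is
#' materialized by `m` seeks instead of a full parse. Gzip input (suffix
#' `.gz`) is decompressed once to a temporary file and indexed there.
#'
#' FASTQ must be strict 4-line records; multi-line (wrapped) FASTA is
#' accepted. An empty file yields a valid index with zero records.
#'
#' @param path FASTA or FASTQ file, optionally gzip-compressed.
#' @param format `"auto"` (default, by suffix then content), `"fasta"` or
#'   `"fastq"`.
#' @return a [ReadIndex].
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), fq)
#' nrecords(indexReads(fq))
#' @export
indexReads <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("reads file not found: ", path)
    streamPath <- path
    if (isGzPath(path)) {
        streamPath <- tempfile(fileext = paste0(".", tools::file_ext(
            sub("\\.gz$", "", path, ignore.case = TRUE))))
        inc <- gzfile(path, "rb")
        out <- file(streamPath, "wb")
        while (length(chunk <- readBin(inc, "raw", n = 1048576L)) > 0)
            writeBin(chunk, out)
        close(inc); close(out)
    }
    if (format == "auto") format <- guessFormat(path)
    sc <- scanLines(streamPath)
    lines <- sc$lines
    starts <- sc$starts
    n <- length(lines)
    if (n == 0) {
        return(new("ReadIndex", path = path, streamPath = streamPath,
                   format = format, offsets = numeric(0), spans = numeric(0),
                   nrecords = 0L))
    }
    if (format == "fastq") {
        if (n %% 4 != 0)
            stop("malformed FASTQ (line count not a multiple of 4) near byte offset ",
                 starts[4 * (n %/% 4) + 1])
        h <- seq(1, n, by = 4)
        bad <- which(!startsWith(lines[h], "@"))
        if (length(bad))
            stop("malformed FASTQ header at byte offset ", starts[h[bad[1]]])
        badp <- which(!startsWith(lines[h + 2], "+"))
        if (length(badp))
            stop("malformed FASTQ separator at byte offset ", starts[h[badp[1]] + 2])
        badq <- which(nchar(lines[h + 1]) != nchar(lines[h + 3]))
        if (length(badq))
            stop("FASTQ quality length mismatch at byte offset ", starts[h[badq[1]]])
        offsets <- starts[h]
    } else {
        heads <- which(startsWith(lines, ">"))
        if (!length(heads) || heads[1] != 1)
            stop("malformed FASTA: no '>' header at byte offset 0")
        offsets <- starts[heads]
    }
    spans <- c(diff(offsets), sc$size - offsets[length(offsets)])
    new("ReadIndex", path = path, streamPath = streamPath, format = format,
        offsets = offsets, spans = spans, nrecords = length(offsets))
}

splitDefline <- function(def) {
    id <- sub("\\s.*$", "", def)
    label <- ifelse(grepl("\\s", def), sub("^\\S+\\s+", "", def), NA_character_)
    list(id = id, label = label)
}

#' Read records at given positions of an indexed file
#'
#' @param index a [ReadIndex].
#' @param positions 1-based record positions (duplicates allowed, order kept).
#' @return data.frame with columns `read_id`, `sequence`, `qualities`
#'   (`NA` for FASTA), `source_label` (definition line after the first
#'   whitespace, `NA` if none).
#' @export
readRecordsAt <- function(index, positions) {
    stopifnot(is(index, "ReadIndex"))
    positions <- as.integer(positions)
    if (!length(positions)) return(emptyReadFrame())
    if (any(positions < 1L | positions > index@nrecords))
        stop("record positions out of range 1..", index@nrecords)
    upos <- sort(unique(positions))
    con <- file(index@streamPath, "rb")
    on.exit(close(con))
    ids <- seqs <- quals <- labs <- character(length(upos))
    for (k in seq_along(upos)) {
        jj <- upos[k]
        seek(con, where = index@offsets[jj], origin = "start")
        txt <- rawToChar(readBin(con, "raw", n = index@spans[jj]))
        ln <- sub("\r$", "", strsplit(txt, "\n", fixed = TRUE)[[1]])
        if (index@format == "fastq") {
            d <- splitDefline(sub("^@", "", ln[1]))
            seqs[k] <- ln[2]; quals[k] <- ln[4]
        } else {
            d <- splitDefline(sub("^>", "", ln[1]))
            body <- ln[-1]
            seqs[k] <- paste(body[nzchar(body)], collapse = "")
            quals[k] <- NA_character_
        }
        ids[k] <- d$id; labs[k] <- d$label
    }
    sel <- match(positions, upos)
    data.frame(read_id = ids[sel], sequence = seqs[sel],
               qualities = quals[sel], source_label = labs[sel],
               stringsAsFactors = FALSE)
}

#' Randomly pick reads from an indexed pool
#'
#' The seed-controlled random read picker: draws `m` read positions
#' uniformly over the offset index with R's Mersenne-Twister generator and
#' materializes the records. Identical `(index, m, seed, replacement)`
#' reproduce the identical ordered selection.
#'
#' @param index a [ReadIndex].
#' @param m number of reads to draw (`m = 0` gives an empty frame).
#' @param seed integer seed.
#' @param replacement draw with replacement (default `FALSE`; without
#'   replacement `m` must not exceed the pool size).
#' @return data.frame of records as in [readRecordsAt()], in draw order.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "TTTT", "+", "IIII"), fq)
#' pickReads(indexReads(fq), m = 1, seed = 7)$read_id
#' @export
pickReads <- function(index, m, seed, replacement = FALSE) {
    stopifnot(is(index, "ReadIndex"))
    m <- as.integer(m)
    if (is.na(m) || m < 0L) stop("m must be a non-negative integer")
    if (!replacement && m > index@nrecords)
        stop("cannot draw ", m, " reads without replacement from a pool of ",
             index@nrecords)
    if (m == 0L) return(emptyReadFrame())
    pos <- withSeed(seed, sample.int(index@nrecords, m, replace = replacement))
    readRecordsAt(index, pos)
}

#' Write read records as FASTA or FASTQ
#'
#' Output FASTA is unwrapped (one sequence line per record). Writing FASTQ
#' from quality-less records synthesizes a constant placeholder quality
#' (`'I'`, Phred 40); writing FASTA drops qualities.
#'
#' @param records data.frame as produced by [readRecordsAt()] /
#'   [pickReads()] (columns `read_id`, `sequence`, optional `qualities`,
#'   optional `source_label`).
#' @param path output path; suffix `.gz` writes gzip.
#' @param format `"fasta"` or `"fastq"`.
#' @return the path, invisibly.
#' @export
writeReads <- function(records, path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    n <- nrow(records)
    defs <- records$read_id
    if (!is.null(records$source_label)) {
        lab <- records$source_label
        defs <- ifelse(is.na(lab), defs, paste(defs, lab))
    }
    if (format == "fastq") {
        quals <- if (is.null(records$qualities)) rep(NA_character_, n)
                 else records$qualities
        miss <- is.na(quals)
        quals[miss] <- strrep("I", nchar(records$sequence[miss]))
        if (any(nchar(quals) != nchar(records$sequence)))
            stop("quality string length must equal sequence length")
        lines <- as.vector(rbind(paste0("@", defs), records$sequence,
                                 "+", quals))
    } else {
        lines <- as.vector(rbind(paste0(">", defs), records$sequence))
    }
    if (n == 0) lines <- character(0)
    con <- if (isGzPath(path)) gzfile(path, "wb") else file(path, "wb")
    tryCatch({
        writeLines(lines, con, sep = "\n")
    }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)),
       finally = close(con))
    invisible(path)
}

#' Load a reference FASTA as a named sequence vector
#'
#' Subject ids are taken as the definition line up to the first whitespace.
#'
#' @param path FASTA file (wrapped sequences accepted).
#' @return named character vector of upper-case sequences.
#' @export
loadReference <- function(path) {
    idx <- indexReads(path, "fasta")
    if (idx@nrecords == 0L) return(setNames(character(0), character(0)))
    recs <- readRecordsAt(idx, seq_len(idx@nrecords))
    if (anyDuplicated(recs$read_id))
        stop("duplicated subject ids in reference: ",
             paste(unique(recs$read_id[duplicated(recs$read_id)]), collapse = ", "))
    setNames(toupper(recs$sequence), recs$read_id)
}
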