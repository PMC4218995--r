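#' @include AllClasses.R seqio.R taxonomy.R aligner.R
NULL

BASES <- c("A", "C", "G", "T")

randomGenome <- function(len) paste(sample(BASES, len, replace = TRUE),
                                    collapse = "")

#' Construct a synthetic community specification
#'
#' The default emulates a six-organism mixture at proportions
#' 0.50/0.20/0.20/0.07/0.02/0.01 — two dominant organisms, mid-range ones,
#' and rare components down to 1 percent — sequenced as 50 bp single-end
#' reads with 1 percent uniform substitution error.
#'
#' @param components data.frame with `subject_id`, `taxid`, `proportion`
#'   (must sum to 1); defaults to the six-component design above with
#'   subject ids `genome01..genome06` and taxids 101..106.
#' @param nReads number of reads to simulate (default 50000).
#' @param readLength read length in bases (default 50).
#' @param errorRate per-base substitution probability (default 0.01).
#' @param seed simulation seed.
#' @return a [CommunitySpec].
#' @export
communitySpec <- function(components = NULL, nReads = 50000L,
                          readLength = 50L, errorRate = 0.01, seed = 1L) {
    if (is.null(components))
        components <- data.frame(
            subject_id = sprintf("genome%02d", 1:6),
            taxid = 100L + 1:6,
            proportion = c(0.50, 0.20, 0.20, 0.07, 0.02, 0.01),
            stringsAsFactors = FALSE)
    new("CommunitySpec", components = components, nReads = as.integer(nReads),
        readLength = as.integer(readLength), errorRate = as.numeric(errorRate),
        seed = as.integer(seed))
}

# Toy taxonomy over nTaxa leaf organisms: root -> domains -> phyla ->
# classes -> leaves (leaf depth 4), one class per leaf so that slim
# projection at depth 3 keeps the components distinct.
buildFixtureTaxonomy <- function(nTaxa, leafTaxids, leafNames) {
    classIds <- 30L + seq_len(nTaxa)
    phylumOf <- 20L + (seq_len(nTaxa) - 1L) %/% 3L
    phylumIds <- sort(unique(phylumOf))
    domainOf <- 2L + (phylumIds - 20L) %% 2L
    domainIds <- sort(unique(domainOf))
    taxid <- c(1L, domainIds, phylumIds, classIds, leafTaxids)
    parent <- c(1L, rep(1L, length(domainIds)),
                domainOf, phylumOf, classIds)
    rank <- c("no rank", rep("superkingdom", length(domainIds)),
              rep("phylum", length(phylumIds)),
              rep("class", nTaxa), rep("species", nTaxa))
    name <- c("root",
              paste("Synthetic domain", domainIds - 2L),
              paste("Synthetic phylum", phylumIds - 19L),
              paste("Synthetic class", seq_len(nTaxa)),
              leafNames)
    newTaxonomyTree(taxid, parent, rank, name)
}

writeDmp <- function(fields, path) {
    writeLines(paste0(apply(fields, 1, paste, collapse = "\t|\t"), "\t|"), path)
}

#' Generate a hermetic reference fixture
#'
#' Builds `nTaxa` uniform-random toy genomes, a four-level toy taxonomy
#' whose leaves are the genomes, and a complete subject-to-taxid map.
#' Random genomes make the perfect-alignment assumption of the design
#' calculator realizable: genomes are rejection-checked so that no
#' read-length window of one genome aligns to another at 90 percent
#' identity or better, hence truth labels are unambiguous.
#'
#' @param nTaxa number of organisms (>= 1, default 6).
#' @param genomeLength genome length in bases (default 1000).
#' @param readLength window length used by the cross-mapping rejection
#'   check (default 50).
#' @param seed generation seed.
#' @param outdir optional directory; when given, writes `reference.fasta`,
#'   `nodes.dmp`, `names.dmp` and `subject_map.tsv` there.
#' @return list with `reference` (named character vector), `tree`
#'   ([TaxonomyTree]), `map` ([SubjectTaxMap]), `components`
#'   (subject_id/taxid frame) and, if `outdir` was given, `paths`.
#' @examples
#' fix <- makeReferenceFixture(nTaxa = 2, genomeLength = 200, seed = 1)
#' taxDepth(fix$tree, fix$components$taxid)
#' @export
makeReferenceFixture <- function(nTaxa = 6L, genomeLength = 1000L,
                                 readLength = 50L, seed = 1L, outdir = NULL) {
    stopifnot(nTaxa >= 1, genomeLength >= readLength)
    subjectIds <- sprintf("genome%02d", seq_len(nTaxa))
    leafTaxids <- 100L + seq_len(nTaxa)
    genomes <- withSeed(seed, {
        g <- vapply(seq_len(nTaxa), function(k) randomGenome(genomeLength), "")
        maxmm <- floor(0.1 * readLength + 1e-9)
        for (attempt in seq_len(20L)) {
            clash <- FALSE
            if (nTaxa > 1) for (k in seq_len(nTaxa)) {
                starts <- seq(1, genomeLength - readLength + 1, by = readLength)
                windows <- substring(g[k], starts, starts + readLength - 1)
                others <- g[-k]
                res <- cpp_best_hits(windows, others,
                                     rep(maxmm, length(windows)))
                if (any(res$subject > 0L)) {
                    g[k] <- randomGenome(genomeLength)
                    clash <- TRUE
                }
            }
            if (!clash) break
            if (attempt == 20L)
                stop("could not generate cross-mapping-free genomes in 20 ",
                     "attempts; try a different seed")
        }
        g
    })
    names(genomes) <- subjectIds
    tree <- buildFixtureTaxonomy(nTaxa, leafTaxids,
                                 paste("Synthetic organism", seq_len(nTaxa)))
    map <- subjectTaxMap(subjectIds, leafTaxids)
    out <- list(reference = genomes, tree = tree, map = map,
                components = data.frame(subject_id = subjectIds,
                                        taxid = leafTaxids,
                                        stringsAsFactors = FALSE))
    if (!is.null(outdir)) {
        if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
        paths <- file.path(outdir, c("reference.fasta", "nodes.dmp",
                                     "names.dmp", "subject_map.tsv"))
        writeReads(data.frame(read_id = subjectIds, sequence = unname(genomes),
                              stringsAsFactors = FALSE), paths[1], "fasta")
        nd <- tree@nodes
        writeDmp(cbind(nd$taxid, nd$parent, nd$rank), paths[2])
        writeDmp(cbind(nd$taxid, nd$name, "", "scientific name"), paths[3])
        writeLines(paste(subjectIds, leafTaxids, sep = "\t"), paths[4])
        out$paths <- setNames(as.list(paths),
                              c("reference", "nodes", "names", "map"))
    }
    out
}

#' Simulate labelled error-bearing reads from a community
#'
#' Each read draws its source component with probability equal to its
#' proportion, a uniform start on the genome and a uniform strand, then
#' substitution errors i.i.d. at the spec's error rate. The definition line
#' carries the source subject id as a label after the read id, so truth is
#' recoverable downstream. Qualities are a constant Phred character
#' matching the error rate.
#'
#' @param spec a [CommunitySpec].
#' @param reference named character vector containing every subject in the
#'   spec (see [makeReferenceFixture()]).
#' @param path optional output path; written as strict 4-line FASTQ (or
#'   FASTA if `format = "fasta"`).
#' @param format output format when `path` is given.
#' @return record frame (invisibly when `path` is given) with the true
#'   source in `source_label`.
#' @export
simulateReads <- function(spec, reference, path = NULL,
                          format = c("fastq", "fasta")) {
    format <- match.arg(format)
    stopifnot(is(spec, "CommunitySpec"))
    cp <- spec@components
    miss <- setdiff(cp$subject_id, names(reference))
    if (length(miss))
        stop("reference lacks subjects: ", paste(miss, collapse = ", "))
    glen <- nchar(reference[cp$subject_id])
    rl <- spec@readLength
    if (any(glen < rl))
        stop("read length ", rl, " exceeds genome length of: ",
             paste(cp$subject_id[glen < rl], collapse = ", "))
    n <- spec@nReads
    recs <- withSeed(spec@seed, {
        comp <- sample.int(nrow(cp), n, replace = TRUE, prob = cp$proportion)
        starts <- floor(runif(n) * (glen[comp] - rl + 1)) + 1
        seqs <- substring(reference[cp$subject_id[comp]], starts,
                          starts + rl - 1)
        rev <- runif(n) < 0.5
        seqs[rev] <- cpp_revcomp(seqs[rev])
        if (spec@errorRate > 0) {
            chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE),
                                   use.names = FALSE), nrow = rl)
            hit <- matrix(runif(rl * n) < spec@errorRate, nrow = rl)
            nerr <- sum(hit)
            if (nerr) {
                # substitute with one of the three other bases, uniformly
                shift <- sample.int(3L, nerr, replace = TRUE)
                old <- match(chars[hit], BASES)
                old[is.na(old)] <- 1L
                chars[hit] <- BASES[((old - 1L + shift) %% 4L) + 1L]
            }
            seqs <- do.call(paste0, asplit(chars, 1))
        }
        phred <- if (spec@errorRate <= 0) 40L
                 else min(40L, as.integer(round(-10 * log10(spec@errorRate))))
        data.frame(read_id = sprintf("read%06d", seq_len(n)),
                   sequence = unname(seqs),
                   qualities = strrep(rawToChar(as.raw(33L + phred)), rl),
                   source_label = cp$subject_id[comp],
                   stringsAsFactors = FALSE)
    })
    if (!is.null(path)) {
        writeReads(recs, path, format)
        return(invisible(recs))
    }
    recs
}
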