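# Shared fixtures, built once per test run, and slow independent oracles.

.fixtureEnv <- new.env()

# Six-component community (0.50/0.20/0.20/0.07/0.02/0.01), toy genomes,
# toy taxonomy, 20k-read labelled pool at 1% substitution error.
sharedFixture <- function() {
    if (is.null(.fixtureEnv$fix)) {
        fix <- makeReferenceFixture(nTaxa = 6, genomeLength = 1000, seed = 101)
        spec <- communitySpec(nReads = 20000L, seed = 101L)
        fq <- tempfile(fileext = ".fastq")
        recs <- simulateReads(spec, fix$reference, path = fq)
        .fixtureEnv$fix <- fix
        .fixtureEnv$spec <- spec
        .fixtureEnv$readsPath <- fq
        .fixtureEnv$records <- recs
        .fixtureEnv$index <- indexReads(fq)
        # class-level (depth 3) taxid for each component
        .fixtureEnv$classOf <- setNames(
            slimProject(fix$tree, fix$components$taxid, 3),
            fix$components$subject_id)
    }
    .fixtureEnv
}

revcompR <- function(s) {
    vapply(s, function(x) paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x),
                                             "")[[1]]), collapse = ""), "",
           USE.NAMES = FALSE)
}

# Exhaustive ungapped best-placement oracle in plain R, replicating the
# documented tie-break (lex-smallest subject, forward strand, leftmost
# offset, strict improvement).
oracleBestHit <- function(seq, reference) {
    best <- list(mm = Inf, subject = NA_character_, pos = NA_integer_,
                 strand = NA_integer_)
    for (sid in sort(names(reference))) {
        ref <- strsplit(reference[[sid]], "")[[1]]
        L <- length(ref)
        for (str in c(1L, -1L)) {
            q <- strsplit(if (str == 1L) seq else revcompR(seq), "")[[1]]
            w <- length(q)
            if (L < w) next
            for (o in seq_len(L - w + 1)) {
                mm <- sum(q != ref[o:(o + w - 1)])
                if (mm < best$mm)
                    best <- list(mm = mm, subject = sid, pos = o, strand = str)
            }
        }
    }
    best
}

# Plant nsub substitutions at distinct positions of a sequence.
mutateSeq <- function(seq, nsub) {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(length(ch), nsub)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[sample(3, 1)]
    paste(ch, collapse = "")
}

writeTaxdump <- function(dir, nodes, names_) {
    # nodes: data.frame taxid/parent/rank; names_: taxid/name
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste0(nodes$taxid, "\t|\t", nodes$parent, "\t|\t",
                      nodes$rank, "\t|"), file.path(dir, "nodes.dmp"))
    writeLines(paste0(names_$taxid, "\t|\t", names_$name,
                      "\t|\t\t|\tscientific name\t|"),
               file.path(dir, "names.dmp"))
    dir
}

makeProfile <- function(iteration, counts, m, unresolved = 0L) {
    counts <- setNames(as.integer(counts), names(counts))
    new("IterationProfile", iteration = as.integer(iteration), counts = counts,
        unaligned = as.integer(m - sum(counts) - unresolved),
        unresolved = as.integer(unresolved), m = as.integer(m),
        hits = data.frame())
}

randomSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = "")
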