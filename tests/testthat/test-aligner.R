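test_that("exact containment, mismatches and misses behave as specified", {
    withr_seed <- function(s, e) {   # local seed without touching global state
        old <- .GlobalEnv$.Random.seed
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(s); e
    }
    ref <- withr_seed(11, c(refA = randomSeq(400), refB = randomSeq(400)))
    read50 <- substr(ref[["refA"]], 101, 150)
    hit <- alignBestHit(data.frame(read_id = "r1", sequence = read50), ref)
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$subject_id, "refA")
    expect_equal(hit$percent_identity, 100)
    expect_identical(hit$subject_start, 101L)

    # one substituted base out of 50 -> 98% identity
    mut <- read50
    substr(mut, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                   substr(read50, 25, 25))[1]
    hit2 <- alignBestHit(data.frame(read_id = "r2", sequence = mut), ref)
    expect_equal(hit2$percent_identity, 98)
    expect_identical(hit2$mismatches, 1L)

    # random read: no qualifying placement at >= 90% identity
    rnd <- withr_seed(99, randomSeq(50))
    expect_identical(nrow(alignBestHit(
        data.frame(read_id = "r3", sequence = rnd), ref)), 0L)

    expect_identical(nrow(alignBestHit(
        data.frame(read_id = character(0), sequence = character(0)), ref)),
        0L)                                                # empty read list
    expect_error(alignBestHit(data.frame(read_id = "r", sequence = "ACGT"),
                              character(0)), "empty")
})

test_that("reverse-complement placements are found (Biostrings as oracle)", {
    fix <- sharedFixture()
    ref <- fix$fix$reference
    frag <- substr(ref[["genome03"]], 201, 260)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    hit <- alignBestHit(data.frame(read_id = "rc", sequence = rc), ref)
    expect_identical(hit$subject_id, "genome03")
    expect_identical(hit$strand, -1L)
    expect_equal(hit$percent_identity, 100)
})

test_that("ties between equal-best subjects break lexicographically", {
    core <- randomSeq(60)
    ref <- c(zeta = paste0(randomSeq(40), core, randomSeq(40)),
             alpha = paste0(randomSeq(30), core, randomSeq(50)))
    hit <- naiveBestHit(data.frame(read_id = "t", sequence = core), ref)
    expect_identical(hit$subject_id, "alpha")
})

test_that("the scan kernel reproduces an exhaustive R oracle on mutated reads", {
    set.seed(77)
    ref <- c(gA = randomSeq(300), gB = randomSeq(300))
    n <- 60L
    reads <- data.frame(read_id = sprintf("m%03d", 1:n),
                        sequence = vapply(1:n, function(k) {
        src <- ref[[sample(2, 1)]]
        o <- sample(251, 1)
        mutateSeq(substr(src, o, o + 49), sample(0:4, 1))
    }, ""), stringsAsFactors = FALSE)
    hits <- alignBestHit(reads, ref, alignerParams(minIdentity = 90))
    expect_identical(nrow(hits), n)          # <= 4 mismatches always qualifies
    for (k in sample(n, 25)) {
        ob <- oracleBestHit(reads$sequence[k], ref)
        row <- hits[hits$read_id == reads$read_id[k], ]
        expect_identical(row$mismatches, as.integer(ob$mm))
        expect_identical(row$subject_id, ob$subject)
        expect_identical(row$subject_start, ob$pos)
        expect_identical(row$strand, ob$strand)
    }
})

test_that("best hits are unique per read and hit counts fall as minIdentity rises", {
    fix <- sharedFixture()
    reads <- pickReads(fix$index, 150, seed = 8)
    grid <- c(80, 90, 96, 100)
    counts <- vapply(grid, function(mi)
        nrow(alignBestHit(reads, fix$fix$reference,
                          alignerParams(minIdentity = mi))), 1L)
    expect_true(all(diff(counts) <= 0))
    hits <- alignBestHit(reads, fix$fix$reference)
    expect_identical(anyDuplicated(hits$read_id), 0L)
    expect_lte(nrow(hits), nrow(reads))
    expect_true(all(hits$percent_identity >= 90))
    expect_true(all(hits$aligned_length <= nchar(
        reads$sequence[match(hits$read_id, reads$read_id)])))
})

test_that("naive and external megablast backends pick the same subjects", {
    fix <- sharedFixture()
    reads <- pickReads(fix$index, 200, seed = 21)
    naive <- alignBestHit(reads, fix$fix$reference, backend = "naive")
    ext <- alignBestHit(reads, fix$fix$reference, backend = "external")
    shared <- intersect(naive$read_id, ext$read_id)
    expect_gt(length(shared), 150)
    agree <- naive$subject_id[match(shared, naive$read_id)] ==
             ext$subject_id[match(shared, ext$read_id)]
    expect_gte(mean(agree), 0.95)
})

test_that("host depletion partitions labelled reads by origin", {
    set.seed(31)
    host <- c(hostChr = randomSeq(2000))
    microbe <- c(bug = randomSeq(2000))
    mkReads <- function(ref, tag, n, id0) {
        data.frame(read_id = sprintf("%s%03d", id0, 1:n),
                   sequence = vapply(1:n, function(k) {
                       o <- sample(1951, 1)
                       mutateSeq(substr(ref, o, o + 49), rbinom(1, 50, 0.01))
                   }, ""),
                   source_label = tag, stringsAsFactors = FALSE)
    }
    reads <- rbind(mkReads(host[[1]], "host", 100, "h"),
                   mkReads(microbe[[1]], "microbe", 100, "m"))
    parts <- hostFilter(reads, host)
    expect_identical(nrow(parts$host) + nrow(parts$unaligned), 200L)
    expect_identical(intersect(parts$host$read_id, parts$unaligned$read_id),
                     character(0))
    expect_gte(sum(parts$host$source_label == "host"), 95)
    expect_gte(sum(parts$unaligned$source_label == "microbe"), 95)
    # order preserved within each part
    expect_identical(parts$unaligned$read_id,
                     reads$read_id[reads$read_id %in% parts$unaligned$read_id])

    expect_warning(p0 <- hostFilter(reads, character(0)), "empty host")
    expect_identical(nrow(p0$unaligned), 200L)

    one <- reads[1, ]
    expect_identical(hostFilter(one, host)$host$read_id, one$read_id)
    rnd <- data.frame(read_id = "x", sequence = randomSeq(50))
    expect_identical(nrow(hostFilter(rnd, host)$host), 0L)
})
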