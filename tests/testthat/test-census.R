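test_that("one iteration tallies hits, unaligned and unresolved conservatively", {
    fix <- sharedFixture()
    tr <- fix$fix$tree
    cfg <- censusConfig(m = 100, iterations = 1, seed = 5)

    # all reads exact copies of one subject -> a single count key of value m
    oneSpec <- communitySpec(
        components = data.frame(subject_id = "genome01", taxid = 101L,
                                proportion = 1.0),
        nReads = 300L, errorRate = 0, seed = 2L)
    fq <- tempfile(fileext = ".fastq")
    simulateReads(oneSpec, fix$fix$reference, path = fq)
    pr <- runIteration(indexReads(fq), fix$fix$reference, tr, fix$fix$map,
                       cfg, 1)
    expect_identical(pr@counts, setNames(100L, as.character(
        slimProject(tr, 101L, 3))))
    expect_identical(pr@unaligned, 0L)

    # random reads with no reference similarity -> all unaligned
    rnd <- data.frame(read_id = sprintf("x%03d", 1:120),
                      sequence = vapply(1:120, function(k) randomSeq(50), ""))
    fq2 <- tempfile(fileext = ".fastq")
    writeReads(rnd, fq2, "fastq")
    pr2 <- runIteration(indexReads(fq2), fix$fix$reference, tr, fix$fix$map,
                        cfg, 1)
    expect_identical(pr2@unaligned, 100L)
    expect_identical(length(pr2@counts), 0L)

    # hits on subjects missing from the map are counted as unresolved
    partialMap <- subjectTaxMap("genome02", 102L)
    pr3 <- runIteration(indexReads(fq), fix$fix$reference, tr, partialMap,
                        cfg, 1)
    expect_identical(pr3@unresolved, 100L)
    expect_identical(sum(pr3@counts) + pr3@unaligned + pr3@unresolved, 100L)
})

test_that("a 50/50 two-taxon subsample splits binomially", {
    fix2 <- makeReferenceFixture(nTaxa = 2, genomeLength = 1000, seed = 17)
    spec <- communitySpec(
        components = data.frame(subject_id = c("genome01", "genome02"),
                                taxid = c(101L, 102L),
                                proportion = c(0.5, 0.5)),
        nReads = 4000L, errorRate = 0, seed = 17L)
    fq <- tempfile(fileext = ".fastq")
    simulateReads(spec, fix2$reference, path = fq)
    cfg <- censusConfig(m = 200, iterations = 1, seed = 9)
    pr <- runIteration(indexReads(fq), fix2$reference, fix2$tree, fix2$map,
                       cfg, 1)
    expect_identical(sum(pr@counts), 200L)
    sd4 <- 4 * sqrt(200 * 0.25)
    for (ct in pr@counts) expect_lt(abs(ct - 100), sd4)
})

test_that("aggregation computes the documented statistics and strict boundary", {
    # fractions 0.4, 0.5, 0.45, 0.5, 0.4 at m = 20
    profiles <- lapply(seq_len(5), function(j)
        makeProfile(j, c("7" = c(8L, 10L, 9L, 10L, 8L)[j]), m = 20))
    res <- aggregateProfiles(profiles, p = 0.8)
    tb <- censusTable(res)
    expect_identical(tb$presence_count, 5L)
    expect_true(tb$retained)
    expect_equal(tb$mean, 0.45)
    expect_equal(tb$median, 0.45)
    expect_equal(tb$min, 0.4)
    expect_equal(tb$max, 0.5)
    expect_true(tb$ci_low <= tb$mean && tb$mean <= tb$ci_high)

    # present in 4 of 5: presence fraction 0.8 is NOT > 0.8 -> filtered
    profiles[[5]] <- makeProfile(5, integer(0), m = 20)
    res2 <- aggregateProfiles(profiles, p = 0.8)
    expect_identical(censusTable(res2)$presence_count, 4L)
    expect_false(censusTable(res2)$retained)

    expect_error(aggregateProfiles(list(), p = 0.8), "at least one")
    expect_error(aggregateProfiles(list(makeProfile(1, c("7" = 1L), 10),
                                        makeProfile(2, c("7" = 1L), 20)),
                                   p = 0.8), "disagree")
})

test_that("retention matches a brute-force recount on random count matrices", {
    set.seed(404)
    for (rep in 1:5) {
        i <- sample(5:12, 1)
        K <- sample(2:5, 1)
        m <- 50L
        counts <- matrix(rpois(i * K, lambda = sample(c(0.5, 2, 10), K,
                                                      replace = TRUE)),
                         nrow = i)
        counts[counts > 10] <- 10L
        p <- sample(c(0.5, 0.8), 1)
        profiles <- lapply(seq_len(i), function(j)
            makeProfile(j, setNames(as.integer(counts[j, ]),
                                    as.character(100 + seq_len(K))), m))
        res <- aggregateProfiles(profiles, p = p)
        tb <- censusTable(res)
        # independent recount straight from the matrix
        presence <- colSums(counts >= 1)
        expect_identical(tb$presence_count,
                         as.integer(presence[match(tb$taxid, 100 + seq_len(K))]))
        expect_identical(tb$retained, unname(presence > p * i)[
            match(tb$taxid, 100 + seq_len(K))])
        expect_equal(tb$mean, unname(colMeans(counts / m))[
            match(tb$taxid, 100 + seq_len(K))])
    }
})

test_that("raising the presence threshold never grows the retained set", {
    fix <- sharedFixture()
    cfg <- censusConfig(m = 150, iterations = 12, seed = 77)
    profiles <- lapply(1:12, function(j)
        runIteration(fix$index, fix$fix$reference, fix$fix$tree, fix$fix$map,
                     cfg, j))
    kept <- lapply(c(0.2, 0.5, 0.8, 0.95), function(p)
        retainedTaxa(aggregateProfiles(profiles, p, fix$fix$tree)))
    for (k in seq_len(length(kept) - 1))
        expect_true(all(kept[[k + 1]] %in% kept[[k]]))
    # conservation on every profile
    for (pr in profiles)
        expect_identical(sum(pr@counts) + pr@unaligned + pr@unresolved, pr@m)
})

test_that("a census is deterministic for a fixed seed", {
    fix <- sharedFixture()
    cfg <- censusConfig(m = 100, iterations = 5, seed = 123)
    r1 <- runCensus(cfg, fix$readsPath, fix$fix$reference, fix$fix$tree,
                    fix$fix$map)
    r2 <- runCensus(cfg, fix$readsPath, fix$fix$reference, fix$fix$tree,
                    fix$fix$map)
    expect_identical(serialize(censusTable(r1), NULL),
                     serialize(censusTable(r2), NULL))
    expect_identical(r1@fractions, r2@fractions)
    expect_identical(r1@hits, r2@hits)
})

test_that("host filtering runs the census on the non-host remainder", {
    fix2 <- makeReferenceFixture(nTaxa = 2, genomeLength = 1000, seed = 23)
    hostRef <- fix2$reference["genome01"]
    microbeRef <- fix2$reference["genome02"]
    spec <- communitySpec(
        components = data.frame(subject_id = c("genome01", "genome02"),
                                taxid = c(101L, 102L),
                                proportion = c(0.99, 0.01)),
        nReads = 3000L, seed = 23L)
    fq <- tempfile(fileext = ".fastq")
    recs <- simulateReads(spec, fix2$reference, path = fq)
    nMicrobe <- sum(recs$source_label == "genome02")
    expect_gt(nMicrobe, 10)
    cfg <- censusConfig(m = 10, iterations = 5, seed = 4, hostFilter = TRUE)
    res <- runCensus(cfg, fq, microbeRef, fix2$tree,
                     subjectTaxMap("genome02", 102L), hostReference = hostRef)
    expect_gt(attr(res, "hostRemovedFraction"), 0.9)
    tb <- censusTable(res)
    microbeClass <- slimProject(fix2$tree, 102L, 3)
    expect_true(microbeClass %in% tb$taxid)
    expect_gt(tb$mean[tb$taxid == microbeClass], 0.9)

    # too few remaining reads is a size error advising a smaller m
    cfgBig <- censusConfig(m = 2500, iterations = 2, seed = 4,
                           hostFilter = TRUE)
    expect_error(runCensus(cfgBig, fq, microbeRef, fix2$tree,
                           subjectTaxMap("genome02", 102L),
                           hostReference = hostRef), "smaller")

    # host filter off: identical result with or without host arguments
    cfgOff <- censusConfig(m = 50, iterations = 3, seed = 6)
    a <- runCensus(cfgOff, fq, fix2$reference, fix2$tree, fix2$map)
    b <- runCensus(cfgOff, fq, fix2$reference, fix2$tree, fix2$map,
                   hostReference = hostRef)
    expect_identical(censusTable(a), censusTable(b))

    expect_error(runCensus(censusConfig(10, 2, hostFilter = TRUE), fq,
                           microbeRef, fix2$tree,
                           subjectTaxMap("genome02", 102L)),
                 "no host reference")
})

test_that("the four report files are written, stable and complete", {
    fix <- sharedFixture()
    cfg <- censusConfig(m = 120, iterations = 6, seed = 55)
    out1 <- file.path(tempfile(), "rep1")
    out2 <- file.path(tempfile(), "rep2")
    r1 <- runCensus(cfg, fix$readsPath, fix$fix$reference, fix$fix$tree,
                    fix$fix$map, outdir = out1)
    r2 <- runCensus(cfg, fix$readsPath, fix$fix$reference, fix$fix$tree,
                    fix$fix$map, outdir = out2)
    files <- c("log.txt", "gi_centric_table.csv", "tax_centric_table.csv",
               "taxslim_centric_table.csv", "taxslim_centric_table.json")
    expect_true(all(file.exists(file.path(out1, files))))
    # identical seed -> byte-identical tables (log carries a timestamp)
    for (f in files[-1])
        expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                         readBin(file.path(out2, f), "raw", 1e6))
    gi <- read.csv(file.path(out1, "gi_centric_table.csv"))
    expect_identical(gi$subject_id, sort(gi$subject_id))
    expect_identical(sum(gi$total_hits), nrow(r1@hits))
    tax <- read.csv(file.path(out1, "tax_centric_table.csv"))
    expect_true(all(tax$taxid %in% fix$fix$components$taxid))  # leaf-most ids
    slim <- read.csv(file.path(out1, "taxslim_centric_table.csv"))
    expect_true(all(c("unaligned", "unresolved") %in% slim$slim_taxid))
    expect_identical(nrow(slim), nrow(censusTable(r1)) + 2L)
    js <- jsonlite::read_json(file.path(out1, "taxslim_centric_table.json"),
                              simplifyVector = TRUE)
    expect_identical(nrow(js), nrow(slim))
    # log echoes every config field
    lg <- readLines(file.path(out1, "log.txt"))
    for (key in c("reads_per_iteration_m: 120", "iterations_i: 6",
                  "presence_threshold_p: 0.8", "taxonomy_slim_depth: 3",
                  "seed: 55", "host_filter_enabled: FALSE"))
        expect_true(any(grepl(key, lg, fixed = TRUE)), info = key)

    # an empty census still yields all report files with headers only
    rnd <- data.frame(read_id = sprintf("x%02d", 1:30),
                      sequence = vapply(1:30, function(k) randomSeq(50), ""))
    fqr <- tempfile(fileext = ".fastq")
    writeReads(rnd, fqr, "fastq")
    out3 <- tempfile()
    r3 <- runCensus(censusConfig(m = 20, iterations = 3, seed = 1), fqr,
                    fix$fix$reference, fix$fix$tree, fix$fix$map,
                    outdir = out3)
    expect_identical(nrow(censusTable(r3)), 0L)
    gi3 <- read.csv(file.path(out3, "gi_centric_table.csv"))
    expect_identical(nrow(gi3), 0L)
})

test_that("across-iteration spread shrinks as the subsample grows", {
    fix <- sharedFixture()
    sdAt <- function(m) {
        cfg <- censusConfig(m = m, iterations = 10, seed = 303)
        res <- runCensus(cfg, fix$readsPath, fix$fix$reference, fix$fix$tree,
                         fix$fix$map)
        tb <- censusTable(res)
        mean(tb$sd[tb$mean > 0.05])   # spread on the common taxa
    }
    expect_gt(sdAt(50), sdAt(1000))
})
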