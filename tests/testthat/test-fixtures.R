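test_that("fixture generation is deterministic given the seed", {
    spec <- randomFixtureSpec(seed = 42)
    fx1 <- generateFixture(spec)
    fx2 <- generateFixture(spec)
    expect_identical(geneRecords(fx1$rTable), geneRecords(fx2$rTable))
    expect_identical(geneRecords(fx1$sTable), geneRecords(fx2$sTable))
    expect_identical(truthPairs(fx1$truth), truthPairs(fx2$truth))
    # written tables are byte-identical
    p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
    writeGeneTable(fx1$rTable, p1); writeGeneTable(fx2$rTable, p2)
    expect_identical(readLines(p1), readLines(p2))
    # a different seed moves the genes
    fx3 <- generateFixture(randomFixtureSpec(seed = 43))
    expect_false(identical(geneRecords(fx1$rTable),
                           geneRecords(fx3$rTable)))
})

test_that("planted pairs sit at their exact intended center distances", {
    pp <- plantedPairAt(genome = 1, scaffold = 2, rStart = 5000,
                        rLength = 1200, distance = 40000, sLength = 3000)
    expect_identical(pp$centerDistance, 40000)
    spec <- fixtureSpec(nGenomes = 2, plantedPairs = list(pp),
                        cutoff = 70000)
    fx <- generateFixture(spec)
    tp <- truthPairs(fx$truth)
    rrec <- geneRecords(fx$rTable)
    srec <- geneRecords(fx$sTable)
    d <- abs(centerTimesTwo(rrec[rrec$gene_id == tp$resistance_gene_id, ]) -
             centerTimesTwo(srec[srec$gene_id == tp$sm_gene_id, ])) / 2
    expect_identical(d, 40000)
})

test_that("truth derives from planted distances and the stated cutoff", {
    mk <- function(d, genome)
        plantedPairAt(genome = genome, scaffold = 1, rStart = 200000,
                      rLength = 2000, distance = d, sLength = 3000)
    spec <- fixtureSpec(nGenomes = 4, scaffoldLength = 1e6,
                        plantedPairs = list(mk(10000, 1), mk(40000, 2),
                                            mk(69999, 3)),
                        cutoff = 70000)
    fx <- generateFixture(spec)
    expect_identical(nrow(truthPairs(fx$truth)), 3L)
    hits <- mineHits(fx$rTable, fx$sTable, MinerConfig(70000))
    expect_setequal(hitKeys(hits), truthKeys(fx$truth))
    # the same layout judged at C = 30 kb keeps only the 10 kb pair
    spec30 <- fixtureSpec(nGenomes = 4, scaffoldLength = 1e6,
                          plantedPairs = list(mk(10000, 1), mk(40000, 2),
                                              mk(69999, 3)),
                          cutoff = 30000)
    fx30 <- generateFixture(spec30)
    expect_identical(truthPairs(fx30$truth)$center_distance, 10000)
    hits30 <- mineHits(fx30$rTable, fx30$sTable, MinerConfig(30000))
    expect_setequal(hitKeys(hits30), truthKeys(fx30$truth))
})

test_that("every planted pair passes, and every decoy fails exactly its predicate", {
    fx <- generateFixture(randomFixtureSpec(seed = 314,
        decoys = c(singleton_near = 2L, far_pair = 2L,
                   overlapping_pair = 2L, oversized_resistance = 2L),
        nGenomes = 14))
    truth <- fx$truth
    rrec <- geneRecords(fx$rTable)
    srec <- geneRecords(fx$sTable)
    C <- truth@cutoff; M <- truth@maxGeneLength
    counts <- table(rrec$organism)
    pairPredicates <- function(rid, sid) {
        r <- rrec[rrec$gene_id == rid, ]
        s <- srec[srec$gene_id == sid, ]
        c(sameLoc = r$organism == s$organism && r$scaffold == s$scaffold,
          within = abs(centerTimesTwo(r) - centerTimesTwo(s)) <= 2 * C,
          noOverlap = !genesOverlap(r, s),
          lengthOk = geneLength(r) <= M,
          twoCopies = counts[[r$organism]] >= 2L)
    }
    tp <- truthPairs(truth)
    for (i in seq_len(nrow(tp)))
        expect_true(all(pairPredicates(tp$resistance_gene_id[i],
                                       tp$sm_gene_id[i])))
    td <- truthDecoys(truth)
    failedPredicate <- c(singleton_near = "twoCopies",
                         far_pair = "within",
                         overlapping_pair = "noOverlap",
                         oversized_resistance = "lengthOk")
    for (i in seq_len(nrow(td))) {
        p <- pairPredicates(td$gene_id[i], td$partner_sm_id[i])
        bad <- failedPredicate[[td$class[i]]]
        expect_false(p[[bad]], label = paste(td$class[i], "violates", bad))
        expect_true(all(p[setdiff(names(p), bad)]),
                    label = paste(td$class[i], "passes the rest"))
    }
})

test_that("the miner recovers planted truth with precision = recall = 1", {
    for (seed in 101:120) {
        fx <- generateFixture(randomFixtureSpec(seed = seed))
        hits <- mineHits(fx$rTable, fx$sTable,
                         MinerConfig(cutoff = 70000, maxGeneLength = 20000))
        expect_setequal(hitKeys(hits), truthKeys(fx$truth))
    }
})

test_that("singleton_near decoys surface exactly under the waiver", {
    fx <- generateFixture(randomFixtureSpec(seed = 55,
        decoys = c(singleton_near = 3L, far_pair = 0L,
                   overlapping_pair = 0L, oversized_resistance = 0L),
        nGenomes = 10))
    cfg <- MinerConfig(cutoff = 70000, maxGeneLength = 20000)
    strict <- mineHits(fx$rTable, fx$sTable, cfg)
    waived <- mineHits(fx$rTable, fx$sTable,
                       initialize(cfg, singletonCheck = FALSE))
    sn <- truthDecoys(fx$truth)
    extra <- setdiff(hitKeys(waived), hitKeys(strict))
    expect_setequal(extra, paste(sn$organism, sn$gene_id, sn$partner_sm_id))
})

test_that("infeasible specs fail loudly instead of emitting inexact truth", {
    # oversized decoys are impossible without a finite length limit
    expect_error(fixtureSpec(nGenomes = 3,
        decoys = c(oversized_resistance = 1L), maxGeneLength = Inf),
        "finite maxGeneLength")
    # more decoy genomes than genomes exist
    spec <- randomFixtureSpec(seed = 1)
    spec@nGenomes <- 5
    expect_error(generateFixture(spec), "free|out of range")
    # genes that cannot fit on their scaffold
    expect_error(fixtureSpec(nGenomes = 2, scaffoldLength = 10000,
        plantedPairs = list(plantedPairAt(1, 1, rStart = 5000,
            rLength = 2000, distance = 40000, sLength = 2000))),
        "fit")
    # overlapping planted intervals are rejected at construction
    expect_error(plantedPairAt(1, 1, rStart = 100, rLength = 5000,
                               distance = 1000, sLength = 5000),
                 "too small")
})

test_that("fixture specs round-trip through the YAML config format", {
    spec <- randomFixtureSpec(seed = 9, nPlantedPairs = 3, nGenomes = 10)
    p <- withr::local_tempfile(fileext = ".yaml")
    writeFixtureSpec(spec, p)
    back <- readFixtureSpec(p)
    for (sl in slotNames("FixtureSpec"))
        if (sl != "plantedPairs")
            expect_equal(slot(back, sl), slot(spec, sl), label = sl)
    expect_equal(back@plantedPairs, spec@plantedPairs)
    # unlimited length limit survives the round trip
    spec2 <- fixtureSpec(nGenomes = 3, maxGeneLength = Inf, seed = 2)
    writeFixtureSpec(spec2, p)
    expect_identical(readFixtureSpec(p)@maxGeneLength, Inf)
})

test_that("the database-scale preset matches its advertised shape", {
    spec <- mycocosmScaleSpec(seed = 4)
    expect_identical(spec@nGenomes, 1800)
    # ~2300 resistance homologs and ~28000 SM genes once materialized:
    # counts are fixed by the spec's arithmetic, not by generation
    rUpper <- spec@nBackgroundResistance +
        sum(vapply(spec@plantedPairs,
                   function(p) 1 + p$nExtraCopies, numeric(1))) +
        sum(spec@decoys) + sum(spec@decoys[c("far_pair",
            "overlapping_pair", "oversized_resistance")])
    expect_gt(rUpper, 2200); expect_lt(rUpper, 2400)
    sTotal <- spec@nBackgroundSm + length(spec@plantedPairs) +
        sum(spec@decoys)
    expect_gt(sTotal, 27500); expect_lt(sTotal, 28500)
})
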