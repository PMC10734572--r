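# Layout used across these tests: one genome, resistance gene r1 on the
# same scaffold as SM gene s1, plus a second resistance copy r2 on another
# scaffold so the two-copy rule is satisfied.
twoCopyTables <- function(rStart = 10000, rStop = 11000,
                          sStart = 70000, sStop = 72000,
                          sScaffold = "scaf1") {
    list(r = rTab(rec("org1", "r1", "scaf1", rStart, rStop),
                  rec("org1", "r2", "scaf2", 500000, 501000)),
         s = sTab(rec("org1", "s1", sScaffold, sStart, sStop)))
}

test_that("a qualifying pair yields one hit with the exact center distance", {
    tb <- twoCopyTables()
    hits <- mineHits(tb$r, tb$s, MinerConfig(cutoff = 70000))
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$center_distance, abs(10500 - 71000))  # 60500
    expect_identical(hits$resistance_gene_id, "r1")
    expect_identical(hits$sm_gene_id, "s1")
})

test_that("each predicate alone excludes a would-be hit", {
    cfg <- MinerConfig(cutoff = 70000)
    # different scaffolds
    tb <- twoCopyTables(sScaffold = "scaf3")
    expect_identical(nrow(mineHits(tb$r, tb$s, cfg)), 0L)
    # overlap, even at a huge cutoff
    tb <- twoCopyTables(rStart = 100, rStop = 200, sStart = 150,
                        sStop = 1150)
    expect_identical(nrow(mineHits(tb$r, tb$s, MinerConfig(1e9))), 0L)
    # distance one past the cutoff
    tb <- twoCopyTables()
    expect_identical(nrow(mineHits(tb$r, tb$s, MinerConfig(60499))), 0L)
    expect_identical(nrow(mineHits(tb$r, tb$s, MinerConfig(60500))), 1L)
    # singleton genome (drop the second copy)
    r1 <- rTab(rec("org1", "r1", "scaf1", 10000, 11000))
    expect_identical(nrow(mineHits(r1, tb$s, cfg)), 0L)
    expect_identical(nrow(mineHits(r1, tb$s,
        MinerConfig(70000, singletonCheck = FALSE))), 1L)
})

test_that("the resistance length limit M is a closed bound", {
    tb <- twoCopyTables(rStart = 10000, rStop = 60000)   # 50001 bp gene
    s <- sTab(rec("org1", "s1", "scaf1", 200000, 202000))
    expect_identical(nrow(mineHits(tb$r, s,
        MinerConfig(cutoff = 2e5, maxGeneLength = 50000))), 0L)
    expect_identical(nrow(mineHits(tb$r, s,
        MinerConfig(cutoff = 2e5, maxGeneLength = 50001))), 1L)
    expect_identical(nrow(mineHits(tb$r, s, MinerConfig(cutoff = 2e5))), 1L)
})

test_that("role checking rejects swapped tables", {
    tb <- twoCopyTables()
    expect_error(mineHits(tb$s, tb$r, MinerConfig(70000)), "role")
    expect_error(bruteForceMine(tb$s, tb$r, MinerConfig(70000)), "role")
    expect_error(eliminateSingletons(tb$s), "resistance")
})

test_that("singleton elimination keeps exactly multi-copy genomes, in order", {
    r <- rTab(rec("orgA", "a1", "s1", 100, 200),
              rec("orgB", "b1", "s1", 100, 200),
              rec("orgA", "a2", "s2", 300, 400),
              rec("orgC", "c1", "s1", 100, 200),
              rec("orgC", "c2", "s1", 900, 950),
              rec("orgC", "c3", "s2", 100, 200))
    kept <- geneRecords(eliminateSingletons(r))
    expect_identical(kept$gene_id, c("a1", "a2", "c1", "c2", "c3"))
    # every genome a singleton -> empty output is legal
    solo <- rTab(rec("orgA", "a1", "s1", 100, 200),
                 rec("orgB", "b1", "s1", 100, 200))
    expect_identical(length(eliminateSingletons(solo)), 0L)
})

test_that("singletons are counted before the length filter", {
    # org1 has two copies but one is oversized: the genome still passes
    # the two-copy rule, and the normal-length copy can hit
    r <- rTab(rec("org1", "short", "scaf1", 10000, 11000),
              rec("org1", "long", "scaf2", 1000, 80000))
    s <- sTab(rec("org1", "s1", "scaf1", 40000, 42000))
    hits <- mineHits(r, s, MinerConfig(cutoff = 70000,
                                       maxGeneLength = 20000))
    expect_identical(hits$resistance_gene_id, "short")
})

test_that("empty S and self-identical R/S records give no hits", {
    tb <- twoCopyTables()
    sEmpty <- GeneTable(rec("x", "y", "z", 1, 2)[0, ], role = "sm_core")
    expect_identical(nrow(mineHits(tb$r, sEmpty, MinerConfig(70000))), 0L)
    expect_identical(nrow(bruteForceMine(tb$r, sEmpty,
                                         MinerConfig(70000))), 0L)
    # the same physical gene in both tables can never self-pair
    shared <- rec("org1", "dual", "scaf1", 1000, 2000)
    r <- rTab(shared, rec("org1", "r2", "scaf2", 5000, 6000))
    s <- sTab(shared)
    expect_identical(nrow(mineHits(r, s, MinerConfig(1e6))), 0L)
})

test_that("a resistance gene near two backbone genes yields two hits", {
    r <- rTab(rec("org1", "res", "scaf1", 100000, 102000),
              rec("org1", "res2", "scaf2", 5000, 6000))
    s <- sTab(rec("org1", "nrpsA", "scaf1", 60000, 68000),
              rec("org1", "nrpsB", "scaf1", 120000, 131000))
    hits <- mineHits(r, s, MinerConfig(70000))
    expect_identical(nrow(hits), 2L)
    expect_identical(sort(hits$sm_gene_id), c("nrpsA", "nrpsB"))
})

test_that("indexed engine and literal all-pairs oracle agree on random fixtures", {
    for (seed in 1:10) {
        fx <- generateFixture(randomFixtureSpec(seed = seed))
        cfg <- MinerConfig(cutoff = 70000, maxGeneLength = 20000)
        expect_identical(mineHits(fx$rTable, fx$sTable, cfg),
                         bruteForceMine(fx$rTable, fx$sTable, cfg))
        # also at a perturbed cutoff and with the waiver on
        cfg2 <- MinerConfig(cutoff = 31000, singletonCheck = FALSE)
        expect_identical(mineHits(fx$rTable, fx$sTable, cfg2),
                         bruteForceMine(fx$rTable, fx$sTable, cfg2))
    }
})

test_that("hits survive an independent post-hoc predicate audit", {
    fx <- generateFixture(randomFixtureSpec(seed = 99))
    cfg <- MinerConfig(cutoff = 70000, maxGeneLength = 20000)
    hits <- mineHits(fx$rTable, fx$sTable, cfg)
    expect_gt(nrow(hits), 0L)
    expect_true(auditHitPredicates(hits, cfg, fx$rTable))
})

test_that("hit sets are nested in the cutoff and in the length limit", {
    fx <- generateFixture(randomFixtureSpec(seed = 5, nPlantedPairs = 6,
                                            nGenomes = 14))
    hitsAt <- function(C, M = Inf)
        hitKeys(mineHits(fx$rTable, fx$sTable,
                         MinerConfig(cutoff = C, maxGeneLength = M)))
    prev <- character()
    for (C in seq(10000, 100000, by = 10000)) {
        cur <- hitsAt(C)
        expect_true(all(prev %in% cur))
        prev <- cur
    }
    expect_true(all(hitsAt(70000, 5000) %in% hitsAt(70000, 20000)))
    expect_true(all(hitsAt(70000, 20000) %in% hitsAt(70000, Inf)))
})

test_that("waiving the singleton check only ever adds hits", {
    fx <- generateFixture(randomFixtureSpec(seed = 17,
        decoys = c(singleton_near = 3L, far_pair = 1L,
                   overlapping_pair = 1L, oversized_resistance = 1L)))
    cfg <- MinerConfig(cutoff = 70000, maxGeneLength = 20000)
    strict <- mineHits(fx$rTable, fx$sTable, cfg)
    waived <- mineHits(fx$rTable, fx$sTable,
                       initialize(cfg, singletonCheck = FALSE))
    expect_true(all(hitKeys(strict) %in% hitKeys(waived)))
    expect_gt(nrow(waived), nrow(strict))
})

test_that("mining is deterministic: identical inputs, identical output", {
    fx <- generateFixture(randomFixtureSpec(seed = 2))
    cfg <- MinerConfig(cutoff = 70000)
    expect_identical(mineHits(fx$rTable, fx$sTable, cfg),
                     mineHits(fx$rTable, fx$sTable, cfg))
})

test_that("homolog table holds every R record of every hit genome, as a set", {
    r <- rTab(rec("orgA", "a1", "s1", 10000, 11000),
              rec("orgA", "a2", "s2", 5000, 6000),
              rec("orgA", "a3", "s3", 7000, 8000),
              rec("orgB", "b1", "s1", 10000, 11000),
              rec("orgB", "b2", "s2", 1000, 2000))
    s <- sTab(rec("orgA", "sm1", "s1", 40000, 42000))
    hits <- mineHits(r, s, MinerConfig(70000))
    hom <- collectHomologs(hits, r)
    expect_s4_class(hom, "GeneTable")
    expect_identical(geneRecords(hom)$gene_id, c("a2", "a3", "a1"))
    expect_identical(tableSource(hom), "homologs")

    # five hits in one organism give the same table as one hit
    s5 <- sTab(rec("orgA", "sm1", "s1", 40000, 42000),
               rec("orgA", "sm2", "s1", 60000, 62000))
    hits5 <- mineHits(r, s5, MinerConfig(70000))
    expect_gt(nrow(hits5), nrow(hits))
    expect_identical(geneRecords(collectHomologs(hits5, r)),
                     geneRecords(hom))

    # no hits -> empty homolog table
    expect_identical(length(collectHomologs(hits[0, ], r)), 0L)
    # organisms in the table are exactly the hit organisms
    expect_identical(unique(geneRecords(hom)$organism),
                     unique(hits$organism))
})
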