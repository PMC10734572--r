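# Shared builders for in-code fixtures.

rec <- function(organism, gene_id, scaffold, start, stop,
                evalue = NA_real_, pct_identity = NA_real_,
                description = NA_character_) {
    data.frame(organism = organism, gene_id = gene_id, scaffold = scaffold,
               start = start, stop = stop, evalue = evalue,
               pct_identity = pct_identity, description = description,
               stringsAsFactors = FALSE)
}

rTab <- function(...) GeneTable(do.call(rbind, list(...)),
                                role = "resistance")
sTab <- function(...) GeneTable(do.call(rbind, list(...)), role = "sm_core")

randomRecord <- function(n = 1L, orgs = c("orgA", "orgB"),
                         scafs = c("s1", "s2")) {
    start <- sample.int(50000L, n)
    rec(organism = sample(orgs, n, replace = TRUE),
        gene_id = sprintf("g%04d", sample.int(9999L, n)),
        scaffold = sample(scafs, n, replace = TRUE),
        start = start, stop = start + sample.int(5000L, n) - 1L)
}

# Independent re-check of the five hit predicates, straight from the hit
# row and the configuration: same organism and scaffold, centers within
# the cutoff (doubled-coordinate comparison), no overlap, resistance gene
# within the length limit. Used as a post-hoc audit of miner output.
auditHitPredicates <- function(hits, config, rTable = NULL) {
    if (nrow(hits) == 0L) return(TRUE)
    ok <- hits$resistance_scaffold == hits$sm_scaffold &
        abs((hits$resistance_start + hits$resistance_stop) -
            (hits$sm_start + hits$sm_stop)) <= 2 * config@cutoff &
        !(hits$resistance_start <= hits$sm_stop &
          hits$sm_start <= hits$resistance_stop) &
        (hits$resistance_stop - hits$resistance_start + 1) <=
            config@maxGeneLength
    if (config@singletonCheck && !is.null(rTable)) {
        counts <- table(geneRecords(rTable)$organism)
        ok <- ok & counts[hits$organism] >= 2L
    }
    all(ok)
}

hitKeys <- function(hits)
    paste(hits$organism, hits$resistance_gene_id, hits$sm_gene_id)
truthKeys <- function(truth) {
    tp <- truthPairs(truth)
    paste(tp$organism, tp$resistance_gene_id, tp$sm_gene_id)
}
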