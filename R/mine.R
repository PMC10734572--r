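#' Construct a MinerConfig
#'
#' @param cutoff center-to-center distance cutoff C, base pairs (>= 1).
#'   Required: the appropriate value depends on the gene class being mined;
#'   70000 bp is the recommended working value for fungal secondary
#'   metabolite clusters.
#' @param maxGeneLength maximum resistance-gene length M, base pairs;
#'   \code{Inf} (default) disables the length filter.
#' @param singletonCheck require at least two resistance-gene copies per
#'   genome (default \code{TRUE}); \code{FALSE} is the "nocheck" waiver.
#' @param homologMode whether a homolog table should be collected for hit
#'   genomes.
#' @return a [MinerConfig-class].
#' @examples
#' MinerConfig(cutoff = 70000)
#' @export
MinerConfig <- function(cutoff, maxGeneLength = Inf, singletonCheck = TRUE,
                        homologMode = FALSE) {
    new("MinerConfig", cutoff = as.numeric(cutoff)[1],
        maxGeneLength = as.numeric(maxGeneLength)[1],
        singletonCheck = as.logical(singletonCheck)[1],
        homologMode = as.logical(homologMode)[1])
}

setMethod("show", "MinerConfig", function(object) {
    cat("MinerConfig\n")
    cat("  cutoff (C):        ", .formatBp(object@cutoff), " bp\n", sep = "")
    cat("  maxGeneLength (M): ",
        if (is.finite(object@maxGeneLength))
            paste0(.formatBp(object@maxGeneLength), " bp") else "unlimited",
        "\n", sep = "")
    cat("  singletonCheck:    ", object@singletonCheck,
        if (!object@singletonCheck) " (nocheck waiver)" else "",
        "\n", sep = "")
    cat("  homologMode:       ", object@homologMode, "\n", sep = "")
})

.HIT_COLS <- c("organism", "resistance_gene_id", "resistance_scaffold",
               "resistance_start", "resistance_stop", "resistance_evalue",
               "resistance_pct_identity", "sm_gene_id", "sm_scaffold",
               "sm_start", "sm_stop", "center_distance")

.emptyHits <- function() {
    data.frame(organism = character(), resistance_gene_id = character(),
               resistance_scaffold = character(),
               resistance_start = numeric(), resistance_stop = numeric(),
               resistance_evalue = numeric(),
               resistance_pct_identity = numeric(),
               sm_gene_id = character(), sm_scaffold = character(),
               sm_start = numeric(), sm_stop = numeric(),
               center_distance = numeric(), stringsAsFactors = FALSE)
}

## Build the hit data.frame from index vectors into the r and s record
## frames, then sort into the canonical deterministic order.
.buildHits <- function(rr, ss, ri, si) {
    if (length(ri) == 0L) return(.emptyHits())
    r <- rr[ri, , drop = FALSE]
    s <- ss[si, , drop = FALSE]
    hits <- data.frame(organism = r$organism,
                       resistance_gene_id = r$gene_id,
                       resistance_scaffold = r$scaffold,
                       resistance_start = r$start,
                       resistance_stop = r$stop,
                       resistance_evalue = r$evalue,
                       resistance_pct_identity = r$pct_identity,
                       sm_gene_id = s$gene_id,
                       sm_scaffold = s$scaffold,
                       sm_start = s$start,
                       sm_stop = s$stop,
                       center_distance =
                           abs((r$start + r$stop) - (s$start + s$stop)) / 2,
                       stringsAsFactors = FALSE)
    ord <- .radixOrder(hits$organism, hits$resistance_start,
                       hits$resistance_gene_id, hits$sm_start,
                       hits$sm_gene_id)
    hits <- hits[ord, , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

.checkRoles <- function(rTable, sTable) {
    if (tableRole(rTable) != "resistance")
        stop("rTable must have role 'resistance', got '",
             tableRole(rTable), "'", call. = FALSE)
    if (tableRole(sTable) != "sm_core")
        stop("sTable must have role 'sm_core', got '",
             tableRole(sTable), "'", call. = FALSE)
}

#' Discard genomes carrying fewer than two resistance-gene copies
#'
#' Self-resistance via a duplicated target gene requires both a
#' housekeeping allele and a resistant allele, so by default genomes with a
#' single resistance-gene copy are removed before the proximity join.
#' Copies are counted per organism on the full deduplicated table, before
#' any gene-length filtering; record order is preserved.
#'
#' @param rTable a resistance-role [GeneTable-class].
#' @return a [GeneTable-class] containing exactly the records of organisms
#'   with >= 2 copies (possibly empty).
#' @rdname eliminateSingletons
#' @export
setMethod("eliminateSingletons", "GeneTable", function(rTable) {
    if (tableRole(rTable) != "resistance")
        stop("eliminateSingletons expects a resistance-role table",
             call. = FALSE)
    rec <- geneRecords(rTable)
    counts <- table(rec$organism)
    keep <- rec$organism %in% names(counts)[counts >= 2L]
    initialize(rTable, records = {
        out <- rec[keep, , drop = FALSE]; rownames(out) <- NULL; out
    })
})

## Shared preamble of both mining routes: role checks, optional singleton
## elimination. Returns the effective R records.
.prepareR <- function(rTable, sTable, config) {
    .checkRoles(rTable, sTable)
    stopifnot(is(config, "MinerConfig"))
    validObject(config)
    if (config@singletonCheck) rTable <- eliminateSingletons(rTable)
    geneRecords(rTable)
}

#' Mine resistance-gene/SM-gene proximity hits (indexed engine)
#'
#' The core mining operation. After optional singleton elimination of the
#' resistance table R, reports every pair (r, s) of R x S satisfying all
#' five predicates: same organism; same scaffold; gene centers at most
#' \code{cutoff} base pairs apart (compared exactly on doubled
#' coordinates); the two genes do not overlap; and the resistance gene is
#' at most \code{maxGeneLength} long. One hit is emitted per qualifying
#' pair, so a resistance gene flanked by two in-range backbone genes
#' yields two hits (as a complete two-NRPS or two-PKS cluster does).
#'
#' This engine groups genes by (organism, scaffold) and binary-searches a
#' sorted array of doubled SM-gene centers for the window
#' \code{[2c_r - 2C, 2c_r + 2C]}; it is provably equivalent to the literal
#' all-pairs loop kept as [bruteForceMine()].
#'
#' @param rTable resistance-role [GeneTable-class] (the set R).
#' @param sTable sm_core-role [GeneTable-class] (the set S).
#' @param config a [MinerConfig-class].
#' @return a data.frame of hits, one row per qualifying pair, with columns
#'   \code{organism}, \code{resistance_gene_id}, \code{resistance_scaffold},
#'   \code{resistance_start}, \code{resistance_stop},
#'   \code{resistance_evalue}, \code{resistance_pct_identity},
#'   \code{sm_gene_id}, \code{sm_scaffold}, \code{sm_start}, \code{sm_stop},
#'   \code{center_distance} (exact, base pairs; integer or half-integer),
#'   sorted by (organism, resistance start, resistance gene id, SM start,
#'   SM gene id).
#' @seealso [bruteForceMine()], [collectHomologs()], [writeHitsCsv()]
#' @rdname mineHits
#' @export
setMethod("mineHits",
    signature(rTable = "GeneTable", sTable = "GeneTable",
              config = "MinerConfig"),
    function(rTable, sTable, config) {
        rr <- .prepareR(rTable, sTable, config)
        ss <- geneRecords(sTable)
        ## length predicate depends only on r: filter up front (singleton
        ## counting has already happened on the full table)
        rr <- rr[rr$stop - rr$start + 1 <= config@maxGeneLength, ,
                 drop = FALSE]
        if (nrow(rr) == 0L || nrow(ss) == 0L) return(.emptyHits())

        skey <- .pasteKey(ss$scaffold, ss$organism)
        rkey <- .pasteKey(rr$scaffold, rr$organism)
        sc2 <- ss$start + ss$stop
        ## per-(organism, scaffold) sorted center index over S
        sgroups <- split(seq_len(nrow(ss)), skey)
        sgroups <- lapply(sgroups, function(idx) idx[order(sc2[idx])])
        rc2 <- rr$start + rr$stop
        lim2 <- 2 * config@cutoff

        ri <- si <- vector("list", nrow(rr))
        for (i in seq_len(nrow(rr))) {
            grp <- sgroups[[rkey[i]]]
            if (is.null(grp)) next
            centers <- sc2[grp]
            lo <- findInterval(rc2[i] - lim2, centers,
                               left.open = TRUE) + 1L
            hi <- findInterval(rc2[i] + lim2, centers)
            if (lo > hi) next
            cand <- grp[lo:hi]
            ## overlap exclusion (same organism/scaffold by construction)
            keep <- !(rr$start[i] <= ss$stop[cand] &
                      ss$start[cand] <= rr$stop[i])
            cand <- cand[keep]
            if (length(cand)) {
                ri[[i]] <- rep.int(i, length(cand))
                si[[i]] <- cand
            }
        }
        .buildHits(rr, ss, unlist(ri), unlist(si))
    })

#' Mine hits with the literal all-pairs loop (testing oracle)
#'
#' Evaluates the five hit predicates for every (r, s) pair of R x S with no
#' indexing, exactly as the algorithm is defined: an outer pass over every
#' resistance gene and an inner pass over every SM gene (worst-case
#' O(|R||S|)). Retained permanently as the independent oracle against
#' which the indexed [mineHits()] engine is verified; the two must produce
#' element-wise identical hit lists on any input.
#'
#' @inheritParams mineHits
#' @inherit mineHits return
#' @rdname bruteForceMine
#' @export
setMethod("bruteForceMine",
    signature(rTable = "GeneTable", sTable = "GeneTable",
              config = "MinerConfig"),
    function(rTable, sTable, config) {
        rr <- .prepareR(rTable, sTable, config)
        ss <- geneRecords(sTable)
        if (nrow(rr) == 0L || nrow(ss) == 0L) return(.emptyHits())
        sc2 <- ss$start + ss$stop
        lim2 <- 2 * config@cutoff
        ri <- si <- vector("list", nrow(rr))
        for (i in seq_len(nrow(rr))) {      # for each r_gene in R
            ok <- ss$organism == rr$organism[i]            # same organism
            ok <- ok & ss$scaffold == rr$scaffold[i]       # same scaffold
            ok <- ok & abs((rr$start[i] + rr$stop[i]) - sc2) <= lim2
            ok <- ok & !(rr$start[i] <= ss$stop & ss$start <= rr$stop[i])
            ok <- ok & (rr$stop[i] - rr$start[i] + 1) <= config@maxGeneLength
            hit <- which(ok)
            if (length(hit)) {
                ri[[i]] <- rep.int(i, length(hit))
                si[[i]] <- hit
            }
        }
        .buildHits(rr, ss, unlist(ri), unlist(si))
    })

#' Collect the resistance-gene homolog table of hit genomes
#'
#' For every genome contributing at least one hit, gathers all resistance
#' records of that genome from R -- including the hit genes themselves --
#' deduplicated to a set and sorted by (organism, start, gene id). This is
#' the "homolog mode" output: the full complement of target-gene copies in
#' each hit genome, for downstream inspection of which copy is the
#' housekeeping allele and which the resistant allele.
#'
#' @param hits a hit data.frame as returned by [mineHits()].
#' @param rTable the same resistance [GeneTable-class] used to produce the
#'   hits (post-singleton-elimination if that was applied).
#' @return a resistance-role [GeneTable-class] of homologs (possibly
#'   empty), source \code{"homologs"}.
#' @rdname collectHomologs
#' @export
setMethod("collectHomologs",
    signature(hits = "data.frame", rTable = "GeneTable"),
    function(hits, rTable) {
        if (tableRole(rTable) != "resistance")
            stop("collectHomologs expects a resistance-role table",
                 call. = FALSE)
        rec <- geneRecords(rTable)
        rec <- rec[rec$organism %in% unique(hits$organism), , drop = FALSE]
        rec <- .dedupRecords(rec)
        ord <- .radixOrder(rec$organism, rec$start, rec$gene_id)
        rec <- rec[ord, , drop = FALSE]
        rownames(rec) <- NULL
        initialize(rTable, records = rec, source = "homologs")
    })
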