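## ---- planted pairs ---------------------------------------------------------

#' Describe one planted resistance/SM gene pair
#'
#' A planted pair fixes the exact intervals of one resistance gene and one
#' SM backbone gene on a chosen scaffold, plus the number of extra
#' resistance-gene copies (>= 1, placed elsewhere in the genome) that make
#' the two-copy rule satisfiable. The intended center distance is the
#' arithmetic of the placed intervals, never an independent number.
#'
#' @param genome,scaffold 1-based genome and scaffold indices.
#' @param rStart,rStop resistance-gene interval (1-based inclusive).
#' @param sStart,sStop SM-gene interval; must not overlap the resistance
#'   interval.
#' @param nExtraCopies extra resistance copies for this genome (>= 1).
#' @return a list of class \code{"PlantedPair"} with the fields above plus
#'   \code{centerDistance}.
#' @seealso [plantedPairAt()] to construct a pair from a target distance.
#' @export
plantedPair <- function(genome, scaffold, rStart, rStop, sStart, sStop,
                        nExtraCopies = 1L) {
    pp <- list(genome = as.numeric(genome), scaffold = as.numeric(scaffold),
               rStart = as.numeric(rStart), rStop = as.numeric(rStop),
               sStart = as.numeric(sStart), sStop = as.numeric(sStop),
               nExtraCopies = as.numeric(nExtraCopies),
               centerDistance =
                   abs((rStart + rStop) - (sStart + sStop)) / 2)
    class(pp) <- "PlantedPair"
    pp
}

#' Construct a planted pair at an exact center distance
#'
#' Places the SM gene to the right of the resistance gene so that the
#' center-to-center distance equals \code{distance} exactly; the SM gene
#' length is increased by one base when needed to make the start
#' coordinate integral (centers may sit on half-integers, but coordinates
#' cannot).
#'
#' @inheritParams plantedPair
#' @param rLength,sLength requested gene lengths, base pairs.
#' @param distance exact center-to-center distance, base pairs (integer).
#' @return a \code{"PlantedPair"}.
#' @export
plantedPairAt <- function(genome, scaffold, rStart, rLength, distance,
                          sLength, nExtraCopies = 1L) {
    rStop <- rStart + rLength - 1
    sc2 <- (rStart + rStop) + 2 * distance
    if ((sc2 - sLength + 1) %% 2 != 0) sLength <- sLength + 1
    sStart <- (sc2 - sLength + 1) / 2
    sStop <- sStart + sLength - 1
    if (sStart <= rStop)
        stop("distance ", distance,
             " too small for non-overlapping genes of lengths ",
             rLength, "/", sLength, call. = FALSE)
    plantedPair(genome, scaffold, rStart, rStop, sStart, sStop, nExtraCopies)
}

## Validity helper used by the FixtureSpec class: returns TRUE or a message.
.checkPlantedPair <- function(pp, spec) {
    if (!inherits(pp, "PlantedPair"))
        return("plantedPairs must be built with plantedPair()")
    v <- unlist(pp[c("genome", "scaffold", "rStart", "rStop",
                     "sStart", "sStop", "nExtraCopies")])
    if (any(!is.finite(v)) || any(v < 1) || any(v != floor(v)))
        return("planted-pair fields must be whole numbers >= 1")
    if (pp$rStart > pp$rStop || pp$sStart > pp$sStop)
        return("planted intervals must satisfy start <= stop")
    if (pp$rStart <= pp$sStop && pp$sStart <= pp$rStop)
        return("planted resistance and SM intervals must be disjoint")
    if (pp$nExtraCopies < 1)
        return("nExtraCopies must be >= 1 (two-copy rule must be satisfiable)")
    if (pp$genome > spec@nGenomes || pp$scaffold > spec@scaffoldsPerGenome)
        return("planted pair genome/scaffold index out of range")
    if (max(pp$rStop, pp$sStop) > spec@scaffoldLength)
        return("planted genes must fit on their scaffold")
    TRUE
}

## ---- FixtureSpec constructor ----------------------------------------------

#' Construct a FixtureSpec
#'
#' @param nGenomes,scaffoldsPerGenome,scaffoldLength genome-set geometry.
#' @param nBackgroundSm background SM genes (placed > cutoff from every
#'   resistance-gene center by rejection sampling).
#' @param nBackgroundResistance background resistance homologs (placed >
#'   cutoff from every SM-gene center).
#' @param plantedPairs list of [plantedPair()] objects.
#' @param decoys named counts over the classes \code{singleton_near}
#'   (one resistance copy only: fails the two-copy rule), \code{far_pair}
#'   (center distance > cutoff), \code{overlapping_pair} (intervals share
#'   bases), \code{oversized_resistance} (length > maxGeneLength). Each
#'   decoy violates exactly its designated predicate.
#' @param geneLengthRange sampled gene lengths, \code{c(min, max)} bp.
#' @param cutoff,maxGeneLength the (C, M) the truth set is stated at.
#' @param seed integer seed: equal specs generate identical fixtures.
#' @return a [FixtureSpec-class].
#' @seealso [generateFixture()], [randomFixtureSpec()]
#' @export
fixtureSpec <- function(nGenomes, scaffoldsPerGenome = 3,
                        scaffoldLength = 1e6,
                        nBackgroundSm = 0, nBackgroundResistance = 0,
                        plantedPairs = list(),
                        decoys = c(singleton_near = 0L, far_pair = 0L,
                                   overlapping_pair = 0L,
                                   oversized_resistance = 0L),
                        geneLengthRange = c(500, 15000),
                        cutoff = 70000, maxGeneLength = Inf, seed = 1L) {
    d <- c(singleton_near = 0, far_pair = 0, overlapping_pair = 0,
           oversized_resistance = 0)
    d[names(decoys)] <- as.numeric(decoys)
    new("FixtureSpec", nGenomes = as.numeric(nGenomes),
        scaffoldsPerGenome = as.numeric(scaffoldsPerGenome),
        scaffoldLength = as.numeric(scaffoldLength),
        nBackgroundSm = as.numeric(nBackgroundSm),
        nBackgroundResistance = as.numeric(nBackgroundResistance),
        plantedPairs = plantedPairs, decoys = d,
        geneLengthRange = as.numeric(geneLengthRange),
        cutoff = as.numeric(cutoff),
        maxGeneLength = as.numeric(maxGeneLength),
        seed = as.numeric(seed))
}

setMethod("show", "FixtureSpec", function(object) {
    cat("FixtureSpec: ", .formatBp(object@nGenomes), " genomes x ",
        .formatBp(object@scaffoldsPerGenome), " scaffolds (",
        .formatBp(object@scaffoldLength), " bp)\n", sep = "")
    cat("  planted pairs: ", length(object@plantedPairs),
        "; decoys: ", paste(names(object@decoys), object@decoys,
                            sep = "=", collapse = ", "), "\n", sep = "")
    cat("  background: ", .formatBp(object@nBackgroundSm), " SM, ",
        .formatBp(object@nBackgroundResistance), " resistance\n", sep = "")
    cat("  truth at C=", .formatBp(object@cutoff), " bp, M=",
        if (is.finite(object@maxGeneLength))
            .formatBp(object@maxGeneLength) else "unlimited",
        "; seed ", .formatBp(object@seed), "\n", sep = "")
})

#' @rdname TruthSet-accessors
#' @export
setMethod("truthPairs", "TruthSet", function(x) x@pairs)

#' Accessors for TruthSet slots
#'
#' @param x a [TruthSet-class].
#' @return data.frames; see the class slots.
#' @name TruthSet-accessors
#' @rdname TruthSet-accessors
#' @export
setMethod("truthDecoys", "TruthSet", function(x) x@decoys)

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet: ", nrow(object@pairs), " expected hit pair(s) at C=",
        .formatBp(object@cutoff), " bp, M=",
        if (is.finite(object@maxGeneLength))
            .formatBp(object@maxGeneLength) else "unlimited",
        "; ", nrow(object@decoys), " decoy(s)\n", sep = "")
})

## ---- generation ------------------------------------------------------------

.orgName <- function(i) sprintf("org%04d", i)
.scafName <- function(j) sprintf("scaf%02d", j)

## Growable column store for gene records.
.newAcc <- function() {
    env <- new.env(parent = emptyenv())
    env$organism <- env$gene_id <- env$scaffold <- character()
    env$start <- env$stop <- env$evalue <- env$pct <- numeric()
    env
}
.accAdd <- function(env, organism, gene_id, scaffold, start, stop,
                    evalue = NA_real_, pct = NA_real_) {
    env$organism <- c(env$organism, organism)
    env$gene_id <- c(env$gene_id, gene_id)
    env$scaffold <- c(env$scaffold, scaffold)
    env$start <- c(env$start, start)
    env$stop <- c(env$stop, stop)
    env$evalue <- c(env$evalue, evalue)
    env$pct <- c(env$pct, pct)
    invisible(env)
}
.accFrame <- function(env) {
    data.frame(organism = env$organism, gene_id = env$gene_id,
               scaffold = env$scaffold, start = env$start, stop = env$stop,
               evalue = env$evalue, pct_identity = env$pct,
               description = NA_character_, stringsAsFactors = FALSE)
}

## Synthetic search statistics for resistance homologs (the emulated tables
## come from a TBLASTN search, which reports both).
.fakeStats <- function() {
    list(evalue = signif(10^(-round(stats::runif(1, 41, 180), 1)), 3),
         pct = round(stats::runif(1, 35, 99), 1))
}

.randLen <- function(spec) {
    r <- spec@geneLengthRange
    sample.int(r[2] - r[1] + 1L, 1L) + r[1] - 1L
}

#' Generate a synthetic gene-table fixture with known truth
#'
#' Materializes a [FixtureSpec-class] into a resistance [GeneTable-class],
#' an SM-core [GeneTable-class], and a [TruthSet-class] enumerating, by
#' construction arithmetic alone, exactly the hits a default-configuration
#' run at the spec's (cutoff, maxGeneLength) must produce. Planted pairs
#' sit at their exact intended center distances; each decoy class violates
#' exactly one predicate; background genes are kept out of range by
#' rejection sampling, and generation aborts (rather than emitting an
#' inexact truth) if an incidental qualifying pair cannot be avoided.
#' Output is deterministic given the spec (including its seed).
#'
#' @param spec a [FixtureSpec-class].
#' @return a list with elements \code{rTable}, \code{sTable} (sources
#'   \code{"synthetic"}) and \code{truth}.
#' @rdname generateFixture
#' @export
setMethod("generateFixture", "FixtureSpec", function(spec) {
    validObject(spec)
    withr::with_seed(as.integer(spec@seed) %% .Machine$integer.max,
                     .generateFixtureImpl(spec))
})

.generateFixtureImpl <- function(spec) {
    L <- spec@scaffoldLength
    C <- spec@cutoff
    nscaf <- spec@scaffoldsPerGenome
    racc <- .newAcc()
    sacc <- .newAcc()
    ## per-(organism|scaffold) center/interval bookkeeping for rejection
    idx <- new.env(parent = emptyenv())
    getIdx <- function(key)
        if (is.null(idx[[key]])) list(rc2 = numeric(), rs = numeric(),
                                      re = numeric(), sc2 = numeric(),
                                      ss = numeric(), se = numeric())
        else idx[[key]]
    noteR <- function(org, scaf, start, stop) {
        key <- .pasteKey(org, scaf); g <- getIdx(key)
        g$rc2 <- c(g$rc2, start + stop)
        g$rs <- c(g$rs, start); g$re <- c(g$re, stop)
        idx[[key]] <- g
    }
    noteS <- function(org, scaf, start, stop) {
        key <- .pasteKey(org, scaf); g <- getIdx(key)
        g$sc2 <- c(g$sc2, start + stop)
        g$ss <- c(g$ss, start); g$se <- c(g$se, stop)
        idx[[key]] <- g
    }
    rid <- sid <- 0L
    nextRId <- function() { rid <<- rid + 1L; sprintf("rgene%05d", rid) }
    nextSId <- function() { sid <<- sid + 1L; sprintf("smgene%05d", sid) }
    addR <- function(org, scaf, start, stop) {
        st <- .fakeStats()
        id <- nextRId()
        .accAdd(racc, org, id, scaf, start, stop, st$evalue, st$pct)
        noteR(org, scaf, start, stop)
        id
    }
    addS <- function(org, scaf, start, stop) {
        id <- nextSId()
        .accAdd(sacc, org, id, scaf, start, stop)
        noteS(org, scaf, start, stop)
        id
    }
    ## Rejection-sample a start position for a gene of length len on a
    ## random (or fixed) scaffold such that accept(key, start, stop) holds.
    place <- function(len, org = NULL, scaf = NULL, accept,
                      attempts = 500L, orgPool = seq_len(spec@nGenomes)) {
        for (t in seq_len(attempts)) {
            o <- if (is.null(org))
                     .orgName(orgPool[sample.int(length(orgPool), 1L)])
                 else org
            sc <- if (is.null(scaf))
                      .scafName(sample.int(nscaf, 1L)) else scaf
            start <- sample.int(L - len + 1L, 1L)
            stop <- start + len - 1
            if (accept(.pasteKey(o, sc), start, stop))
                return(list(org = o, scaf = sc, start = start, stop = stop))
        }
        stop("fixture generation failed: could not place a gene after ",
             attempts, " rejection attempts (spec too crowded?)",
             call. = FALSE)
    }
    farFromS <- function(key, start, stop) {
        g <- getIdx(key)
        length(g$sc2) == 0L ||
            (all(abs((start + stop) - g$sc2) > 2 * C) &&
             !any(start <= g$se & g$ss <= stop))
    }
    farFromR <- function(key, start, stop) {
        g <- getIdx(key)
        length(g$rc2) == 0L ||
            (all(abs((start + stop) - g$rc2) > 2 * C) &&
             !any(start <= g$re & g$rs <= stop))
    }

    truthOrg <- truthR <- truthS <- character(); truthD <- numeric()
    decoyId <- decoyOrg <- decoyClass <- decoyPartner <- character()
    decoyDist <- numeric()

    ## 1. planted pairs and their extra resistance copies
    for (pp in spec@plantedPairs) {
        org <- .orgName(pp$genome)
        scaf <- .scafName(pp$scaffold)
        rId <- addR(org, scaf, pp$rStart, pp$rStop)
        sId <- addS(org, scaf, pp$sStart, pp$sStop)
        if (pp$centerDistance <= C &&
            (pp$rStop - pp$rStart + 1) <= spec@maxGeneLength) {
            truthOrg <- c(truthOrg, org); truthR <- c(truthR, rId)
            truthS <- c(truthS, sId)
            truthD <- c(truthD, pp$centerDistance)
        }
        for (k in seq_len(pp$nExtraCopies)) {
            scafIdx <- if (nscaf > 1L)
                ((pp$scaffold - 1L + k - 1L) %% (nscaf - 1L)) + 1L else 1L
            if (nscaf > 1L && scafIdx >= pp$scaffold)
                scafIdx <- scafIdx + 1L
            p <- place(.randLen(spec), org = org,
                       scaf = .scafName(scafIdx), accept = farFromS)
            addR(p$org, p$scaf, p$start, p$stop)
        }
    }

    ## 2. decoys, each on its own otherwise-empty organism
    usedOrgs <- unique(vapply(spec@plantedPairs,
                              function(pp) pp$genome, numeric(1)))
    freeOrgs <- setdiff(seq_len(spec@nGenomes), usedOrgs)
    if (length(freeOrgs) < sum(spec@decoys))
        stop("fixture generation failed: need ", sum(spec@decoys),
             " decoy genomes but only ", length(freeOrgs), " are free",
             call. = FALSE)
    takeOrg <- function() {
        o <- freeOrgs[1L]; freeOrgs <<- freeOrgs[-1L]; .orgName(o)
    }
    glmax <- spec@geneLengthRange[2]
    nearPair <- function(org, overlap = FALSE, rLen = .randLen(spec)) {
        ## place an (r, s) pair on scaffold 1 of org: overlapping, or
        ## non-overlapping within the cutoff
        sLen <- .randLen(spec)
        if (overlap) {
            rStart <- sample.int(L - rLen - sLen, 1L)
            sStart <- rStart + max(1L, rLen %/% 2L)
        } else {
            dmin <- ceiling((rLen + sLen) / 2) + 10
            if (dmin >= C)
                stop("fixture generation failed: cutoff ", C,
                     " too small for gene lengths", call. = FALSE)
            d <- sample.int(C - dmin, 1L) + dmin - 1L
            rStart <- sample.int(L - (d + rLen + sLen), 1L)
            sc2 <- (2 * rStart + rLen - 1) + 2 * d
            sLen <- sLen + (sc2 - sLen + 1) %% 2
            sStart <- (sc2 - sLen + 1) / 2
        }
        rStop <- rStart + rLen - 1; sStop <- sStart + sLen - 1
        rId <- addR(org, .scafName(1L), rStart, rStop)
        sId <- addS(org, .scafName(1L), sStart, sStop)
        list(rId = rId, sId = sId,
             d = abs((rStart + rStop) - (sStart + sStop)) / 2)
    }
    extraCopy <- function(org) {
        scaf <- if (nscaf > 1L) .scafName(nscaf) else NULL
        p <- place(.randLen(spec), org = org, scaf = scaf,
                   accept = farFromS)
        addR(p$org, p$scaf, p$start, p$stop)
    }
    noteDecoy <- function(id, org, cls, partner = NA_character_,
                          d = NA_real_) {
        decoyId <<- c(decoyId, id); decoyOrg <<- c(decoyOrg, org)
        decoyClass <<- c(decoyClass, cls)
        decoyPartner <<- c(decoyPartner, partner)
        decoyDist <<- c(decoyDist, d)
    }
    for (k in seq_len(spec@decoys[["singleton_near"]])) {
        org <- takeOrg()
        pr <- nearPair(org)                      # only resistance copy
        noteDecoy(pr$rId, org, "singleton_near", pr$sId, pr$d)
    }
    for (k in seq_len(spec@decoys[["far_pair"]])) {
        org <- takeOrg()
        rLen <- .randLen(spec); sLen <- .randLen(spec)
        dmax <- L - rLen - sLen - 2
        if (dmax <= C + 1)
            stop("fixture generation failed: scaffold too short for a ",
                 "far_pair decoy beyond cutoff ", C, call. = FALSE)
        d <- sample.int(dmax - C - 1L, 1L) + C
        rStart <- sample.int(max(1, L - (d + rLen + sLen)), 1L)
        sc2 <- (2 * rStart + rLen - 1) + 2 * d
        sLen <- sLen + (sc2 - sLen + 1) %% 2
        sStart <- (sc2 - sLen + 1) / 2
        rId <- addR(org, .scafName(1L), rStart, rStart + rLen - 1)
        sId <- addS(org, .scafName(1L), sStart, sStart + sLen - 1)
        extraCopy(org)
        noteDecoy(rId, org, "far_pair", sId, d)   # exact by construction
    }
    for (k in seq_len(spec@decoys[["overlapping_pair"]])) {
        org <- takeOrg()
        pr <- nearPair(org, overlap = TRUE)
        extraCopy(org)
        noteDecoy(pr$rId, org, "overlapping_pair", pr$sId, pr$d)
    }
    for (k in seq_len(spec@decoys[["oversized_resistance"]])) {
        org <- takeOrg()
        rLen <- ceiling(spec@maxGeneLength * 1.5)
        if (rLen + 2 * glmax + C >= L)
            stop("fixture generation failed: scaffold too short for an ",
                 "oversized_resistance decoy", call. = FALSE)
        pr <- nearPair(org, rLen = rLen)
        extraCopy(org)
        noteDecoy(pr$rId, org, "oversized_resistance", pr$sId, pr$d)
    }

    ## 3. background resistance homologs (> C from every SM center).
    ## singleton_near genomes are off limits: a second copy there would
    ## quietly turn the decoy into a genuine hit.
    snIdx <- match(decoyOrg[decoyClass == "singleton_near"],
                   .orgName(seq_len(spec@nGenomes)))
    brPool <- setdiff(seq_len(spec@nGenomes), snIdx)
    for (k in seq_len(spec@nBackgroundResistance)) {
        p <- place(.randLen(spec), accept = farFromS, orgPool = brPool)
        addR(p$org, p$scaf, p$start, p$stop)
    }
    ## 4. background SM genes (> C from every resistance center)
    for (k in seq_len(spec@nBackgroundSm)) {
        p <- place(.randLen(spec), accept = farFromR)
        addS(p$org, p$scaf, p$start, p$stop)
    }

    rdf <- .accFrame(racc)
    sdf <- .accFrame(sacc)
    ord <- .radixOrder(truthOrg, truthR, truthS)
    truth <- new("TruthSet",
        pairs = data.frame(organism = truthOrg[ord],
                           resistance_gene_id = truthR[ord],
                           sm_gene_id = truthS[ord],
                           center_distance = truthD[ord],
                           stringsAsFactors = FALSE),
        decoys = data.frame(gene_id = decoyId, organism = decoyOrg,
                            class = decoyClass, partner_sm_id = decoyPartner,
                            center_distance = decoyDist,
                            stringsAsFactors = FALSE),
        cutoff = C, maxGeneLength = spec@maxGeneLength)
    .auditFixture(rdf, sdf, truth)
    list(rTable = GeneTable(rdf, role = "resistance", source = "synthetic"),
         sTable = GeneTable(sdf, role = "sm_core", source = "synthetic"),
         truth = truth)
}

## Construction-time audit: enumerate qualifying pairs by direct predicate
## arithmetic (grouped per scaffold; this is bookkeeping, not the mining
## engine) and abort if any pair beyond the declared truth slipped in.
.auditFixture <- function(rdf, sdf, truth) {
    qual <- .qualifyingPairs(rdf, sdf, truth@cutoff, truth@maxGeneLength,
                             requireTwoCopies = TRUE)
    want <- .pasteKey(truth@pairs$resistance_gene_id, truth@pairs$sm_gene_id)
    got <- .pasteKey(qual$resistance_gene_id, qual$sm_gene_id)
    if (!setequal(want, got))
        stop("fixture generation failed: incidental qualifying pair(s) ",
             "present; adjust the spec (fewer/looser genes or more ",
             "scaffolds)", call. = FALSE)
    ## under the waiver, exactly the singleton_near pairs are added
    qualNC <- .qualifyingPairs(rdf, sdf, truth@cutoff, truth@maxGeneLength,
                               requireTwoCopies = FALSE)
    sn <- truth@decoys[truth@decoys$class == "singleton_near", , drop = FALSE]
    wantNC <- c(want, .pasteKey(sn$gene_id, sn$partner_sm_id))
    gotNC <- .pasteKey(qualNC$resistance_gene_id, qualNC$sm_gene_id)
    if (!setequal(wantNC, gotNC))
        stop("fixture generation failed: waiver-mode truth is not exactly ",
             "planted pairs plus singleton_near decoys", call. = FALSE)
    invisible(NULL)
}

.qualifyingPairs <- function(rdf, sdf, cutoff, maxGeneLength,
                             requireTwoCopies = TRUE) {
    if (requireTwoCopies) {
        counts <- table(rdf$organism)
        rdf <- rdf[rdf$organism %in% names(counts)[counts >= 2L], ,
                   drop = FALSE]
    }
    rdf <- rdf[rdf$stop - rdf$start + 1 <= maxGeneLength, , drop = FALSE]
    rkey <- .pasteKey(rdf$organism, rdf$scaffold)
    skey <- .pasteKey(sdf$organism, sdf$scaffold)
    out_r <- out_s <- character(); out_o <- character(); out_d <- numeric()
    for (key in intersect(unique(rkey), unique(skey))) {
        ri <- which(rkey == key); si <- which(skey == key)
        for (i in ri) {
            dd2 <- abs((rdf$start[i] + rdf$stop[i]) -
                       (sdf$start[si] + sdf$stop[si]))
            ok <- dd2 <= 2 * cutoff &
                  !(rdf$start[i] <= sdf$stop[si] &
                    sdf$start[si] <= rdf$stop[i])
            if (any(ok)) {
                out_o <- c(out_o, rep(rdf$organism[i], sum(ok)))
                out_r <- c(out_r, rep(rdf$gene_id[i], sum(ok)))
                out_s <- c(out_s, sdf$gene_id[si][ok])
                out_d <- c(out_d, dd2[ok] / 2)
            }
        }
    }
    data.frame(organism = out_o, resistance_gene_id = out_r,
               sm_gene_id = out_s, center_distance = out_d,
               stringsAsFactors = FALSE)
}

## ---- canned specs ----------------------------------------------------------

#' Random fixture spec with planted pairs and all four decoy classes
#'
#' Convenience builder for property testing: assigns each planted pair and
#' each decoy to its own genome (so no incidental cross-pair hits can
#' arise) and draws gene lengths, positions and planted distances (all
#' strictly below \code{cutoff}) from the seeded stream.
#'
#' @param seed integer seed (also stored in the spec).
#' @param nPlantedPairs planted true pairs, one genome each.
#' @inheritParams fixtureSpec
#' @return a [FixtureSpec-class].
#' @export
randomFixtureSpec <- function(seed, nGenomes = 12, scaffoldsPerGenome = 3,
                              scaffoldLength = 1e6, nPlantedPairs = 4,
                              nBackgroundSm = 50, nBackgroundResistance = 10,
                              decoys = c(singleton_near = 1L, far_pair = 1L,
                                         overlapping_pair = 1L,
                                         oversized_resistance = 1L),
                              geneLengthRange = c(500, 15000),
                              cutoff = 70000, maxGeneLength = 20000) {
    stopifnot(nGenomes >= nPlantedPairs + sum(decoys))
    pairs <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
        lapply(seq_len(nPlantedPairs), function(i) {
            rLen <- sample.int(geneLengthRange[2] - geneLengthRange[1] + 1L,
                               1L) + geneLengthRange[1] - 1L
            sLen <- sample.int(geneLengthRange[2] - geneLengthRange[1] + 1L,
                               1L) + geneLengthRange[1] - 1L
            dmin <- ceiling((rLen + sLen) / 2) + 10
            d <- sample.int(cutoff - dmin, 1L) + dmin - 1L
            rStart <- sample.int(scaffoldLength - (d + rLen + sLen) - 2L, 1L)
            plantedPairAt(genome = i,
                          scaffold = sample.int(scaffoldsPerGenome, 1L),
                          rStart = rStart, rLength = rLen, distance = d,
                          sLength = sLen,
                          nExtraCopies = sample.int(2L, 1L))
        })
    })
    fixtureSpec(nGenomes = nGenomes,
                scaffoldsPerGenome = scaffoldsPerGenome,
                scaffoldLength = scaffoldLength,
                nBackgroundSm = nBackgroundSm,
                nBackgroundResistance = nBackgroundResistance,
                plantedPairs = pairs, decoys = decoys,
                geneLengthRange = geneLengthRange, cutoff = cutoff,
                maxGeneLength = maxGeneLength, seed = seed)
}

#' Small preset fixture spec
#'
#' A modest deterministic spec (12 genomes, 4 planted pairs, one decoy of
#' each class) suitable for quick demonstrations and the CLI
#' \code{simulate --preset small}.
#'
#' @param seed integer seed.
#' @return a [FixtureSpec-class].
#' @export
smallFixtureSpec <- function(seed = 1L) randomFixtureSpec(seed = seed)

#' Database-scale preset fixture spec
#'
#' Emulates the size of a whole-portal mining run over roughly 1800 fungal
#' genomes: about 28000 SM backbone genes and about 2300 resistance-gene
#' homologs, of which only a small minority sit near an SM gene. Intended
#' for performance testing of the indexed engine; the planted/decoy truth
#' machinery is identical to the small specs.
#'
#' @param seed integer seed.
#' @return a [FixtureSpec-class] with \code{nGenomes = 1800}.
#' @export
mycocosmScaleSpec <- function(seed = 1L) {
    randomFixtureSpec(seed = seed, nGenomes = 1800, scaffoldsPerGenome = 12,
                      scaffoldLength = 3e6, nPlantedPairs = 40,
                      nBackgroundSm = 27800, nBackgroundResistance = 2150,
                      decoys = c(singleton_near = 5L, far_pair = 5L,
                                 overlapping_pair = 5L,
                                 oversized_resistance = 5L),
                      geneLengthRange = c(500, 15000),
                      cutoff = 70000, maxGeneLength = 20000)
}

## ---- plain-text serialization ---------------------------------------------

#' Read or write a FixtureSpec as a YAML config file
#'
#' The schema is a flat mapping of the [fixtureSpec()] arguments, with
#' \code{maxGeneLength: unlimited} standing for \code{Inf} and
#' \code{plantedPairs} a sequence of mappings with keys \code{genome},
#' \code{scaffold}, \code{rStart}, \code{rStop}, \code{sStart},
#' \code{sStop}, \code{nExtraCopies}.
#'
#' @param spec a [FixtureSpec-class].
#' @param path file path.
#' @return \code{readFixtureSpec}: a [FixtureSpec-class];
#'   \code{writeFixtureSpec}: invisibly \code{NULL}.
#' @export
writeFixtureSpec <- function(spec, path) {
    pp <- lapply(spec@plantedPairs, function(p)
        lapply(p[c("genome", "scaffold", "rStart", "rStop", "sStart",
                   "sStop", "nExtraCopies")], as.integer))
    obj <- list(nGenomes = as.integer(spec@nGenomes),
                scaffoldsPerGenome = as.integer(spec@scaffoldsPerGenome),
                scaffoldLength = as.integer(spec@scaffoldLength),
                nBackgroundSm = as.integer(spec@nBackgroundSm),
                nBackgroundResistance =
                    as.integer(spec@nBackgroundResistance),
                plantedPairs = pp,
                decoys = as.list(as.integer(spec@decoys)) |>
                    stats::setNames(names(spec@decoys)),
                geneLengthRange = as.integer(spec@geneLengthRange),
                cutoff = as.integer(spec@cutoff),
                maxGeneLength = if (is.finite(spec@maxGeneLength))
                    as.integer(spec@maxGeneLength) else "unlimited",
                seed = as.integer(spec@seed))
    yaml::write_yaml(obj, path)
    invisible(NULL)
}

#' @rdname writeFixtureSpec
#' @export
readFixtureSpec <- function(path) {
    if (!file.exists(path))
        stop("file not found: '", path, "'", call. = FALSE)
    obj <- yaml::read_yaml(path)
    m <- obj$maxGeneLength
    if (identical(m, "unlimited")) m <- Inf
    pairs <- lapply(obj$plantedPairs, function(p)
        plantedPair(p$genome, p$scaffold, p$rStart, p$rStop,
                    p$sStart, p$sStop, p$nExtraCopies))
    fixtureSpec(nGenomes = obj$nGenomes,
                scaffoldsPerGenome = obj$scaffoldsPerGenome,
                scaffoldLength = obj$scaffoldLength,
                nBackgroundSm = obj$nBackgroundSm,
                nBackgroundResistance = obj$nBackgroundResistance %||% 0,
                plantedPairs = pairs,
                decoys = unlist(obj$decoys),
                geneLengthRange = unlist(obj$geneLengthRange),
                cutoff = obj$cutoff, maxGeneLength = m, seed = obj$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
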