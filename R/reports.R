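.HITS_CSV_HEADER <- c("organism", "resistance_gene_id",
                      "resistance_scaffold", "resistance_start",
                      "resistance_stop", "resistance_evalue",
                      "resistance_pct_identity", "sm_gene_id",
                      "sm_scaffold", "sm_start", "sm_stop",
                      "center_distance", "end_gap")

## Bases strictly between two non-overlapping genes (0 if they abut).
.endGap <- function(hits) {
    pmax(hits$resistance_start, hits$sm_start) -
        pmin(hits$resistance_stop, hits$sm_stop) - 1
}

#' Write a hit list as CSV
#'
#' Serializes the hit table in its deterministic mined order with the
#' fixed header
#' \code{organism,resistance_gene_id,resistance_scaffold,resistance_start,}
#' \code{resistance_stop,resistance_evalue,resistance_pct_identity,}
#' \code{sm_gene_id,sm_scaffold,sm_start,sm_stop,center_distance,end_gap}.
#' \code{center_distance} is the exact center-to-center distance (a
#' half-integer renders with a \code{".5"} suffix, an integer with no
#' decimal point); \code{end_gap} is the number of bases strictly between
#' the two genes as annotated (0 when they abut), reported alongside the
#' center distance because gene-to-gene distances are conventionally
#' quoted end-to-end. Unset E-values / identities are empty cells.
#'
#' @param hits a hit data.frame from [mineHits()].
#' @param path output file path.
#' @return invisibly \code{NULL}.
#' @export
writeHitsCsv <- function(hits, path) {
    .writeCsv(list(hits$organism, hits$resistance_gene_id,
                   hits$resistance_scaffold,
                   .formatBp(hits$resistance_start),
                   .formatBp(hits$resistance_stop),
                   .formatNum(hits$resistance_evalue),
                   .formatNum(hits$resistance_pct_identity),
                   hits$sm_gene_id, hits$sm_scaffold,
                   .formatBp(hits$sm_start), .formatBp(hits$sm_stop),
                   .formatBp(hits$center_distance),
                   .formatBp(.endGap(hits))),
              .HITS_CSV_HEADER, path)
}

#' Write a homolog table as CSV
#'
#' Canonical gene-table CSV (see [writeGeneTable()]) of the deduplicated
#' homolog set in (organism, start, gene id) order, as produced by
#' [collectHomologs()].
#'
#' @param h a [GeneTable-class] of homologs.
#' @param path output file path.
#' @return invisibly \code{NULL}.
#' @export
writeHomologsCsv <- function(h, path) writeGeneTable(h, path)

#' Histogram of hit frequencies by center distance
#'
#' Bins hits into contiguous half-open intervals
#' \code{[0, w), [w, 2w), ...} of their center distances, up to the
#' largest observed distance. A distance exactly on a bin boundary falls
#' in the upper bin. This is the view used to judge a distance cutoff:
#' genuine resistance-gene/backbone pairs pile up at short distances while
#' chance proximities spread flatly, so the histogram shows how little is
#' gained (and risked) by extending the cutoff.
#'
#' @param hits a hit data.frame from [mineHits()].
#' @param binWidth bin width in base pairs (>= 1).
#' @return a [HistogramResult-class].
#' @export
distanceHistogram <- function(hits, binWidth) {
    stopifnot(length(binWidth) == 1L, binWidth >= 1)
    binWidth <- as.numeric(binWidth)
    n <- nrow(hits)
    if (n == 0L)
        return(new("HistogramResult", binWidth = binWidth,
                   bins = data.frame(lower = numeric(), upper = numeric(),
                                     count = integer()),
                   total = 0L))
    bin <- floor(hits$center_distance / binWidth) + 1
    nbins <- max(bin)
    counts <- tabulate(bin, nbins)
    new("HistogramResult", binWidth = binWidth,
        bins = data.frame(lower = (seq_len(nbins) - 1) * binWidth,
                          upper = seq_len(nbins) * binWidth,
                          count = as.integer(counts)),
        total = as.integer(n))
}

#' @rdname HistogramResult-accessors
#' @export
setMethod("histBins", "HistogramResult", function(x) x@bins)

#' Accessors for HistogramResult
#'
#' @param x a [HistogramResult-class].
#' @return \code{histBins}: data.frame with columns \code{lower},
#'   \code{upper}, \code{count}.
#' @name HistogramResult-accessors
NULL

setMethod("show", "HistogramResult", function(object) {
    cat("HistogramResult: ", object@total, " hit(s) in ",
        nrow(object@bins), " bin(s) of ", .formatBp(object@binWidth),
        " bp\n", sep = "")
    if (nrow(object@bins)) print(object@bins, row.names = FALSE)
})

#' Sweep the distance cutoff over a ladder of values
#'
#' Runs the miner at each cutoff and reports the hit count and the number
#' of distinct genomes with at least one hit. Both counts are
#' non-decreasing in the cutoff (hit sets are nested), which is exactly
#' why extending a cutoff can only add candidates, never remove them.
#' Internally a single run at the largest cutoff is filtered down, which
#' is equivalent to per-cutoff runs because every predicate except the
#' distance itself is cutoff-independent.
#'
#' @param rTable,sTable the input [GeneTable-class]s.
#' @param baseConfig a [MinerConfig-class] whose cutoff slot is replaced
#'   by each sweep value in turn.
#' @param cutoffs strictly increasing cutoff values, base pairs.
#' @return a [SweepResult-class].
#' @export
cutoffSweep <- function(rTable, sTable, baseConfig, cutoffs) {
    if (length(cutoffs) == 0L)
        stop("cutoffs must be a non-empty list of values", call. = FALSE)
    cutoffs <- as.numeric(cutoffs)
    if (any(is.na(cutoffs)) ||
        is.unsorted(cutoffs, strictly = TRUE))
        stop("cutoffs must be strictly increasing", call. = FALSE)
    cfg <- initialize(baseConfig, cutoff = max(cutoffs))
    hits <- mineHits(rTable, sTable, cfg)
    counts <- genomes <- integer(length(cutoffs))
    for (i in seq_along(cutoffs)) {
        sub <- hits[hits$center_distance <= cutoffs[i], , drop = FALSE]
        counts[i] <- nrow(sub)
        genomes[i] <- length(unique(sub$organism))
    }
    new("SweepResult", cutoffs = cutoffs, counts = counts,
        genomes = genomes)
}

#' Accessors for SweepResult
#'
#' @param x a [SweepResult-class].
#' @return \code{sweepTable}: data.frame with columns \code{cutoff},
#'   \code{hits}, \code{genomes}.
#' @name SweepResult-accessors
#' @rdname SweepResult-accessors
#' @export
setMethod("sweepTable", "SweepResult", function(x)
    data.frame(cutoff = x@cutoffs, hits = x@counts, genomes = x@genomes))

setMethod("show", "SweepResult", function(object) {
    cat("SweepResult over ", length(object@cutoffs), " cutoff(s)\n",
        sep = "")
    tb <- sweepTable(object)
    tb$cutoff <- .formatBp(tb$cutoff)
    print(tb, row.names = FALSE)
})

#' Hits per genome
#'
#' One row per distinct organism with its hit count, sorted by organism;
#' the counts sum to the number of hits (the "N hits in M genomes" style
#' of summary a mining run is reported by).
#'
#' @param hits a hit data.frame from [mineHits()].
#' @return data.frame with columns \code{organism}, \code{n_hits}.
#' @export
genomeSummary <- function(hits) {
    if (nrow(hits) == 0L)
        return(data.frame(organism = character(), n_hits = integer(),
                          stringsAsFactors = FALSE))
    tab <- table(hits$organism)
    orgs <- names(tab)
    ord <- .radixOrder(orgs)
    data.frame(organism = orgs[ord], n_hits = as.integer(tab)[ord],
               stringsAsFactors = FALSE)
}

## CSV renderings of sweep/histogram results (used by the CLI).
.writeSweepCsv <- function(sweep, path) {
    tb <- sweepTable(sweep)
    .writeCsv(list(.formatBp(tb$cutoff), as.character(tb$hits),
                   as.character(tb$genomes)),
              c("cutoff", "hits", "genomes"), path)
}
.writeHistogramCsv <- function(hist, path) {
    b <- histBins(hist)
    .writeCsv(list(.formatBp(b$lower), .formatBp(b$upper),
                   as.character(b$count)),
              c("lower", "upper", "count"), path)
}
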