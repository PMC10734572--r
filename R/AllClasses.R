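#' @import methods
NULL

## Canonical column set for gene records. start/stop are stored as doubles
## holding whole numbers (exact up to 2^53, far beyond any scaffold).
.GENE_COLS <- c("organism", "gene_id", "scaffold", "start", "stop",
                "evalue", "pct_identity", "description")
.GENE_KEY <- c("organism", "gene_id", "scaffold", "start", "stop")

#' GeneTable: a role-tagged collection of gene coordinate records
#'
#' A \code{GeneTable} holds one annotated-gene coordinate table, either the
#' resistance-gene homolog table (the algorithm's set R) or the core
#' secondary-metabolite backbone gene table (the set S). Records are
#' 1-based, fully closed genomic intervals on named scaffolds of named
#' organisms, optionally carrying the E-value and percent identity of the
#' sequence search that produced them.
#'
#' @slot role either \code{"resistance"} or \code{"sm_core"}.
#' @slot backboneClass optional free-text label for sm_core tables
#'   (e.g. \code{"NRPS"}, \code{"PKS"}); \code{NA} when unset.
#' @slot records a \code{data.frame} with columns \code{organism},
#'   \code{gene_id}, \code{scaffold}, \code{start}, \code{stop},
#'   \code{evalue}, \code{pct_identity}, \code{description}.
#' @slot source provenance string: the input path, or \code{"synthetic"} /
#'   \code{"in-memory"}.
#'
#' @seealso [GeneTable()], [readGeneTable()], [writeGeneTable()]
#' @exportClass GeneTable
setClass("GeneTable",
    representation(role = "character",
                   backboneClass = "character",
                   records = "data.frame",
                   source = "character"))

setValidity("GeneTable", function(object) {
    msgs <- character()
    if (length(object@role) != 1L ||
        !object@role %in% c("resistance", "sm_core"))
        msgs <- c(msgs, "role must be 'resistance' or 'sm_core'")
    rec <- object@records
    if (!all(.GENE_COLS %in% names(rec)))
        msgs <- c(msgs, paste("records must have columns:",
                              paste(.GENE_COLS, collapse = ", ")))
    else if (nrow(rec) > 0L) {
        if (any(!is.finite(rec$start)) || any(!is.finite(rec$stop)))
            msgs <- c(msgs, "start/stop must be finite")
        else {
            if (any(rec$start < 1) || any(rec$start > rec$stop))
                msgs <- c(msgs, "coordinates must satisfy 1 <= start <= stop")
            if (any(rec$start != floor(rec$start)) ||
                any(rec$stop != floor(rec$stop)))
                msgs <- c(msgs, "start/stop must be whole numbers")
        }
        for (f in c("organism", "gene_id", "scaffold")) {
            v <- rec[[f]]
            if (any(is.na(v)) || any(trimws(v) == ""))
                msgs <- c(msgs, paste(f, "must be non-empty"))
        }
        ev <- rec$evalue
        if (any(ev[!is.na(ev)] < 0))
            msgs <- c(msgs, "evalue must be >= 0 when present")
        pid <- rec$pct_identity
        if (any(pid[!is.na(pid)] < 0 | pid[!is.na(pid)] > 100))
            msgs <- c(msgs, "pct_identity must be in [0, 100] when present")
        key <- do.call(paste, c(rec[.GENE_KEY], sep = "\r"))
        if (anyDuplicated(key))
            msgs <- c(msgs,
                "duplicate (organism, gene_id, scaffold, start, stop) records")
    }
    if (length(msgs)) msgs else TRUE
})

#' MinerConfig: run parameters for the proximity join
#'
#' @slot cutoff center-to-center distance cutoff C in base pairs; a pair is
#'   a hit only if the gene centers are at most C apart. 70000 bp is the
#'   working value recommended for fungal BGC mining.
#' @slot maxGeneLength maximum resistance-gene length M in base pairs
#'   (\code{Inf} = unlimited, the default).
#' @slot singletonCheck when \code{TRUE} (default) genomes with fewer than
#'   two resistance-gene copies are discarded before the join; \code{FALSE}
#'   is the "nocheck" waiver.
#' @slot homologMode when \code{TRUE}, callers are expected to collect the
#'   homolog table of every hit genome (see [collectHomologs()]).
#'
#' @seealso [MinerConfig()], [mineHits()]
#' @exportClass MinerConfig
setClass("MinerConfig",
    representation(cutoff = "numeric",
                   maxGeneLength = "numeric",
                   singletonCheck = "logical",
                   homologMode = "logical"))

setValidity("MinerConfig", function(object) {
    msgs <- character()
    if (length(object@cutoff) != 1L || is.na(object@cutoff) ||
        object@cutoff < 1)
        msgs <- c(msgs, "cutoff must be a single value >= 1")
    m <- object@maxGeneLength
    if (length(m) != 1L || is.na(m) || (is.finite(m) && m < 1))
        msgs <- c(msgs, "maxGeneLength must be >= 1 or Inf")
    if (length(object@singletonCheck) != 1L || is.na(object@singletonCheck))
        msgs <- c(msgs, "singletonCheck must be TRUE or FALSE")
    if (length(object@homologMode) != 1L || is.na(object@homologMode))
        msgs <- c(msgs, "homologMode must be TRUE or FALSE")
    if (length(msgs)) msgs else TRUE
})

#' FixtureSpec: parameters of a synthetic genome-annotation set
#'
#' Describes a reproducible synthetic gene-coordinate fixture: a number of
#' genomes each with several scaffolds, planted resistance/SM gene pairs at
#' exact center distances, four classes of decoy genes each violating
#' exactly one mining predicate, background genes kept out of range by
#' rejection sampling, and the (cutoff, maxGeneLength) at which the
#' construction-time truth is stated.
#'
#' @slot nGenomes number of genomes.
#' @slot scaffoldsPerGenome scaffolds per genome.
#' @slot scaffoldLength scaffold length in base pairs.
#' @slot nBackgroundSm background SM backbone genes, placed more than
#'   \code{cutoff} from every resistance-gene center.
#' @slot nBackgroundResistance background resistance homologs, placed more
#'   than \code{cutoff} from every SM gene center (emulates the bulk of a
#'   database-wide homolog table, which is nowhere near a BGC).
#' @slot plantedPairs list of planted pairs, see [plantedPair()].
#' @slot decoys named integer counts for the classes
#'   \code{singleton_near}, \code{far_pair}, \code{overlapping_pair},
#'   \code{oversized_resistance}.
#' @slot geneLengthRange min/max sampled gene length, base pairs.
#' @slot cutoff,maxGeneLength the (C, M) at which the truth set is stated.
#' @slot seed integer seed; equal specs generate byte-identical tables.
#'
#' @seealso [fixtureSpec()], [generateFixture()]
#' @exportClass FixtureSpec
setClass("FixtureSpec",
    representation(nGenomes = "numeric",
                   scaffoldsPerGenome = "numeric",
                   scaffoldLength = "numeric",
                   nBackgroundSm = "numeric",
                   nBackgroundResistance = "numeric",
                   plantedPairs = "list",
                   decoys = "numeric",
                   geneLengthRange = "numeric",
                   cutoff = "numeric",
                   maxGeneLength = "numeric",
                   seed = "numeric"))

.DECOY_CLASSES <- c("singleton_near", "far_pair", "overlapping_pair",
                    "oversized_resistance")

setValidity("FixtureSpec", function(object) {
    msgs <- character()
    for (f in c("nGenomes", "scaffoldsPerGenome", "scaffoldLength"))
        if (slot(object, f) < 1) msgs <- c(msgs, paste(f, "must be >= 1"))
    if (object@nBackgroundSm < 0 || object@nBackgroundResistance < 0)
        msgs <- c(msgs, "background gene counts must be >= 0")
    if (!identical(sort(names(object@decoys)), sort(.DECOY_CLASSES)))
        msgs <- c(msgs, paste("decoys must be a named count vector over:",
                              paste(.DECOY_CLASSES, collapse = ", ")))
    else if (any(object@decoys < 0))
        msgs <- c(msgs, "decoy counts must be >= 0")
    glr <- object@geneLengthRange
    if (length(glr) != 2L || glr[1] < 1 || glr[1] > glr[2])
        msgs <- c(msgs, "geneLengthRange must be c(min, max) with min >= 1")
    if (object@cutoff < 1)
        msgs <- c(msgs, "cutoff must be >= 1")
    m <- object@maxGeneLength
    if (is.na(m) || (is.finite(m) && m < 1))
        msgs <- c(msgs, "maxGeneLength must be >= 1 or Inf")
    if (!is.finite(m) && object@decoys[["oversized_resistance"]] > 0)
        msgs <- c(msgs,
            "oversized_resistance decoys require a finite maxGeneLength")
    for (pp in object@plantedPairs) {
        ok <- .checkPlantedPair(pp, object)
        if (!isTRUE(ok)) { msgs <- c(msgs, ok); break }
    }
    if (length(msgs)) msgs else TRUE
})

#' TruthSet: construction-time ground truth of a synthetic fixture
#'
#' @slot pairs data.frame of the hits a default-configuration run at the
#'   stated (cutoff, maxGeneLength) must recover: columns \code{organism},
#'   \code{resistance_gene_id}, \code{sm_gene_id}, \code{center_distance}.
#' @slot decoys data.frame labelling every decoy resistance gene: columns
#'   \code{gene_id}, \code{organism}, \code{class}, \code{partner_sm_id},
#'   \code{center_distance} (partner columns NA for unpaired decoys).
#' @slot cutoff,maxGeneLength the (C, M) the truth is stated at.
#'
#' @exportClass TruthSet
setClass("TruthSet",
    representation(pairs = "data.frame",
                   decoys = "data.frame",
                   cutoff = "numeric",
                   maxGeneLength = "numeric"))

#' HistogramResult: hit counts binned by center distance
#'
#' Half-open bins \code{[0,w), [w,2w), ...} contiguous from zero up to the
#' largest observed distance; every hit is counted exactly once.
#'
#' @slot binWidth bin width, base pairs.
#' @slot bins data.frame with columns \code{lower} (inclusive),
#'   \code{upper} (exclusive), \code{count}.
#' @slot total number of hits binned.
#'
#' @seealso [distanceHistogram()]
#' @exportClass HistogramResult
setClass("HistogramResult",
    representation(binWidth = "numeric", bins = "data.frame",
                   total = "integer"))

setValidity("HistogramResult", function(object) {
    b <- object@bins
    if (sum(b$count) != object@total)
        return("bin counts must sum to total")
    if (nrow(b) > 0L) {
        if (b$lower[1] != 0) return("bins must start at 0")
        if (any(b$upper - b$lower != object@binWidth))
            return("bins must all have width binWidth")
        if (nrow(b) > 1L && any(b$lower[-1] != b$upper[-nrow(b)]))
            return("bins must be contiguous")
    }
    TRUE
})

#' SweepResult: hit and genome counts across a ladder of distance cutoffs
#'
#' @slot cutoffs strictly increasing cutoff values, base pairs.
#' @slot counts hit count at each cutoff (non-decreasing).
#' @slot genomes distinct hit-genome count at each cutoff (non-decreasing).
#'
#' @seealso [cutoffSweep()]
#' @exportClass SweepResult
setClass("SweepResult",
    representation(cutoffs = "numeric", counts = "integer",
                   genomes = "integer"))

setValidity("SweepResult", function(object) {
    if (length(object@counts) != length(object@cutoffs) ||
        length(object@genomes) != length(object@cutoffs))
        return("counts and genomes must match cutoffs in length")
    if (is.unsorted(object@cutoffs, strictly = TRUE))
        return("cutoffs must be strictly increasing")
    if (is.unsorted(object@counts) || is.unsorted(object@genomes))
        return("counts and genomes must be non-decreasing")
    TRUE
})
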