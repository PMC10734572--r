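## Header alias sets for column inference, lowercased; header matching is
## case-insensitive with surrounding whitespace ignored.
.COLUMN_ALIASES <- list(
    organism     = c("organism", "portal", "genome", "species"),
    gene_id      = c("gene_id", "geneid", "proteinid", "protein id", "id",
                     "name"),
    scaffold     = c("scaffold", "contig", "chromosome", "chr"),
    start        = c("start", "gene start", "begin"),
    stop         = c("stop", "end", "gene stop"),
    evalue       = c("evalue", "e-value", "e value"),
    pct_identity = c("pct_identity", "percent identity", "identity",
                     "% identity"),
    description  = c("description")
)

.REQUIRED_FIELDS <- c("organism", "gene_id", "scaffold", "start", "stop")

## Coerce a loosely-specified data.frame to the canonical record schema:
## add missing optional columns as NA, order columns, type columns.
.canonicalRecords <- function(df) {
    for (col in c("evalue", "pct_identity"))
        if (is.null(df[[col]])) df[[col]] <- NA_real_
    if (is.null(df$description)) df$description <- NA_character_
    for (col in c("organism", "gene_id", "scaffold"))
        df[[col]] <- trimws(as.character(df[[col]]))
    df$description <- as.character(df$description)
    for (col in c("start", "stop", "evalue", "pct_identity"))
        df[[col]] <- as.numeric(df[[col]])
    df <- df[.GENE_COLS]
    rownames(df) <- NULL
    df
}

.emptyRecords <- function() {
    .canonicalRecords(data.frame(organism = character(),
                                 gene_id = character(),
                                 scaffold = character(),
                                 start = numeric(), stop = numeric()))
}

## Drop records sharing a (organism, gene_id, scaffold, start, stop) key,
## keeping the first occurrence; row order otherwise preserved.
.dedupRecords <- function(df) {
    key <- .pasteKey(df$organism, df$gene_id, df$scaffold, df$start, df$stop)
    df <- df[!duplicated(key), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Construct a GeneTable from a records data.frame
#'
#' Builds a validated [GeneTable-class] object. Required columns are
#' \code{organism}, \code{gene_id}, \code{scaffold}, \code{start},
#' \code{stop}; optional columns \code{evalue}, \code{pct_identity},
#' \code{description} are filled with \code{NA} when absent. Records that
#' duplicate another's (organism, gene_id, scaffold, start, stop) key are
#' collapsed to the first occurrence.
#'
#' @param records a data.frame of gene records.
#' @param role \code{"resistance"} or \code{"sm_core"}.
#' @param backboneClass optional backbone-class label (e.g. "NRPS").
#' @param source provenance string.
#' @return a \code{GeneTable}.
#' @examples
#' gt <- GeneTable(data.frame(organism = "orgA", gene_id = c("g1", "g2"),
#'                            scaffold = "scaf01",
#'                            start = c(100, 5000), stop = c(1200, 6200)),
#'                 role = "resistance")
#' geneLength(geneRecords(gt))
#' @export
GeneTable <- function(records, role = c("resistance", "sm_core"),
                      backboneClass = NA_character_, source = "in-memory") {
    role <- match.arg(role)
    miss <- setdiff(.REQUIRED_FIELDS, names(records))
    if (length(miss))
        stop("records lack required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    rec <- .dedupRecords(.canonicalRecords(records))
    new("GeneTable", role = role,
        backboneClass = as.character(backboneClass)[1],
        records = rec, source = as.character(source)[1])
}

#' Accessors for GeneTable slots
#'
#' @param x a [GeneTable-class].
#' @return \code{geneRecords}: the records data.frame; \code{tableRole},
#'   \code{tableSource}, \code{backboneClass}: length-one character.
#' @name GeneTable-accessors
#' @aliases geneRecords tableRole tableSource backboneClass
NULL

#' @rdname GeneTable-accessors
setMethod("geneRecords", "GeneTable", function(x) x@records)
#' @rdname GeneTable-accessors
setMethod("tableRole", "GeneTable", function(x) x@role)
#' @rdname GeneTable-accessors
setMethod("tableSource", "GeneTable", function(x) x@source)
#' @rdname GeneTable-accessors
setMethod("backboneClass", "GeneTable", function(x) x@backboneClass)

#' @export
setMethod("length", "GeneTable", function(x) nrow(x@records))

setMethod("show", "GeneTable", function(object) {
    rec <- object@records
    cat("GeneTable (role: ", object@role,
        if (!is.na(object@backboneClass))
            paste0(", class: ", object@backboneClass) else "",
        ")\n", sep = "")
    cat("  ", nrow(rec), " records across ",
        length(unique(rec$organism)), " organism(s)\n", sep = "")
    cat("  source: ", object@source, "\n", sep = "")
})

#' Read a gene-coordinate CSV table with flexible column inference
#'
#' Parses a genome-portal-style CSV export (header row mandatory,
#' comma-delimited, UTF-8). Column names are matched case-insensitively,
#' with surrounding whitespace ignored, against alias sets covering the
#' common portal export headers: e.g. \code{portal}/\code{genome}/
#' \code{species} all map to organism, \code{proteinId}/\code{name} to
#' gene_id, \code{contig}/\code{chromosome} to scaffold. E-values may use
#' scientific notation (\code{1E-40}). Rows identical in all mapped fields
#' are collapsed to one, first occurrence kept.
#'
#' Missing required columns abort with an error naming the missing field;
#' two columns mapping to the same field is an ambiguity error; malformed
#' rows (non-numeric or non-integral coordinates, start > stop, empty
#' identifiers) abort with the offending file line number rather than
#' being skipped, since silent row loss would silently change hit counts.
#'
#' @param path CSV file path.
#' @param role \code{"resistance"} or \code{"sm_core"}.
#' @param backboneClass optional backbone-class label for sm_core tables.
#' @return a [GeneTable-class].
#' @seealso [writeGeneTable()]
#' @export
readGeneTable <- function(path, role = c("resistance", "sm_core"),
                          backboneClass = NA_character_) {
    role <- match.arg(role)
    if (!file.exists(path))
        stop("file not found: '", path, "'", call. = FALSE)
    raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           blank.lines.skip = FALSE, encoding = "UTF-8")
    header <- tolower(trimws(names(raw)))
    colmap <- list()
    for (field in names(.COLUMN_ALIASES)) {
        idx <- which(header %in% .COLUMN_ALIASES[[field]])
        if (length(idx) > 1L)
            stop("unreadable table '", path, "': columns ",
                 paste(sQuote(names(raw)[idx]), collapse = " and "),
                 " both map to field '", field, "'", call. = FALSE)
        if (length(idx) == 1L) colmap[[field]] <- idx
    }
    miss <- setdiff(.REQUIRED_FIELDS, names(colmap))
    if (length(miss))
        stop("unreadable table '", path, "': no column found for ",
             paste(sQuote(miss), collapse = ", "), call. = FALSE)

    n <- nrow(raw)
    lineno <- seq_len(n) + 1L   # header is file line 1
    getcol <- function(field) {
        if (is.null(colmap[[field]])) return(rep(NA_character_, n))
        raw[[colmap[[field]]]]
    }
    parseNum <- function(field, integral = FALSE) {
        txt <- trimws(getcol(field))
        txt[txt == ""] <- NA_character_
        val <- suppressWarnings(as.numeric(txt))
        bad <- !is.na(txt) & is.na(val)
        if (integral) bad <- bad | (!is.na(val) & val != floor(val))
        if (any(bad))
            stop("parse error in '", path, "' line ", lineno[which(bad)[1]],
                 ": invalid ", field, " value '", txt[which(bad)[1]], "'",
                 call. = FALSE)
        val
    }
    df <- data.frame(organism = trimws(getcol("organism")),
                     gene_id = trimws(getcol("gene_id")),
                     scaffold = trimws(getcol("scaffold")),
                     start = parseNum("start", integral = TRUE),
                     stop = parseNum("stop", integral = TRUE),
                     evalue = parseNum("evalue"),
                     pct_identity = parseNum("pct_identity"),
                     description = getcol("description"),
                     stringsAsFactors = FALSE)
    df$description[!is.na(df$description) & df$description == ""] <-
        NA_character_

    for (field in .REQUIRED_FIELDS[1:3]) {
        bad <- is.na(df[[field]]) | df[[field]] == ""
        if (any(bad))
            stop("validation error in '", path, "' line ",
                 lineno[which(bad)[1]], ": empty ", field, call. = FALSE)
    }
    bad <- is.na(df$start) | is.na(df$stop)
    if (any(bad))
        stop("parse error in '", path, "' line ", lineno[which(bad)[1]],
             ": missing start/stop", call. = FALSE)
    bad <- df$start > df$stop | df$start < 1
    if (any(bad))
        stop("validation error in '", path, "' line ", lineno[which(bad)[1]],
             ": start=", .formatBp(df$start[which(bad)[1]]),
             " stop=", .formatBp(df$stop[which(bad)[1]]),
             " violates 1 <= start <= stop", call. = FALSE)
    GeneTable(df, role = role, backboneClass = backboneClass, source = path)
}

#' Write a GeneTable as canonical CSV
#'
#' Writes the fixed header
#' \code{organism,gene_id,scaffold,start,stop,evalue,pct_identity,description}
#' with unset optional fields as empty cells (never "0"). Reading the file
#' back with [readGeneTable()] reproduces the table's mapped fields.
#'
#' @param table a [GeneTable-class].
#' @param path output file path.
#' @return invisibly \code{NULL}.
#' @rdname writeGeneTable
#' @export
setMethod("writeGeneTable", signature(table = "GeneTable", path = "character"),
    function(table, path) {
        rec <- geneRecords(table)
        .writeCsv(list(rec$organism, rec$gene_id, rec$scaffold,
                       .formatBp(rec$start), .formatBp(rec$stop),
                       .formatNum(rec$evalue), .formatNum(rec$pct_identity),
                       rec$description),
                  .GENE_COLS, path)
    })

#' Doubled interval center of gene records
#'
#' Returns \code{start + stop}: exactly twice the interval midpoint, as an
#' integer-valued number. All distance comparisons in the miner are done on
#' doubled coordinates (|2c_r - 2c_s| vs 2C) so half-integer centers never
#' require floating-point arithmetic and results are bit-exact on every
#' platform.
#'
#' @param g a records data.frame (one or more rows), or a [GeneTable-class].
#' @return numeric vector of doubled centers.
#' @examples
#' centerTimesTwo(data.frame(organism = "a", gene_id = "g", scaffold = "s",
#'                           start = 100, stop = 300))  # 400: midpoint 200
#' @export
centerTimesTwo <- function(g) {
    if (is(g, "GeneTable")) g <- geneRecords(g)
    g$start + g$stop
}

#' Gene length in base pairs
#'
#' \code{stop - start + 1}: the 1-based fully-closed interval convention,
#' under which a single-base gene has length 1.
#'
#' @inheritParams centerTimesTwo
#' @return numeric vector of lengths (all >= 1 for valid records).
#' @export
geneLength <- function(g) {
    if (is(g, "GeneTable")) g <- geneRecords(g)
    g$stop - g$start + 1
}

#' Do two gene records overlap?
#'
#' \code{TRUE} iff the records are on the same scaffold of the same
#' organism and their closed intervals share at least one base. A gene
#' always overlaps itself, so identical records can never form a hit pair.
#' Vectorized elementwise with the usual recycling of one-row arguments.
#'
#' @param a,b records data.frames (or [GeneTable-class]s of equal length,
#'   or one of length 1).
#' @return logical vector.
#' @export
genesOverlap <- function(a, b) {
    if (is(a, "GeneTable")) a <- geneRecords(a)
    if (is(b, "GeneTable")) b <- geneRecords(b)
    a$organism == b$organism & a$scaffold == b$scaffold &
        a$start <= b$stop & b$start <= a$stop
}
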