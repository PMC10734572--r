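#' @rdname GeneTable-accessors
#' @export
setGeneric("geneRecords", function(x) standardGeneric("geneRecords"))

#' @rdname GeneTable-accessors
#' @export
setGeneric("tableRole", function(x) standardGeneric("tableRole"))

#' @rdname GeneTable-accessors
#' @export
setGeneric("tableSource", function(x) standardGeneric("tableSource"))

#' @rdname GeneTable-accessors
#' @export
setGeneric("backboneClass", function(x) standardGeneric("backboneClass"))

#' @rdname writeGeneTable
#' @export
setGeneric("writeGeneTable",
           function(table, path) standardGeneric("writeGeneTable"))

#' @rdname eliminateSingletons
#' @export
setGeneric("eliminateSingletons",
           function(rTable) standardGeneric("eliminateSingletons"))

#' @rdname mineHits
#' @export
setGeneric("mineHits",
           function(rTable, sTable, config) standardGeneric("mineHits"))

#' @rdname bruteForceMine
#' @export
setGeneric("bruteForceMine",
           function(rTable, sTable, config) standardGeneric("bruteForceMine"))

#' @rdname collectHomologs
#' @export
setGeneric("collectHomologs",
           function(hits, rTable) standardGeneric("collectHomologs"))

#' @rdname generateFixture
#' @export
setGeneric("generateFixture",
           function(spec) standardGeneric("generateFixture"))

#' @rdname TruthSet-accessors
#' @export
setGeneric("truthPairs", function(x) standardGeneric("truthPairs"))

#' @rdname TruthSet-accessors
#' @export
setGeneric("truthDecoys", function(x) standardGeneric("truthDecoys"))

#' @rdname HistogramResult-accessors
#' @export
setGeneric("histBins", function(x) standardGeneric("histBins"))

#' @rdname SweepResult-accessors
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))
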