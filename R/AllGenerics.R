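#' @include AllClasses.R
NULL

#' Accessors for essalign containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an essalign S4 object.
#' @return The underlying data.frame, vector or scalar, as documented per
#'   method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("essEntries", function(x) standardGeneric("essEntries"))

#' @rdname accessors
#' @export
setGeneric("nrSequences", function(x) standardGeneric("nrSequences"))

#' @rdname accessors
#' @export
setGeneric("nrProvenance", function(x) standardGeneric("nrProvenance"))

#' @rdname accessors
#' @export
setGeneric("alignmentRecords", function(x) standardGeneric("alignmentRecords"))

#' @rdname accessors
#' @export
setGeneric("alignmentSettings", function(x) standardGeneric("alignmentSettings"))

#' @rdname accessors
#' @export
setGeneric("ecCatalogue", function(x) standardGeneric("ecCatalogue"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname accessors
#' @export
setGeneric("alignmentCost", function(x) standardGeneric("alignmentCost"))

#' @rdname accessors
#' @export
setGeneric("alignmentColumns", function(x) standardGeneric("alignmentColumns"))

#' @rdname accessors
#' @export
setGeneric("scanHits", function(x) standardGeneric("scanHits"))

#' @rdname accessors
setMethod("essEntries", "ESSDatabase", function(x) x@entries)

#' @rdname accessors
setMethod("nrSequences", "NRESSDatabase", function(x) x@sequences)

#' @rdname accessors
setMethod("nrProvenance", "NRESSDatabase", function(x) x@provenance)

#' @rdname accessors
setMethod("alignmentRecords", "AlignmentTable", function(x) x@records)

#' @rdname accessors
setMethod("alignmentSettings", "AlignmentTable", function(x) x@settings)

#' @rdname accessors
setMethod("alignmentSettings", "NullEnsemble", function(x) x@settings)

#' @rdname accessors
setMethod("ecCatalogue", "ECWeightMatrix", function(x) x@catalogue)

#' @rdname accessors
setMethod("graphNodes", "MetabolicGraph", function(x) x@nodes)

#' @rdname accessors
setMethod("graphEdges", "MetabolicGraph", function(x) x@edges)

#' @rdname accessors
setMethod("alignmentScore", "ESSAlignment", function(x) x@score)

#' @rdname accessors
setMethod("alignmentCost", "ESSAlignment", function(x) x@cost)

#' @rdname accessors
setMethod("alignmentColumns", "ESSAlignment", function(x)
  data.frame(a = x@aCols, b = x@bCols, stringsAsFactors = FALSE))

#' @rdname accessors
setMethod("scanHits", "ScanResult", function(x) x@hits)

#' Distance matrix of an ECWeightMatrix
#'
#' @param x an \linkS4class{ECWeightMatrix}.
#' @param ... ignored.
#' @return the numeric distance matrix with EC dimnames.
#' @export
setMethod("as.matrix", "ECWeightMatrix", function(x, ...) x@dist)

setMethod("show", "PathwayModel", function(object) {
  cat(sprintf("PathwayModel %s%s: %d reactions, %d cross-map compounds\n",
              object@organism, object@mapId, length(object@reactions),
              length(object@compoundLinks)))
})

setMethod("show", "MetabolicGraph", function(object) {
  cat(sprintf("MetabolicGraph: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "ESSDatabase", function(object) {
  e <- object@entries
  cat(sprintf("ESSDatabase: %d ESS from %d organisms x %d maps (%d zero-yield maps)\n",
              nrow(e), length(unique(e$organism)),
              length(unique(paste(e$organism, e$map_id))),
              nrow(object@zeroYield)))
})

setMethod("show", "NRESSDatabase", function(object) {
  cat(sprintf("NRESSDatabase: %d non-redundant ESS, %d provenance records\n",
              nrow(object@sequences), nrow(object@provenance)))
})

setMethod("show", "ECWeightMatrix", function(object) {
  cat(sprintf("ECWeightMatrix (%s): %d x %d EC catalogue\n",
              object@mode, length(object@catalogue), length(object@catalogue)))
})

setMethod("show", "ESSAlignment", function(object) {
  gap <- function(v) ifelse(is.na(v), "-----", sprintf("%-5s", v))
  cat(sprintf("ESSAlignment: cost %.4f over %d columns, score %.4f\n",
              object@cost, length(object@aCols), object@score))
  cat(" a:", paste(gap(object@aCols), collapse = " "), "\n")
  cat(" b:", paste(gap(object@bCols), collapse = " "), "\n")
})

setMethod("show", "AlignmentTable", function(object) {
  s <- object@settings
  cat(sprintf("AlignmentTable: %d stored records of %s pairs (matrix %s, gap %s, ceiling %s)\n",
              nrow(object@records),
              format(s$n_pairs %||% NA), s$matrix_mode %||% "?",
              format(s$gap %||% NA), format(s$keep_ceiling %||% NA)))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble: %d shuffled replicates, %s scores each\n",
              length(object@scores),
              if (length(object@scores)) length(object@scores[[1]]) else 0))
})

setMethod("show", "ScoreHistogram", function(object) {
  cat(sprintf("ScoreHistogram: %d scores in %d bins of width %.3g\n",
              object@total, length(object@counts), object@binWidth))
})

setMethod("show", "MapSimilarityMatrix", function(object) {
  cat(sprintf("MapSimilarityMatrix: %d maps, %d nonzero cells\n",
              length(object@maps), sum(object@counts > 0)))
})

setMethod("show", "MapConservationReport", function(object) {
  cat(sprintf("Map %s: %d/%d ECs conserved (%.1f%%) -> %s\n",
              object@mapId, length(object@conservedEcs),
              length(object@cladeEcs), 100 * object@proportion,
              object@category))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult '%s': %d hits at score <= %.3g over %d maps\n",
              object@queryId, nrow(object@hits), object@threshold,
              length(object@perMap)))
})
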