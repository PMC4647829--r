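#' @import methods
NULL

#' PathwayModel: an in-memory KGML pathway
#'
#' Holds the reactions of one organism x map pathway as parsed from a KGML
#' document, together with the set of compounds annotated as entering from
#' other maps.
#'
#' @slot organism single character, short organism code (e.g. \code{"eco"}).
#' @slot mapId single character, 5-digit pathway identifier (e.g. \code{"00010"}).
#' @slot reactions list of reaction entries; each element is a list with
#'   components \code{reaction_id}, \code{ec_labels} (character, possibly
#'   empty), \code{substrates}, \code{products} (character, compound ids) and
#'   \code{reversible} (logical).
#' @slot compoundLinks character vector of compound ids annotated as imported
#'   from another metabolic map.
#' @exportClass PathwayModel
setClass("PathwayModel",
  representation(
    organism = "character",
    mapId = "character",
    reactions = "list",
    compoundLinks = "character"
  )
)

setValidity("PathwayModel", function(object) {
  msg <- character()
  if (length(object@mapId) != 1L || !nzchar(object@mapId))
    msg <- c(msg, "mapId must be a single nonempty string")
  ids <- vapply(object@reactions, function(r) r$reaction_id, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "reaction ids must be unique within a pathway")
  for (r in object@reactions) {
    if (length(r$substrates) == 0L || length(r$products) == 0L)
      msg <- c(msg, sprintf("reaction '%s' lacks substrates or products",
                            r$reaction_id))
  }
  if (length(msg)) msg else TRUE
})

#' MetabolicGraph: the directed enzyme graph of one pathway
#'
#' Nodes are (reaction, EC) pairs; a directed edge u -> v labelled with
#' compound c exists when c is a product of u's reaction and a substrate of
#' v's reaction (reversible reactions contribute both orientations through
#' the same node). Self-loops and edges between nodes of the same reaction
#' are excluded.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{ec},
#'   \code{reaction_id}.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{compound}.
#' @slot compoundLinks character, cross-map compound ids inherited from the
#'   parsed model (needed for root selection).
#' @slot produced,consumed named lists (by reaction id) of the compounds each
#'   reaction produces / consumes after reversible expansion; kept so root
#'   selection can reason about pathway chemistry.
#' @exportClass MetabolicGraph
setClass("MetabolicGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    compoundLinks = "character",
    produced = "list",
    consumed = "list"
  )
)

setValidity("MetabolicGraph", function(object) {
  msg <- character()
  if (!all(c("node_id", "ec", "reaction_id") %in% names(object@nodes)))
    msg <- c(msg, "nodes needs columns node_id, ec, reaction_id")
  if (!all(c("from", "to", "compound") %in% names(object@edges)))
    msg <- c(msg, "edges needs columns from, to, compound")
  if (nrow(object@edges) && any(object@edges$from == object@edges$to))
    msg <- c(msg, "self-loop edges are not allowed")
  if (nrow(object@edges)) {
    known <- object@nodes$node_id
    if (!all(object@edges$from %in% known) || !all(object@edges$to %in% known))
      msg <- c(msg, "edges reference unknown nodes")
  }
  if (length(msg)) msg else TRUE
})

#' BFSTree: a breadth-first search tree over a MetabolicGraph
#'
#' @slot root single character node id.
#' @slot parent named character vector mapping each non-root visited node to
#'   its parent node id.
#' @slot leaves character vector of tree nodes without children.
#' @exportClass BFSTree
setClass("BFSTree",
  representation(root = "character", parent = "character", leaves = "character")
)

#' ESSDatabase: redundant Enzymatic Step Sequences with provenance
#'
#' One row per extracted root-to-leaf sequence. EC tuples are stored as
#' semicolon-joined 3-level strings (the interchange encoding).
#'
#' @slot entries data.frame with columns \code{organism}, \code{map_id},
#'   \code{root}, \code{leaf}, \code{ecs}.
#' @slot zeroYield data.frame of (organism, map_id) pairs that produced no
#'   sequence.
#' @slot skipped character vector of unreadable input files (empty unless a
#'   non-strict build skipped inputs).
#' @exportClass ESSDatabase
setClass("ESSDatabase",
  representation(entries = "data.frame", zeroYield = "data.frame",
                 skipped = "character")
)

setValidity("ESSDatabase", function(object) {
  need <- c("organism", "map_id", "root", "leaf", "ecs")
  if (!all(need %in% names(object@entries)))
    return(sprintf("entries needs columns %s", paste(need, collapse = ", ")))
  TRUE
})

#' NRESSDatabase: the non-redundant ESS database
#'
#' Identical EC tuples (order-sensitive) are collapsed to one representative;
#' the provenance of every collapsed original is retained.
#'
#' @slot sequences data.frame with columns \code{nr_id}, \code{ecs}
#'   (semicolon-joined EC tuple).
#' @slot provenance data.frame with columns \code{nr_id}, \code{organism},
#'   \code{map_id}; one row per distinct (nr_id, organism, map) combination.
#' @exportClass NRESSDatabase
setClass("NRESSDatabase",
  representation(sequences = "data.frame", provenance = "data.frame")
)

setValidity("NRESSDatabase", function(object) {
  msg <- character()
  if (!all(c("nr_id", "ecs") %in% names(object@sequences)))
    msg <- c(msg, "sequences needs columns nr_id, ecs")
  if (!all(c("nr_id", "organism", "map_id") %in% names(object@provenance)))
    msg <- c(msg, "provenance needs columns nr_id, organism, map_id")
  if (anyDuplicated(object@sequences$ecs))
    msg <- c(msg, "EC tuples must be pairwise distinct")
  if (anyDuplicated(object@sequences$nr_id))
    msg <- c(msg, "nr ids must be unique")
  if (nrow(object@provenance) &&
      !all(object@provenance$nr_id %in% object@sequences$nr_id))
    msg <- c(msg, "provenance references unknown nr ids")
  if (length(msg)) msg else TRUE
})

#' ECWeightMatrix: pairwise EC distances respecting the EC hierarchy
#'
#' Distances lie in [0, 1]; identical ECs have distance 0; ECs differing in
#' the first classification level have distance 1; the 9.9.9 unknown sentinel
#' is similar only to itself.
#'
#' @slot catalogue character vector of canonical 3-level EC strings
#'   (always includes \code{"9.9.9"}).
#' @slot mode \code{"uniform"} or \code{"entropy"}.
#' @slot dist numeric matrix of distances with catalogue dimnames.
#' @exportClass ECWeightMatrix
setClass("ECWeightMatrix",
  representation(catalogue = "character", mode = "character", dist = "matrix")
)

setValidity("ECWeightMatrix", function(object) {
  msg <- character()
  d <- object@dist
  if (!identical(rownames(d), object@catalogue) ||
      !identical(colnames(d), object@catalogue))
    msg <- c(msg, "dist dimnames must equal the catalogue")
  if (!"9.9.9" %in% object@catalogue)
    msg <- c(msg, "catalogue must include the 9.9.9 sentinel")
  if (nrow(d)) {
    if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "d(x,x) must be 0")
    if (max(abs(d - t(d))) > 1e-12) msg <- c(msg, "distances must be symmetric")
    if (min(d) < -1e-12 || max(d) > 1 + 1e-12)
      msg <- c(msg, "distances must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' ESSAlignment: a single global alignment of two EC sequences
#'
#' @slot aCols,bCols character vectors of equal length giving the aligned
#'   columns; \code{NA} marks a gap. No column is gap/gap.
#' @slot cost total alignment cost (sum of column costs).
#' @slot score normalized score, cost divided by the number of columns.
#' @exportClass ESSAlignment
setClass("ESSAlignment",
  representation(aCols = "character", bCols = "character",
                 cost = "numeric", score = "numeric")
)

setValidity("ESSAlignment", function(object) {
  msg <- character()
  if (length(object@aCols) != length(object@bCols))
    msg <- c(msg, "aligned rows must have equal length")
  if (any(is.na(object@aCols) & is.na(object@bCols)))
    msg <- c(msg, "no column may be gap/gap")
  if (length(msg)) msg else TRUE
})

#' AlignmentTable: sparse unordered-pair scores over an nrESS database
#'
#' @slot records data.frame with columns \code{i}, \code{j} (nr ids,
#'   \code{i < j} lexicographically), \code{score}.
#' @slot settings list recording how scores were produced
#'   (\code{matrix_mode}, \code{gap}, \code{keep_ceiling}, \code{n}, and the
#'   total number of pairs scored \code{n_pairs}).
#' @exportClass AlignmentTable
setClass("AlignmentTable",
  representation(records = "data.frame", settings = "list")
)

setValidity("AlignmentTable", function(object) {
  msg <- character()
  if (!all(c("i", "j", "score") %in% names(object@records)))
    msg <- c(msg, "records needs columns i, j, score")
  r <- object@records
  if (nrow(r)) {
    if (any(r$i == r$j)) msg <- c(msg, "self pairs are not allowed")
    if (anyDuplicated(paste(r$i, r$j))) msg <- c(msg, "duplicate pairs")
  }
  if (length(msg)) msg else TRUE
})

#' NullEnsemble: alignment scores of shuffled null databases
#'
#' @slot scores list of numeric vectors, one per shuffled replicate, holding
#'   every unordered-pair alignment score of that replicate.
#' @slot seeds integer vector of the per-replicate shuffle seeds.
#' @slot settings list with the alignment settings shared by all replicates
#'   (must match the real run they are compared with).
#' @exportClass NullEnsemble
setClass("NullEnsemble",
  representation(scores = "list", seeds = "integer", settings = "list")
)

#' ScoreHistogram: binned alignment scores on [0, 1]
#'
#' Bins are half-open [x, x + w) tiling [0, 1]; the final bin is closed at 1.
#'
#' @slot binWidth single numeric bin width.
#' @slot counts integer vector of per-bin counts, named by bin left edge.
#' @slot total integer, total number of scores binned.
#' @exportClass ScoreHistogram
setClass("ScoreHistogram",
  representation(binWidth = "numeric", counts = "integer", total = "integer")
)

setValidity("ScoreHistogram", function(object) {
  if (sum(object@counts) != object@total)
    return("counts must sum to total")
  TRUE
})

#' MapSimilarityMatrix: shared significant alignments between map pairs
#'
#' @slot maps character vector of map ids (row/column order).
#' @slot counts symmetric integer matrix of shared significant alignments.
#' @slot normalized row-normalized real matrix (all-zero rows preserved).
#' @exportClass MapSimilarityMatrix
setClass("MapSimilarityMatrix",
  representation(maps = "character", counts = "matrix", normalized = "matrix")
)

setValidity("MapSimilarityMatrix", function(object) {
  msg <- character()
  if (nrow(object@counts) &&
      max(abs(object@counts - t(object@counts))) > 1e-9)
    msg <- c(msg, "counts must be symmetric")
  rs <- rowSums(object@normalized)
  bad <- abs(rs - 1) > 1e-8 & rs != 0
  if (any(bad)) msg <- c(msg, "normalized rows must sum to 1 (or be all zero)")
  if (length(msg)) msg else TRUE
})

#' MapConservationReport: conserved-EC proportion and category for one map
#'
#' @slot mapId single character map id.
#' @slot conservedEcs character, ECs occurring in identical non-gap aligned
#'   columns of the map's MMFCD alignments (9.9.9 excluded).
#' @slot cladeEcs character, all ECs carried by the map's sequences
#'   (9.9.9 excluded).
#' @slot proportion conserved / clade proportion in [0, 1].
#' @slot category one of \code{"conserved"}, \code{"moderately"},
#'   \code{"barely"}, \code{"non_conserved"}.
#' @exportClass MapConservationReport
setClass("MapConservationReport",
  representation(mapId = "character", conservedEcs = "character",
                 cladeEcs = "character", proportion = "numeric",
                 category = "character")
)

#' ScanResult: significant hits of one query ESS against an nrESS database
#'
#' @slot queryId single character label for the query.
#' @slot hits data.frame with columns \code{nr_id}, \code{score},
#'   \code{maps} (comma-joined provenance maps).
#' @slot perMap named integer vector of hit counts per target map
#'   (multi-map provenance counted once per map).
#' @slot sameMapFraction fraction of hits sharing a map with the query
#'   (NA when the query's maps are unknown).
#' @slot threshold the score threshold applied.
#' @exportClass ScanResult
setClass("ScanResult",
  representation(queryId = "character", hits = "data.frame",
                 perMap = "integer", sameMapFraction = "numeric",
                 threshold = "numeric")
)
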