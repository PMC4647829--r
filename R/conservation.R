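#' Functionally conserved nrESS pairs
#'
#' A pair of sequences is functionally conserved when its alignment score is
#' at or below the operating threshold and, in conjunction, the pair is
#' present in more than \code{coverageThreshold} of the organism panel. By
#' default "present" is judged on the union of the two sequences' provenance
#' organism sets (the pair jointly covers the panel); the stricter reading,
#' each sequence individually exceeding the coverage, is available with
#' \code{coverageMode = "each"}.
#'
#' @param table an \linkS4class{AlignmentTable}.
#' @param db the \linkS4class{NRESSDatabase} the table was built over.
#' @param scoreThreshold operating score threshold; default 0.3.
#' @param organismPanel character vector of the organism panel under study.
#' @param coverageThreshold fraction of the panel that must be exceeded
#'   (strictly); default 0.75.
#' @param coverageMode \code{"union"} (default) or \code{"each"}.
#' @return data.frame with columns \code{i}, \code{j}, \code{score},
#'   \code{organism_coverage}, \code{same_map} (logical), \code{shared_maps}
#'   (comma-joined, empty when none).
#' @export
conservedPairs <- function(table, db, scoreThreshold = 0.3, organismPanel,
                           coverageThreshold = 0.75,
                           coverageMode = c("union", "each")) {
  stopifnot(is(table, "AlignmentTable"), is(db, "NRESSDatabase"))
  coverageMode <- match.arg(coverageMode)
  if (!length(organismPanel)) stop("organism panel must be nonempty")
  prov <- db@provenance
  outside <- setdiff(unique(prov$organism), organismPanel)
  if (length(outside))
    stop(sprintf("provenance organisms outside the panel: %s",
                 paste(outside, collapse = ", ")), call. = FALSE)
  orgsOf <- lapply(split(prov$organism, prov$nr_id), unique)
  mapsOf <- lapply(split(prov$map_id, prov$nr_id), unique)

  r <- table@records
  r <- r[r$score <= scoreThreshold + 1e-12, , drop = FALSE]
  if (!nrow(r))
    return(data.frame(i = character(), j = character(), score = numeric(),
                      organism_coverage = numeric(), same_map = logical(),
                      shared_maps = character(), stringsAsFactors = FALSE))
  nPanel <- length(unique(organismPanel))
  cov <- vapply(seq_len(nrow(r)), function(k) {
    oi <- orgsOf[[r$i[k]]]; oj <- orgsOf[[r$j[k]]]
    if (coverageMode == "union")
      length(union(oi, oj)) / nPanel
    else
      min(length(oi), length(oj)) / nPanel
  }, numeric(1))
  keep <- cov > coverageThreshold
  r <- r[keep, , drop = FALSE]
  cov <- cov[keep]
  shared <- vapply(seq_len(nrow(r)), function(k)
    paste(sort(intersect(mapsOf[[r$i[k]]], mapsOf[[r$j[k]]])), collapse = ","),
    character(1))
  out <- data.frame(i = r$i, j = r$j, score = r$score,
                    organism_coverage = cov,
                    same_map = nzchar(shared), shared_maps = shared,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Restrict conserved pairs to the same-map subset (MMFCD)
#'
#' Keeps the conserved pairs whose two sequences share at least one map in
#' their provenance: the Metabolic Map Functional Conserved Dataset. A pair
#' sharing several maps contributes to every shared map.
#'
#' @param pairs output of \code{\link{conservedPairs}}.
#' @return the same-map subset of \code{pairs}.
#' @export
mmfcdPairs <- function(pairs) {
  pairs[pairs$same_map, , drop = FALSE]
}

#' Conserved-EC proportion and category of one metabolic map
#'
#' Realigns every MMFCD pair attributed to the map and collects the ECs that
#' occur in identical non-gap aligned columns (exact 3-level equality,
#' column cost 0); the \code{"9.9.9"} unknown sentinel never counts. The
#' clade EC set is the union of ECs over all the map's sequences in the
#' database (sentinel excluded). The proportion conserved/clade is
#' classified with \code{\link{classifyMap}}.
#'
#' @param pairs MMFCD pairs from \code{\link{mmfcdPairs}}.
#' @param db the \linkS4class{NRESSDatabase}.
#' @param mapId map to report on.
#' @param matrix,gap alignment settings (must match the table the pairs came
#'   from).
#' @return a \linkS4class{MapConservationReport}.
#' @export
mapConservation <- function(pairs, db, mapId, matrix, gap = 1.0) {
  stopifnot(is(db, "NRESSDatabase"), is(matrix, "ECWeightMatrix"))
  prov <- db@provenance
  mapSeqs <- unique(prov$nr_id[prov$map_id == mapId])
  sq <- setNames(db@sequences$ecs, db@sequences$nr_id)
  clade <- setdiff(unique(unlist(splitEcs(sq[mapSeqs]), use.names = FALSE)),
                   EC_UNKNOWN)
  if (!length(clade))
    stop(sprintf("map '%s' has no clade ECs in the database", mapId),
         call. = FALSE)
  inMap <- vapply(seq_len(nrow(pairs)), function(k)
    mapId %in% strsplit(pairs$shared_maps[k], ",", fixed = TRUE)[[1]],
    logical(1))
  conserved <- character()
  for (k in which(inMap)) {
    aln <- alignESS(sq[[pairs$i[k]]], sq[[pairs$j[k]]], matrix, gap)
    same <- !is.na(aln@aCols) & !is.na(aln@bCols) & aln@aCols == aln@bCols
    conserved <- union(conserved, setdiff(aln@aCols[same], EC_UNKNOWN))
  }
  conserved <- sort(intersect(conserved, clade))
  prop <- length(conserved) / length(clade)
  new("MapConservationReport", mapId = mapId, conservedEcs = conserved,
      cladeEcs = sort(clade), proportion = prop,
      category = classifyMap(prop))
}

#' Classify a conserved-EC proportion into the four conservation categories
#'
#' \code{>= 0.70}: conserved; \code{[0.30, 0.70)}: moderately;
#' \code{(0, 0.30)}: barely; exactly 0: non_conserved.
#'
#' @param proportion numeric in \code{[0, 1]}.
#' @return character vector of categories.
#' @export
classifyMap <- function(proportion) {
  if (any(is.na(proportion)) || any(proportion < 0) || any(proportion > 1))
    stop("proportion must lie in [0, 1]", call. = FALSE)
  vapply(proportion, function(p) {
    if (p >= 0.70) "conserved"
    else if (p >= 0.30) "moderately"
    else if (p > 0) "barely"
    else "non_conserved"
  }, character(1))
}

#' Per-map conservation summary table
#'
#' Runs \code{\link{mapConservation}} for every map appearing in the MMFCD
#' pairs (and optionally every map in the database).
#'
#' @inheritParams mapConservation
#' @param allMaps when TRUE, also report maps without any MMFCD pair
#'   (proportion 0, non_conserved).
#' @return data.frame \code{map_id, n_conserved_ecs, n_clade_ecs,
#'   proportion, category}.
#' @export
conservationTable <- function(pairs, db, matrix, gap = 1.0, allMaps = FALSE) {
  mapsInPairs <- unique(unlist(strsplit(pairs$shared_maps, ",", fixed = TRUE)))
  maps <- if (allMaps) sort(unique(db@provenance$map_id)) else
    sort(mapsInPairs[nzchar(mapsInPairs)])
  rows <- lapply(maps, function(m) {
    rep <- mapConservation(pairs, db, m, matrix, gap)
    data.frame(map_id = m, n_conserved_ecs = length(rep@conservedEcs),
               n_clade_ecs = length(rep@cladeEcs),
               proportion = rep@proportion, category = rep@category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(map_id = character(), n_conserved_ecs = integer(),
                      n_clade_ecs = integer(), proportion = numeric(),
                      category = character(), stringsAsFactors = FALSE)
  out
}
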