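#' Scan a query ESS against an nrESS database
#'
#' Aligns the query against every database sequence and keeps hits with
#' score at or below the threshold, grouped by the hits' provenance maps.
#' A hit with multi-map provenance contributes to every one of its maps, so
#' per-map counts can sum to more than the hit count (both totals are
#' reported).
#'
#' @param query character vector of 3-level EC strings (or one
#'   semicolon-joined string).
#' @param db an \linkS4class{NRESSDatabase}.
#' @param matrix an \linkS4class{ECWeightMatrix} covering query and database.
#' @param threshold score threshold; default 0.3.
#' @param gap linear gap cost; default 1.
#' @param queryId label for the query; default \code{"query"}.
#' @param queryMaps optional character vector of the maps the query belongs
#'   to, enabling the same-map fraction.
#' @return a \linkS4class{ScanResult}.
#' @export
scanQuery <- function(query, db, matrix, threshold = 0.3, gap = 1.0,
                      queryId = "query", queryMaps = NULL) {
  stopifnot(is(db, "NRESSDatabase"), is(matrix, "ECWeightMatrix"))
  if (length(query) == 1L && grepl(";", query)) query <- splitEcs(query)[[1]]
  if (!length(query)) stop("empty query", call. = FALSE)
  if (!nrow(db@sequences)) stop("empty database", call. = FALSE)
  cat <- matrix@catalogue
  q <- encodeSeq(query, cat)
  seqs <- lapply(splitEcs(db@sequences$ecs), encodeSeq, catalogue = cat)
  scores <- nw_score_query_cpp(q, seqs, matrix@dist, gap)
  keep <- scores <= threshold + 1e-12
  mapsOf <- lapply(split(db@provenance$map_id, db@provenance$nr_id), unique)
  hitIds <- db@sequences$nr_id[keep]
  hitMaps <- lapply(hitIds, function(id) sort(mapsOf[[id]] %||% character()))
  hits <- data.frame(nr_id = hitIds, score = scores[keep],
                     maps = vapply(hitMaps, paste, character(1),
                                   collapse = ","),
                     stringsAsFactors = FALSE)
  perMap <- table(unlist(hitMaps, use.names = FALSE))
  perMap <- setNames(as.integer(perMap), names(perMap))
  sameMap <- if (is.null(queryMaps) || !nrow(hits)) NA_real_ else
    mean(vapply(hitMaps, function(m) length(intersect(m, queryMaps)) > 0,
                logical(1)))
  new("ScanResult", queryId = queryId, hits = hits, perMap = perMap,
      sameMapFraction = sameMap, threshold = threshold)
}

#' Scan a query against shuffled null databases
#'
#' Rebuilds the null databases from the ensemble's seeds and counts the
#' query's hits at the threshold in each replicate. Refuses an ensemble
#' whose alignment settings differ from the requested scan settings.
#'
#' @param query as in \code{\link{scanQuery}}.
#' @param db the real \linkS4class{NRESSDatabase} (shuffled per replicate).
#' @param nulls the \linkS4class{NullEnsemble} whose seeds/settings to use.
#' @param matrix,threshold,gap as in \code{\link{scanQuery}}.
#' @return list with \code{counts} (per replicate) and \code{summary}
#'   (min, quartiles, median, max).
#' @export
scanNull <- function(query, db, nulls, matrix, threshold = 0.3, gap = 1.0) {
  stopifnot(is(nulls, "NullEnsemble"), is(matrix, "ECWeightMatrix"))
  s <- nulls@settings
  if (!identical(s$matrix_mode, matrix@mode) || !isTRUE(s$gap == gap))
    stop("null ensemble was built with different alignment settings",
         call. = FALSE)
  if (length(query) == 1L && grepl(";", query)) query <- splitEcs(query)[[1]]
  cat <- matrix@catalogue
  q <- encodeSeq(query, cat)
  counts <- vapply(nulls@seeds, function(seed) {
    null <- shuffleDatabase(db, seed)
    seqs <- lapply(splitEcs(null$sequences$ecs), encodeSeq, catalogue = cat)
    sum(nw_score_query_cpp(q, seqs, matrix@dist, gap) <= threshold + 1e-12)
  }, numeric(1))
  list(counts = as.integer(counts),
       summary = stats::quantile(counts, c(0, 0.25, 0.5, 0.75, 1)))
}

#' Occurrences of each query EC in the database token pool
#'
#' Diagnostic report contextualising scan hit counts: a query made of
#' globally abundant EC classes will match broadly for compositional
#' reasons.
#'
#' @param query character vector of EC strings (or one semicolon-joined
#'   string).
#' @param db an \linkS4class{NRESSDatabase}.
#' @return data.frame \code{ec, occurrences} sorted as in the query.
#' @export
queryOccurrenceReport <- function(query, db) {
  stopifnot(is(db, "NRESSDatabase"))
  if (length(query) == 1L && grepl(";", query)) query <- splitEcs(query)[[1]]
  pool <- unlist(splitEcs(db@sequences$ecs), use.names = FALSE)
  data.frame(ec = query,
             occurrences = vapply(query, function(e) sum(pool == e),
                                  numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read query sequences from a plain text file
#'
#' One sequence per line, semicolon-separated ECs; an optional leading
#' \code{id<TAB>} names the query, otherwise queries are numbered.
#'
#' @param path file path.
#' @return named list of EC character vectors.
#' @export
readQueryFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      out[[parts[1]]] <- parseEC(splitEcs(parts[2])[[1]])
    } else {
      out[[sprintf("query%02d", k)]] <- parseEC(splitEcs(parts[1])[[1]])
    }
  }
  out
}
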