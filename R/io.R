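#' Write an nrESS database in the TSV interchange format
#'
#' Columns: \code{nr_id}, semicolon-joined EC tuple, and the provenance as
#' comma-separated \code{org:map} tokens.
#'
#' @param db an \linkS4class{NRESSDatabase}.
#' @param path output path (extension \code{.json} switches to the JSON
#'   mirror with the same fields).
#' @return \code{path}, invisibly.
#' @export
writeNrDatabase <- function(db, path) {
  stopifnot(is(db, "NRESSDatabase"))
  prov <- db@provenance
  provStr <- vapply(db@sequences$nr_id, function(id) {
    p <- prov[prov$nr_id == id, , drop = FALSE]
    paste(sprintf("%s:%s", p$organism, p$map_id), collapse = ",")
  }, character(1))
  out <- data.frame(nr_id = db@sequences$nr_id, ecs = db@sequences$ecs,
                    provenance = provStr, stringsAsFactors = FALSE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE)
  } else {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an nrESS database from the TSV/JSON interchange format
#'
#' @param path path written by \code{\link{writeNrDatabase}}.
#' @return an \linkS4class{NRESSDatabase}.
#' @export
readNrDatabase <- function(path) {
  tab <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("nr_id", "ecs", "provenance") %in% names(tab)))
  prov <- do.call(rbind, lapply(seq_len(nrow(tab)), function(k) {
    toks <- strsplit(tab$provenance[k], ",", fixed = TRUE)[[1]]
    om <- do.call(rbind, strsplit(toks, ":", fixed = TRUE))
    data.frame(nr_id = tab$nr_id[k], organism = om[, 1], map_id = om[, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(prov) <- NULL
  new("NRESSDatabase",
      sequences = data.frame(nr_id = tab$nr_id, ecs = tab$ecs,
                             stringsAsFactors = FALSE),
      provenance = prov)
}

#' EC occurrence counts of a database
#'
#' Token counts over all sequences; the input for entropy-mode weight
#' matrices.
#'
#' @param db an \linkS4class{NRESSDatabase} or \linkS4class{ESSDatabase}.
#' @return named numeric vector of counts per EC.
#' @export
ecOccurrences <- function(db) {
  ecs <- if (is(db, "NRESSDatabase")) db@sequences$ecs else db@entries$ecs
  pool <- unlist(splitEcs(ecs), use.names = FALSE)
  tab <- table(pool)
  setNames(as.numeric(tab), names(tab))
}
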