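#' The unknown-enzyme EC sentinel
#'
#' Reactions without an assigned EC number are labelled \code{"9.9.9"}; the
#' sentinel is similar only to itself in every weight matrix.
#' @export
EC_UNKNOWN <- "9.9.9"

#' Parse a raw EC string to its canonical 3-level form
#'
#' EC numbers carry a four-level hierarchy \code{class.subclass.subsubclass.serial};
#' only the first three levels, which describe the general reaction
#' chemistry, are retained. Four-level inputs are truncated; an empty or
#' placeholder token (\code{""}, \code{"-"}) becomes the \code{"9.9.9"}
#' unknown sentinel. Fewer than three concrete numeric levels is a format
#' error.
#'
#' @param raw character vector of raw EC strings (an optional \code{"ec:"}
#'   or \code{"EC"} prefix is stripped).
#' @return character vector of canonical \code{"a.b.c"} strings.
#' @examples
#' parseEC("2.7.1.11")   # "2.7.1"
#' parseEC("")           # "9.9.9"
#' @export
parseEC <- function(raw) {
  if (length(raw) == 0L) return(character())
  vapply(raw, function(x) {
    x <- trimws(sub("^(ec:|EC:?)", "", x, ignore.case = TRUE))
    if (is.na(x) || x == "" || x == "-") return(EC_UNKNOWN)
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("EC '%s' has fewer than 3 levels", x), call. = FALSE)
    parts <- parts[1:3]
    if (!all(grepl("^[0-9]+$", parts)))
      stop(sprintf("EC '%s' has non-numeric levels", x), call. = FALSE)
    n <- as.integer(parts)
    if (any(n <= 0L))
      stop(sprintf("EC '%s' has non-positive levels", x), call. = FALSE)
    paste(n, collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

ecLevels <- function(ec) {
  do.call(rbind, lapply(strsplit(ec, ".", fixed = TRUE), as.integer))
}
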