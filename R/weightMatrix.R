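#' Build an EC weight (distance) matrix over a catalogue
#'
#' Pairwise distances between 3-level EC numbers in \code{[0, 1]} that
#' respect the EC hierarchy. Two modes:
#' \describe{
#'   \item{uniform}{distance 0 for identical ECs, 1/3 when only the third
#'     level differs, 2/3 when the second (and possibly third) level differs,
#'     and 1 when the first level differs.}
#'   \item{entropy}{for distinct ECs sharing a prefix of length 1 or 2, the
#'     distance is the Shannon entropy of the catalogue occurrence
#'     distribution restricted to the deepest common ancestor class, divided
#'     by the entropy of the whole-catalogue distribution, clamped to
#'     \code{(0, 1]}. A pair of common specialised ECs inside a small
#'     homogeneous class therefore scores closer than a pair inside a large
#'     heterogeneous one. First-level mismatches are forced to exactly 1 and
#'     identity to 0.}
#' }
#' In both modes the \code{"9.9.9"} unknown sentinel has distance 1 to every
#' other EC and 0 to itself.
#'
#' @param catalogue character vector of EC strings (parsed with
#'   \code{\link{parseEC}}); the sentinel is added if absent.
#' @param mode \code{"uniform"} (default) or \code{"entropy"}.
#' @param counts named numeric vector of occurrence counts per catalogue EC;
#'   required for entropy mode.
#' @return an \linkS4class{ECWeightMatrix}.
#' @examples
#' m <- buildWeightMatrix(c("1.1.1", "1.2.1", "2.7.1"))
#' ecDistance(m, "1.2.1", "1.1.1")  # 2/3
#' @export
buildWeightMatrix <- function(catalogue, mode = c("uniform", "entropy"),
                              counts = NULL) {
  mode <- match.arg(mode)
  if (length(catalogue) == 0L) stop("catalogue must be nonempty")
  catalogue <- sort(unique(c(parseEC(catalogue), EC_UNKNOWN)))
  n <- length(catalogue)
  lv <- ecLevels(catalogue)
  d <- matrix(0, n, n, dimnames = list(catalogue, catalogue))

  shared <- function(i, j) {
    if (lv[i, 1] != lv[j, 1]) 0L
    else if (lv[i, 2] != lv[j, 2]) 1L
    else if (lv[i, 3] != lv[j, 3]) 2L
    else 3L
  }

  if (mode == "entropy") {
    if (is.null(counts))
      stop("entropy mode requires occurrence counts per EC", call. = FALSE)
    counts <- counts[intersect(names(counts), catalogue)]
    full <- setNames(rep(1, n), catalogue)  # unobserved ECs get 1 pseudo-count
    full[names(counts)] <- pmax(as.numeric(counts), 1e-9)
    entropy <- function(w) {
      p <- w / sum(w)
      p <- p[p > 0]
      -sum(p * log2(p))
    }
    hTotal <- entropy(full)
    if (hTotal <= 0)
      stop("degenerate catalogue: whole-catalogue entropy is zero",
           call. = FALSE)
    prefix <- function(i, k) paste(lv[i, seq_len(k)], collapse = ".")
  }

  unk <- match(EC_UNKNOWN, catalogue)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (i == unk || j == unk) { d[i, j] <- 1; next }
      k <- shared(i, j)
      if (k == 0L) { d[i, j] <- 1; next }
      if (mode == "uniform") {
        d[i, j] <- (3L - k) / 3
      } else {
        pre <- prefix(i, k)
        grp <- full[vapply(seq_len(n), function(m)
          m != unk && paste(lv[m, seq_len(k)], collapse = ".") == pre,
          logical(1))]
        h <- entropy(grp) / hTotal
        d[i, j] <- min(1, max(h, 1e-6))
      }
    }
  }
  new("ECWeightMatrix", catalogue = catalogue, mode = mode, dist = d)
}

#' Look up the distance between two ECs
#'
#' @param matrix an \linkS4class{ECWeightMatrix}.
#' @param a,b EC strings present in the catalogue.
#' @return numeric distance in \code{[0, 1]}.
#' @export
ecDistance <- function(matrix, a, b) {
  stopifnot(is(matrix, "ECWeightMatrix"))
  if (!all(c(a, b) %in% matrix@catalogue))
    stop(sprintf("EC outside the matrix catalogue: %s",
                 paste(setdiff(c(a, b), matrix@catalogue), collapse = ", ")),
         call. = FALSE)
  matrix@dist[a, b]
}

#' Export a weight matrix as TSV
#'
#' Writes a header row/column of EC strings with distances at 6 decimal
#' places.
#'
#' @param matrix an \linkS4class{ECWeightMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeWeightMatrix <- function(matrix, path) {
  d <- format(round(matrix@dist, 6), nsmall = 6, trim = TRUE)
  out <- cbind(ec = matrix@catalogue, d)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
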