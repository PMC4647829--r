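#' @useDynLib essalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

encodeSeq <- function(ecs, catalogue) {
  idx <- match(ecs, catalogue)
  if (anyNA(idx))
    stop(sprintf("EC outside the matrix catalogue: %s",
                 paste(unique(ecs[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  idx
}

#' Globally align two EC sequences
#'
#' Needleman-Wunsch-style dynamic programming that minimises the total
#' alignment cost: substitution cost is the weight-matrix distance between
#' the paired ECs and each gap column costs \code{gap}. The normalized score
#' is the total cost divided by the number of alignment columns, which lies
#' in \code{[0, 1]} whenever \code{gap <= 1}: 0 means identical sequences,
#' 1 maximally dissimilar. Among minimum-cost alignments the shortest one
#' (most substitution columns) defines the reported length and score, which
#' makes the score a symmetric function of the pair; traceback ties beyond
#' that are resolved preferring substitution, then a gap in \code{b}, then a
#' gap in \code{a}.
#'
#' @param a,b character vectors of 3-level EC strings (or semicolon-joined
#'   single strings).
#' @param matrix an \linkS4class{ECWeightMatrix} covering both sequences.
#' @param gap linear gap cost per gap column; default 1, the maximal
#'   substitution cost.
#' @return an \linkS4class{ESSAlignment}.
#' @examples
#' m <- buildWeightMatrix(c("2.7.1", "4.1.2", "4.1.3", "1.2.1"))
#' aln <- alignESS(c("2.7.1", "4.1.2", "1.2.1"),
#'                 c("2.7.1", "4.1.3", "1.2.1"), m)
#' alignmentScore(aln)  # 1/9
#' @export
alignESS <- function(a, b, matrix, gap = 1.0) {
  stopifnot(is(matrix, "ECWeightMatrix"))
  if (length(a) == 1L && grepl(";", a)) a <- splitEcs(a)[[1]]
  if (length(b) == 1L && grepl(";", b)) b <- splitEcs(b)[[1]]
  if (!length(a) || !length(b))
    stop("cannot align empty sequences", call. = FALSE)
  cat <- matrix@catalogue
  res <- nw_align_cpp(encodeSeq(a, cat), encodeSeq(b, cat),
                      matrix@dist, gap)
  dec <- function(idx) {
    out <- rep(NA_character_, length(idx))
    out[idx > 0L] <- cat[idx[idx > 0L]]
    out
  }
  new("ESSAlignment",
      aCols = dec(res$a_cols), bCols = dec(res$b_cols),
      cost = res$cost, score = res$score)
}

#' Number of unordered pairs in an all-against-all comparison
#'
#' @param n number of sequences.
#' @return \code{n * (n - 1) / 2} as a double (exact for any realistic n).
#' @examples
#' expectedPairCount(7970)  # 31756465
#' @export
expectedPairCount <- function(n) {
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' Score every unordered pair of an nrESS database
#'
#' Computes all \code{n(n-1)/2} pairwise alignment scores and stores the
#' records with score at or below \code{keepCeiling} (1 keeps everything).
#' Record order is deterministic: ascending (i, j) in nr-id order.
#'
#' @param db an \linkS4class{NRESSDatabase} with at least 2 sequences.
#' @param matrix an \linkS4class{ECWeightMatrix}.
#' @param gap linear gap cost; default 1.
#' @param keepCeiling store only records with score <= this value; default 1.
#' @return an \linkS4class{AlignmentTable}; its settings record the matrix
#'   mode, gap, ceiling and the total number of pairs scored.
#' @export
alignAllPairs <- function(db, matrix, gap = 1.0, keepCeiling = 1.0) {
  stopifnot(is(db, "NRESSDatabase"), is(matrix, "ECWeightMatrix"))
  sq <- db@sequences
  n <- nrow(sq)
  settings <- list(matrix_mode = matrix@mode, gap = gap,
                   keep_ceiling = keepCeiling, n = n,
                   n_pairs = expectedPairCount(n))
  if (n < 2L) {
    warning("fewer than 2 sequences; empty alignment table")
    return(new("AlignmentTable",
               records = data.frame(i = character(), j = character(),
                                    score = numeric(),
                                    stringsAsFactors = FALSE),
               settings = settings))
  }
  cat <- matrix@catalogue
  seqs <- lapply(splitEcs(sq$ecs), encodeSeq, catalogue = cat)
  scores <- nw_score_all_cpp(seqs, matrix@dist, gap)
  ii <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  keep <- scores <= keepCeiling + 1e-12
  records <- data.frame(i = sq$nr_id[ii[keep]], j = sq$nr_id[jj[keep]],
                        score = scores[keep], stringsAsFactors = FALSE)
  rownames(records) <- NULL
  new("AlignmentTable", records = records, settings = settings)
}

#' Exhaustive reference alignment cost
#'
#' Enumerates every global alignment of two sequences (all monotone paths
#' through the alignment lattice, without memoisation) and returns the
#' minimum total cost; ties in cost are resolved towards the shortest
#' alignment (most substitution columns), matching the scorer's symmetric
#' convention. Exponential; intended as an independent validation reference
#' for short sequences only.
#'
#' @param a,b character vectors of EC strings.
#' @param matrix an \linkS4class{ECWeightMatrix}.
#' @param gap linear gap cost.
#' @return list with \code{cost} (minimum total cost), \code{length}
#'   (columns of the shortest minimum-cost alignment), \code{score}
#'   (cost / length) and \code{n_alignments} (alignments enumerated).
#' @export
bruteForceAlignment <- function(a, b, matrix, gap = 1.0) {
  stopifnot(is(matrix, "ECWeightMatrix"))
  d <- matrix@dist
  best <- new.env()
  best$cost <- Inf
  best$len <- NA_integer_
  best$count <- 0L
  recurse <- function(i, j, cost, len) {
    if (i == 0L && j == 0L) {
      best$count <- best$count + 1L
      if (cost < best$cost - 1e-12 ||
          (abs(cost - best$cost) < 1e-12 &&
           (is.na(best$len) || len < best$len))) {
        best$cost <- cost
        best$len <- len
      }
      return(invisible())
    }
    if (i > 0L && j > 0L)
      recurse(i - 1L, j - 1L, cost + d[a[i], b[j]], len + 1L)
    if (i > 0L) recurse(i - 1L, j, cost + gap, len + 1L)
    if (j > 0L) recurse(i, j - 1L, cost + gap, len + 1L)
  }
  recurse(length(a), length(b), 0, 0L)
  list(cost = best$cost, length = best$len,
       score = best$cost / best$len, n_alignments = best$count)
}

#' Write an alignment table as TSV
#'
#' Columns \code{nr_id_i}, \code{nr_id_j}, \code{score}, sorted by (i, j).
#'
#' @param table an \linkS4class{AlignmentTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentTable <- function(table, path) {
  r <- table@records
  r <- r[order(r$i, r$j), , drop = FALSE]
  names(r) <- c("nr_id_i", "nr_id_j", "score")
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
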