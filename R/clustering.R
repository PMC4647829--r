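#' Shared significant alignments between metabolic maps
#'
#' For every alignment record with score at or below the threshold, each
#' combination of a provenance map of the first sequence with a provenance
#' map of the second increments the corresponding cell (symmetrically;
#' same-map combinations land on the diagonal). Rows are then normalized by
#' their totals; all-zero rows are preserved as zero.
#'
#' @param table an \linkS4class{AlignmentTable}.
#' @param db the \linkS4class{NRESSDatabase} the table was built over.
#' @param threshold significance score threshold; default 0.3.
#' @param excludeDiagonal when TRUE, within-map counts are left out of the
#'   row totals used for normalization.
#' @return a \linkS4class{MapSimilarityMatrix}.
#' @export
sharedAlignmentMatrix <- function(table, db, threshold = 0.3,
                                  excludeDiagonal = FALSE) {
  stopifnot(is(table, "AlignmentTable"), is(db, "NRESSDatabase"))
  maps <- sort(unique(db@provenance$map_id))
  n <- length(maps)
  counts <- matrix(0, n, n, dimnames = list(maps, maps))
  mapsOf <- lapply(split(db@provenance$map_id, db@provenance$nr_id), unique)
  r <- table@records
  r <- r[r$score <= threshold + 1e-12, , drop = FALSE]
  for (k in seq_len(nrow(r))) {
    mi <- mapsOf[[r$i[k]]]; mj <- mapsOf[[r$j[k]]]
    for (a in mi) for (b in mj) {
      counts[a, b] <- counts[a, b] + 1
      if (a != b) counts[b, a] <- counts[b, a] + 1
    }
  }
  normBase <- counts
  if (excludeDiagonal) diag(normBase) <- 0
  rs <- rowSums(normBase)
  normalized <- normBase
  nonzero <- rs > 0
  normalized[nonzero, ] <- normBase[nonzero, , drop = FALSE] / rs[nonzero]
  new("MapSimilarityMatrix", maps = maps, counts = counts,
      normalized = normalized)
}

#' Hierarchically cluster metabolic maps by shared-alignment profiles
#'
#' Pairwise distance between maps is one minus the Spearman rank correlation
#' of their normalized row vectors (average ranks under ties); rows with
#' zero variance, for which rank correlation is undefined, get distance 1 to
#' every other map and are reported. Agglomeration uses average linkage, and
#' flat clusters come from cutting the dendrogram at \code{cutFraction}
#' times the maximum merge height (a fraction of 0 yields all singletons).
#'
#' @param msm a \linkS4class{MapSimilarityMatrix} with at least 2 maps.
#' @param cutFraction fraction of the tree height at which to cut;
#'   default 0.46.
#' @return list with \code{hclust} (the merge tree), \code{clusters}
#'   (named integer vector of flat assignments), \code{cutHeight}, and
#'   \code{degenerate} (map ids with zero-variance rows).
#' @export
clusterMaps <- function(msm, cutFraction = 0.46) {
  stopifnot(is(msm, "MapSimilarityMatrix"))
  m <- msm@normalized[order(msm@maps), order(msm@maps), drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 maps to cluster", call. = FALSE)
  vars <- apply(m, 1, stats::var)
  degenerate <- rownames(m)[vars == 0]
  if (length(degenerate))
    warning(sprintf("zero-variance rows (distance 1 to everything): %s",
                    paste(degenerate, collapse = ", ")))
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  D <- 1 - rho
  D[is.na(D)] <- 1
  diag(D) <- 0
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  maxH <- max(tree$height)
  cutHeight <- cutFraction * maxH
  clusters <- if (cutFraction <= 0) {
    setNames(seq_len(n), rownames(m))
  } else {
    stats::cutree(tree, h = cutHeight)
  }
  list(hclust = tree, clusters = clusters, cutHeight = cutHeight,
       degenerate = degenerate)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are the merge-height differences, so root-to-leaf path
#' lengths equal merge heights.
#'
#' @param tree an \code{hclust} object (e.g. from \code{\link{clusterMaps}}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDendrogramNewick <- function(tree, path) {
  labels <- tree$labels
  build <- function(node, parentHeight) {
    if (node < 0) {
      sprintf("%s:%.6f", labels[-node], parentHeight)
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%.6f",
              build(tree$merge[node, 1], h), build(tree$merge[node, 2], h),
              parentHeight - h)
    }
  }
  top <- nrow(tree$merge)
  newick <- paste0("(", build(tree$merge[top, 1], tree$height[top]), ",",
                   build(tree$merge[top, 2], tree$height[top]), ");")
  writeLines(newick, path)
  invisible(path)
}
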