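#' Shuffle the EC content of an nrESS database
#'
#' Builds one null database: every EC token of every sequence is pooled,
#' the pool is permuted with a seeded generator, and tokens are redistributed
#' into sequences of exactly the original lengths. The global EC multiset
#' and every per-sequence length are therefore preserved exactly. Provenance
#' is not carried over: null sequences are synthetic and get their own ids.
#' Shuffled tuples may coincide; the result is a plain sequence set, not a
#' deduplicated database, so downstream all-vs-all runs see the same number
#' of sequences as the real run.
#'
#' @param db an \linkS4class{NRESSDatabase}.
#' @param seed integer seed for the permutation.
#' @return an \linkS4class{NRESSDatabase}-shaped object whose sequences may
#'   contain duplicate tuples (validity relaxed by uniquifying ids only);
#'   technically returned as a plain data.frame with columns \code{nr_id},
#'   \code{ecs} wrapped in a list: \code{list(sequences = ..., seed = seed)}.
#' @export
shuffleDatabase <- function(db, seed) {
  stopifnot(is(db, "NRESSDatabase"))
  sq <- db@sequences
  if (!nrow(sq)) stop("cannot shuffle an empty database", call. = FALSE)
  toks <- splitEcs(sq$ecs)
  len <- lengths(toks)
  pool <- unlist(toks, use.names = FALSE)
  perm <- withSeed(seed, sample.int(length(pool)))
  pool <- pool[perm]
  ends <- cumsum(len)
  starts <- ends - len + 1L
  ecs <- vapply(seq_along(len),
                function(k) joinEcs(pool[starts[k]:ends[k]]), character(1))
  list(sequences = data.frame(nr_id = sprintf("null%06d", seq_along(ecs)),
                              ecs = ecs, stringsAsFactors = FALSE),
       seed = as.integer(seed))
}

# all-vs-all scores of a plain sequence table (real or null)
allPairScores <- function(ecs, matrix, gap) {
  seqs <- lapply(splitEcs(ecs), encodeSeq, catalogue = matrix@catalogue)
  nw_score_all_cpp(seqs, matrix@dist, gap)
}

#' Build a shuffled-null ensemble
#'
#' Generates \code{replicates} shuffled databases (seeds
#' \code{baseSeed + 1 .. baseSeed + R}), aligns each all-against-all with the
#' given settings and stores every replicate's full score vector.
#'
#' @param db an \linkS4class{NRESSDatabase}.
#' @param matrix an \linkS4class{ECWeightMatrix}.
#' @param gap linear gap cost; must match the real run it is compared with.
#' @param replicates number of shuffled replicates; default 10.
#' @param baseSeed integer base seed.
#' @return a \linkS4class{NullEnsemble}.
#' @export
buildNullEnsemble <- function(db, matrix, gap = 1.0, replicates = 10L,
                              baseSeed = 17L) {
  stopifnot(is(db, "NRESSDatabase"), replicates >= 2L)
  seeds <- as.integer(baseSeed) + seq_len(replicates)
  scores <- lapply(seeds, function(s) {
    null <- shuffleDatabase(db, s)
    allPairScores(null$sequences$ecs, matrix, gap)
  })
  new("NullEnsemble", scores = scores, seeds = seeds,
      settings = list(matrix_mode = matrix@mode, gap = gap,
                      n = nrow(db@sequences),
                      n_pairs = expectedPairCount(nrow(db@sequences))))
}

#' Bin alignment scores into a histogram on [0, 1]
#'
#' Bins are half-open \code{[x, x + w)}; the final bin is closed at 1, so a
#' score of exactly 1 lands in the last bin.
#'
#' @param scores numeric vector of scores in \code{[0, 1]}.
#' @param binWidth bin width; default 0.05.
#' @return a \linkS4class{ScoreHistogram}.
#' @export
scoreHistogram <- function(scores, binWidth = 0.05) {
  nbins <- ceiling(1 / binWidth - 1e-9)
  # float-safe binning: a score on a bin edge belongs to the right bin
  idx <- pmin(floor(scores / binWidth + 1e-9), nbins - 1L) + 1L
  counts <- tabulate(idx, nbins = nbins)
  new("ScoreHistogram", binWidth = binWidth,
      counts = setNames(as.integer(counts),
                        format((seq_len(nbins) - 1L) * binWidth,
                               trim = TRUE)),
      total = length(scores))
}

#' Dispersion of the real score histogram against the null ensemble
#'
#' Per bin, the deviation of the real count from the null-replicate mean in
#' units of the null standard deviation:
#' \code{(real_b - mean_null_b) / sd_null_b}. Where the null SD is zero the
#' deviation is 0 if the real count equals the null mean and \code{Inf}
#' otherwise.
#'
#' @param real a \linkS4class{ScoreHistogram} of the real scores.
#' @param nulls a \linkS4class{NullEnsemble} built with matching settings.
#' @return data.frame with columns \code{bin} (left edge), \code{real},
#'   \code{null_mean}, \code{null_sd}, \code{deviation}.
#' @export
dispersionCurve <- function(real, nulls) {
  stopifnot(is(real, "ScoreHistogram"), is(nulls, "NullEnsemble"))
  if (length(nulls@scores) < 2L)
    stop("need at least 2 null replicates", call. = FALSE)
  nullHists <- vapply(nulls@scores, function(s)
    as.numeric(scoreHistogram(s, real@binWidth)@counts),
    numeric(length(real@counts)))
  mu <- rowMeans(nullHists)
  sdv <- apply(nullHists, 1, stats::sd)
  realCounts <- as.numeric(real@counts)
  dev <- ifelse(sdv > 0, (realCounts - mu) / sdv,
                ifelse(abs(realCounts - mu) < 1e-9, 0, Inf))
  data.frame(bin = as.numeric(names(real@counts)), real = realCounts,
             null_mean = mu, null_sd = sdv, deviation = dev)
}

#' Crossing point of real and null score distributions
#'
#' The lowest bin at which the null ensemble's mean count first reaches the
#' real count (the score above which alignments are as frequent by chance);
#' reported as the bin's left edge.
#'
#' @inheritParams dispersionCurve
#' @return single numeric, or NA when the curves never cross.
#' @export
crossingPoint <- function(real, nulls) {
  d <- dispersionCurve(real, nulls)
  idx <- which(d$null_mean >= d$real & d$real + d$null_mean > 0)
  if (!length(idx)) return(NA_real_)
  d$bin[idx[1]]
}

#' Fraction of sequences participating in at least one significant alignment
#'
#' @param db the \linkS4class{NRESSDatabase} the table was built over.
#' @param table an \linkS4class{AlignmentTable}.
#' @param threshold score threshold (records with score <= threshold count).
#' @return fraction in \code{[0, 1]}.
#' @export
coverageAtThreshold <- function(db, table, threshold) {
  stopifnot(is(db, "NRESSDatabase"), is(table, "AlignmentTable"))
  n <- nrow(db@sequences)
  if (!n) stop("empty database", call. = FALSE)
  r <- table@records
  r <- r[r$score <= threshold + 1e-12, , drop = FALSE]
  length(intersect(db@sequences$nr_id, unique(c(r$i, r$j)))) / n
}

#' Null fraction of alignments at or below a threshold
#'
#' @param nulls a \linkS4class{NullEnsemble}.
#' @param threshold score threshold.
#' @return list with \code{fractions} (per replicate), \code{mean},
#'   \code{sd}, and the corresponding raw \code{counts}.
#' @export
nullFractionBelow <- function(nulls, threshold) {
  stopifnot(is(nulls, "NullEnsemble"))
  counts <- vapply(nulls@scores,
                   function(s) sum(s <= threshold + 1e-12), numeric(1))
  fr <- counts / vapply(nulls@scores, length, numeric(1))
  list(fractions = fr, mean = mean(fr), sd = stats::sd(fr), counts = counts)
}
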