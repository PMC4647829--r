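#' Read a pipeline run configuration
#'
#' YAML or JSON file with the \code{\link{runPipeline}} fields; unknown
#' fields error, thresholds are checked to lie in \code{[0, 1]}.
#'
#' @param path config file path.
#' @return a named list of configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE) else
    yaml::read_yaml(path)
  known <- c("input", "output_dir", "matrix_mode", "gap", "score_threshold",
             "coverage_threshold", "null_replicates", "base_seed",
             "cluster_cut", "organism_panel", "queries")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg
}

#' Run the full ESS pipeline
#'
#' Executes build (or load) -> deduplicate -> align -> null -> conserve ->
#' cluster -> optional scan, writing every stage output under
#' \code{outputDir} in the TSV/JSON interchange formats, plus a
#' \code{manifest.json} recording parameters, seeds and per-stage record
#' counts. Given identical inputs and configuration the outputs are
#' byte-identical.
#'
#' @param input a directory of KGML files, a db TSV/JSON path, or an
#'   \linkS4class{NRESSDatabase}.
#' @param outputDir writable output directory (created if absent).
#' @param matrixMode \code{"uniform"} or \code{"entropy"}.
#' @param gap linear gap cost; default 1.
#' @param scoreThreshold significance threshold; default 0.3.
#' @param coverageThreshold panel-coverage threshold; default 0.75.
#' @param nullReplicates shuffled replicates; default 10.
#' @param baseSeed base seed for the null shuffles; default 17.
#' @param clusterCut dendrogram cut fraction; default 0.46.
#' @param organismPanel organism panel; default all organisms in the data.
#' @param queries optional named list of query EC vectors (or a query file
#'   path) for the recruitment scan stage.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(input, outputDir, matrixMode = "uniform", gap = 1.0,
                        scoreThreshold = 0.3, coverageThreshold = 0.75,
                        nullReplicates = 10L, baseSeed = 17L,
                        clusterCut = 0.46, organismPanel = NULL,
                        queries = NULL) {
  for (v in c(scoreThreshold, coverageThreshold, clusterCut))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]", call. = FALSE)
  if (nullReplicates < 2L)
    stop("need at least 2 null replicates", call. = FALSE)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = list(
    matrix_mode = matrixMode, gap = gap, score_threshold = scoreThreshold,
    coverage_threshold = coverageThreshold,
    null_replicates = nullReplicates, base_seed = baseSeed,
    cluster_cut = clusterCut))
  stage <- function(name, count) {
    message(sprintf("[%s] %d records", name, count))
    manifest$stages[[name]] <<- count
  }

  # build / load
  if (is(input, "NRESSDatabase")) {
    nr <- input
    stage("load", nrow(nrSequences(nr)))
  } else if (dir.exists(input)) {
    ess <- buildESSDatabase(input)
    stage("build", nrow(essEntries(ess)))
    manifest$stages$zero_yield_maps <- nrow(ess@zeroYield)
    nr <- deduplicateESS(ess)
    stage("deduplicate", nrow(nrSequences(nr)))
  } else {
    nr <- readNrDatabase(input)
    stage("load", nrow(nrSequences(nr)))
  }
  writeNrDatabase(nr, file.path(outputDir, "nress.tsv"))

  # align
  catalogue <- unique(unlist(splitEcs(nrSequences(nr)$ecs)))
  wm <- buildWeightMatrix(catalogue, mode = matrixMode,
                          counts = if (matrixMode == "entropy")
                            ecOccurrences(nr) else NULL)
  writeWeightMatrix(wm, file.path(outputDir, "weight_matrix.tsv"))
  table <- alignAllPairs(nr, wm, gap = gap)
  stage("align", nrow(alignmentRecords(table)))
  writeAlignmentTable(table, file.path(outputDir, "alignments.tsv"))

  # null significance
  nulls <- buildNullEnsemble(nr, wm, gap = gap,
                             replicates = nullReplicates,
                             baseSeed = baseSeed)
  realHist <- scoreHistogram(alignmentRecords(table)$score)
  disp <- dispersionCurve(realHist, nulls)
  nf <- nullFractionBelow(nulls, scoreThreshold)
  report <- list(
    dispersion = disp,
    crossing_point = crossingPoint(realHist, nulls),
    coverage = coverageAtThreshold(nr, table, scoreThreshold),
    null_fraction = list(mean = nf$mean, sd = nf$sd, counts = nf$counts))
  jsonlite::write_json(report, file.path(outputDir, "null_report.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("null", length(nulls@scores))

  # conservation
  panel <- organismPanel %||% sort(unique(nrProvenance(nr)$organism))
  pairs <- conservedPairs(table, nr, scoreThreshold, panel,
                          coverageThreshold)
  stage("conserved_pairs", nrow(pairs))
  mm <- mmfcdPairs(pairs)
  stage("mmfcd", nrow(mm))
  consTab <- conservationTable(mm, nr, wm, gap)
  utils::write.table(consTab, file.path(outputDir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # clustering
  msm <- sharedAlignmentMatrix(table, nr, scoreThreshold)
  utils::write.table(msm@counts, file.path(outputDir, "map_counts.tsv"),
                     sep = "\t", quote = FALSE)
  cl <- tryCatch(clusterMaps(msm, clusterCut), error = function(e) NULL)
  if (!is.null(cl)) {
    utils::write.table(
      data.frame(map_id = names(cl$clusters), cluster = cl$clusters),
      file.path(outputDir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeDendrogramNewick(cl$hclust, file.path(outputDir, "dendrogram.nwk"))
    stage("cluster", length(unique(cl$clusters)))
  }

  # optional scan
  if (!is.null(queries)) {
    if (is.character(queries) && length(queries) == 1L)
      queries <- readQueryFile(queries)
    scans <- lapply(names(queries), function(qn) {
      sc <- scanQuery(queries[[qn]], nr, wm, scoreThreshold, gap,
                      queryId = qn)
      nullCounts <- scanNull(queries[[qn]], nr, nulls, wm, scoreThreshold,
                             gap)
      list(query = qn, hit_count = nrow(scanHits(sc)),
           per_map = as.list(sc@perMap), null_counts = nullCounts$counts)
    })
    jsonlite::write_json(scans, file.path(outputDir, "scan.json"),
                         auto_unbox = TRUE, digits = NA)
    stage("scan", length(scans))
  }

  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
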