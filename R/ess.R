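#' Select BFS initialization nodes (roots)
#'
#' A node is an initialization node when it represents a metabolic input of
#' the map, by either of two criteria:
#' \describe{
#'   \item{A}{at least one of its substrates is produced by no node of any
#'     other reaction in the map (the compound is not created within the
#'     pathway);}
#'   \item{B}{at least one of its substrates is annotated as entering from
#'     another metabolic map, and the node has at most 2 distinct neighbours
#'     (in- plus out-neighbours).}
#' }
#' Reversibility is honoured: a reversible reaction's substrate set is the
#' union of its substrates and products. The result is sorted by node id for
#' determinism.
#'
#' @param graph a \linkS4class{MetabolicGraph}.
#' @return character vector of root node ids (possibly empty).
#' @export
selectInitializationNodes <- function(graph) {
  stopifnot(is(graph, "MetabolicGraph"))
  nodes <- graph@nodes
  if (!nrow(nodes)) return(character())
  edges <- graph@edges

  produced <- graph@produced
  consumed <- graph@consumed

  neighbours <- function(id) {
    unique(c(edges$to[edges$from == id], edges$from[edges$to == id]))
  }

  roots <- character()
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$node_id[i]
    rx <- nodes$reaction_id[i]
    subs <- consumed[[rx]]
    # criterion A: some substrate produced by no other reaction in the map
    otherProducts <- unlist(produced[setdiff(names(produced), rx)],
                            use.names = FALSE)
    critA <- any(!(subs %in% otherProducts))
    # criterion B: cross-map substrate and degree <= 2 (distinct neighbours)
    critB <- any(subs %in% graph@compoundLinks) && length(neighbours(id)) <= 2L
    if (critA || critB) roots <- c(roots, id)
  }
  sort(roots)
}

#' Build a BFS tree from a root node
#'
#' Standard breadth-first search over the directed edges, visiting each node
#' at most once; out-neighbours are expanded in ascending node-id order so
#' the tree (and every downstream sequence) is deterministic.
#'
#' @param graph a \linkS4class{MetabolicGraph}.
#' @param root node id present in the graph.
#' @return a \linkS4class{BFSTree}.
#' @export
buildBfsTree <- function(graph, root) {
  stopifnot(is(graph, "MetabolicGraph"))
  if (!root %in% graph@nodes$node_id)
    stop(sprintf("root '%s' not in graph", root), call. = FALSE)
  edges <- graph@edges
  adj <- split(edges$to, edges$from)
  adj <- lapply(adj, function(x) sort(unique(x)))

  visited <- root
  parent <- character()
  queue <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]] %||% character()) {
      if (!(v %in% visited)) {
        visited <- c(visited, v)
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  children <- names(parent)
  leaves <- setdiff(visited, parent)  # nodes that are nobody's parent
  new("BFSTree", root = root, parent = parent, leaves = sort(leaves))
}

#' Extract Enzymatic Step Sequences from a BFS tree
#'
#' From each leaf the path is traced back to the root and reported
#' root-to-leaf as the tree nodes' EC labels. A tree yields as many
#' candidate sequences as it has leaves; candidates shorter than 2 steps
#' (an isolated root) are discarded.
#'
#' @param tree a \linkS4class{BFSTree}.
#' @param graph the \linkS4class{MetabolicGraph} the tree was grown on.
#' @return data.frame with columns \code{root}, \code{leaf}, \code{ecs}
#'   (semicolon-joined EC tuple); zero rows when nothing qualifies.
#' @export
extractESS <- function(tree, graph) {
  stopifnot(is(tree, "BFSTree"), is(graph, "MetabolicGraph"))
  ecOf <- setNames(graph@nodes$ec, graph@nodes$node_id)
  out <- lapply(tree@leaves, function(leaf) {
    path <- leaf
    while (path[1] != tree@root) path <- c(tree@parent[[path[1]]], path)
    if (length(path) < 2L) return(NULL)
    data.frame(root = tree@root, leaf = leaf,
               ecs = joinEcs(unname(ecOf[path])), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(root = character(), leaf = character(),
                      ecs = character(), stringsAsFactors = FALSE)
  out
}

# all ESS of one parsed pathway model
pathwayESS <- function(model, excludeCompounds = character()) {
  graph <- buildEnzymeGraph(model, excludeCompounds)
  roots <- selectInitializationNodes(graph)
  out <- lapply(roots, function(r) extractESS(buildBfsTree(graph, r), graph))
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    return(data.frame(organism = character(), map_id = character(),
                      root = character(), leaf = character(),
                      ecs = character(), stringsAsFactors = FALSE))
  cbind(data.frame(organism = model@organism, map_id = model@mapId,
                   stringsAsFactors = FALSE), out)
}

#' Build an ESS database from KGML files
#'
#' Parses each file, builds its enzyme graph, selects roots, grows BFS trees
#' and extracts all root-to-leaf sequences, concatenating them with full
#' provenance. Files are processed in sorted-basename order so the result is
#' independent of filesystem ordering. Maps contributing zero sequences are
#' recorded in the zero-yield report.
#'
#' @param files character vector of KGML file paths, or a directory
#'   containing \code{*.xml} files.
#' @param strict when TRUE an unreadable file aborts the build; otherwise it
#'   is skipped and recorded in the \code{skipped} slot.
#' @param excludeCompounds optional compound exclusion list passed to
#'   \code{\link{buildEnzymeGraph}}.
#' @return an \linkS4class{ESSDatabase}.
#' @export
buildESSDatabase <- function(files, strict = FALSE,
                             excludeCompounds = character()) {
  if (length(files) == 1L && dir.exists(files))
    files <- list.files(files, pattern = "\\.xml$", full.names = TRUE)
  files <- files[order(basename(files))]
  entries <- list()
  zero <- list()
  skipped <- character()
  for (f in files) {
    model <- tryCatch(parseKGML(f), error = function(e) e)
    if (inherits(model, "error")) {
      if (strict) stop(sprintf("failed to parse '%s': %s", f,
                               conditionMessage(model)), call. = FALSE)
      warning(sprintf("skipping unreadable file '%s'", f), call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    e <- pathwayESS(model, excludeCompounds)
    if (nrow(e)) entries[[length(entries) + 1L]] <- e
    else zero[[length(zero) + 1L]] <- data.frame(
      organism = model@organism, map_id = model@mapId,
      stringsAsFactors = FALSE)
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(organism = character(), map_id = character(),
               root = character(), leaf = character(), ecs = character(),
               stringsAsFactors = FALSE)
  zero <- if (length(zero)) do.call(rbind, zero) else
    data.frame(organism = character(), map_id = character(),
               stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new("ESSDatabase", entries = entries, zeroYield = zero, skipped = skipped)
}

#' Collapse an ESS database to its non-redundant form
#'
#' Identical EC tuples (order-sensitive) collapse to one representative, the
#' first by (organism, map, entry index) ordering; the union of all
#' provenances is retained, so every original ESS maps to exactly one nr id.
#'
#' @param db an \linkS4class{ESSDatabase} with at least one entry.
#' @return an \linkS4class{NRESSDatabase}.
#' @export
deduplicateESS <- function(db) {
  stopifnot(is(db, "ESSDatabase"))
  e <- db@entries
  if (!nrow(e)) stop("cannot deduplicate an empty database", call. = FALSE)
  e <- e[order(e$organism, e$map_id, seq_len(nrow(e))), , drop = FALSE]
  key <- e$ecs
  firstIdx <- !duplicated(key)
  uniq <- key[firstIdx]
  nrIds <- sprintf("nr%06d", seq_along(uniq))
  names(nrIds) <- uniq
  sequences <- data.frame(nr_id = unname(nrIds), ecs = uniq,
                          stringsAsFactors = FALSE)
  prov <- data.frame(nr_id = unname(nrIds[key]), organism = e$organism,
                     map_id = e$map_id, stringsAsFactors = FALSE)
  prov <- unique(prov)
  prov <- prov[order(prov$nr_id, prov$organism, prov$map_id), , drop = FALSE]
  rownames(prov) <- NULL
  new("NRESSDatabase", sequences = sequences, provenance = prov)
}

#' Summarize an ESS or nrESS database
#'
#' @param db an \linkS4class{ESSDatabase} or \linkS4class{NRESSDatabase}.
#' @return list with \code{lengths} (integer histogram over sequence
#'   lengths), \code{mean}, \code{mode} (smallest most-frequent length), and
#'   for redundant databases \code{per_organism} counts.
#' @export
summarizeESS <- function(db) {
  if (is(db, "ESSDatabase")) {
    ecs <- db@entries$ecs
    org <- db@entries$organism
  } else if (is(db, "NRESSDatabase")) {
    ecs <- db@sequences$ecs
    org <- NULL
  } else stop("unsupported database type")
  if (!length(ecs)) return(list(lengths = integer(), mean = NA_real_,
                                mode = NA_integer_, per_organism = integer()))
  len <- lengths(splitEcs(ecs))
  hist <- table(factor(len, levels = seq(min(len), max(len))))
  hist <- setNames(as.integer(hist), names(hist))
  modes <- as.integer(names(hist)[hist == max(hist)])
  list(lengths = hist,
       mean = mean(len),
       mode = min(modes),
       per_organism = if (is.null(org)) integer() else
         vapply(split(org, org), length, integer(1)))
}
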