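#' Default synthetic EC alphabet
#'
#' Thirty 3-level EC numbers spanning all six top-level classes, five per
#' class across two subclasses, so uniform and entropy matrices have
#' non-trivial structure at every hierarchy level.
#'
#' @return character vector of 30 EC strings.
#' @export
defaultEcAlphabet <- function() {
  as.vector(vapply(1:6, function(cl)
    c(sprintf("%d.1.%d", cl, 1:3), sprintf("%d.2.%d", cl, 1:2)),
    character(5)))
}

#' Specification of a synthetic toy pathway
#'
#' @param nReactions number of reactions.
#' @param pBranch probability a reaction branches off an earlier compound
#'   instead of extending the current tip.
#' @param pReversible probability a reaction is reversible.
#' @param pCrossLink probability an external substrate (consumed but never
#'   produced) is annotated as entering from another map.
#' @param pMissingEc probability a reaction carries no EC label (9.9.9).
#' @param pMultiEc probability a reaction carries two distinct EC labels.
#' @param pCycle probability a reaction's product is an earlier compound
#'   (creating a cycle).
#' @param ecAlphabet EC alphabet to draw labels from.
#' @param organism,mapId provenance attributes written into the KGML.
#' @param seed integer seed; the fixture is byte-identical given the spec.
#' @return a list of class \code{"PathwaySpec"}.
#' @export
pathwaySpec <- function(nReactions = 6L, pBranch = 0.3, pReversible = 0.2,
                        pCrossLink = 0.3, pMissingEc = 0.1, pMultiEc = 0.1,
                        pCycle = 0.1, ecAlphabet = defaultEcAlphabet(),
                        organism = "syn", mapId = "00001", seed = 1L) {
  probs <- c(pBranch, pReversible, pCrossLink, pMissingEc, pMultiEc, pCycle)
  stopifnot(all(probs >= 0 & probs <= 1), length(ecAlphabet) > 0)
  structure(list(nReactions = as.integer(nReactions), pBranch = pBranch,
                 pReversible = pReversible, pCrossLink = pCrossLink,
                 pMissingEc = pMissingEc, pMultiEc = pMultiEc,
                 pCycle = pCycle, ecAlphabet = ecAlphabet,
                 organism = organism, mapId = mapId, seed = as.integer(seed)),
            class = "PathwaySpec")
}

# serialize a reaction plan to KGML text
reactionsToKGML <- function(reactions, compoundLinks, organism, mapId) {
  allCompounds <- sort(unique(unlist(lapply(reactions, function(r)
    c(r$substrates, r$products)))))
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="path:%s%s" org="%s" number="%s" title="synthetic fixture">',
            organism, mapId, organism, mapId))
  eid <- 0L
  for (cp in allCompounds) {
    eid <- eid + 1L
    link <- if (cp %in% compoundLinks)
      ' link="path:map99999"' else ""
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="cpd:%s" type="compound"%s/>', eid, cp, link))
  }
  for (r in reactions) {
    if (length(r$ec_labels)) {
      eid <- eid + 1L
      lines <- c(lines, sprintf(
        '  <entry id="%d" name="%s" type="enzyme" reaction="%s"/>',
        eid, paste0("ec:", r$ec_labels, collapse = " "), r$reaction_id))
    }
    body <- c(
      sprintf('  <reaction id="%s" name="%s" type="%s">', r$reaction_id,
              r$reaction_id,
              if (r$reversible) "reversible" else "irreversible"),
      sprintf('    <substrate id="0" name="cpd:%s"/>', r$substrates),
      sprintf('    <product id="0" name="cpd:%s"/>', r$products),
      '  </reaction>')
    lines <- c(lines, body)
  }
  paste(c(lines, "</pathway>"), collapse = "\n")
}

#' Generate a synthetic KGML pathway with planted ground truth
#'
#' Emits a well-formed KGML document exercising every parser branch
#' (reversible, EC-less, multi-EC, cross-map-linked and cyclic reactions,
#' depending on the spec's probabilities) together with the ground-truth
#' root and sequence sets computed by \code{\link{traceEssPaths}}, an
#' independent adjacency-matrix path tracer.
#'
#' @param spec a \code{\link{pathwaySpec}}.
#' @return list with \code{xml} (KGML text), \code{reactions} (the internal
#'   plan), \code{compoundLinks}, and \code{truth} (data.frame
#'   \code{root, leaf, ecs} from the reference tracer).
#' @export
generateToyPathway <- function(spec) {
  stopifnot(inherits(spec, "PathwaySpec"))
  plan <- withSeed(spec$seed, {
    reactions <- list()
    compounds <- "C001"
    tip <- "C001"
    nextC <- 2L
    for (i in seq_len(spec$nReactions)) {
      sub <- if (stats::runif(1) < spec$pBranch && length(compounds) > 1L)
        sample(compounds, 1L) else tip
      cyclic <- stats::runif(1) < spec$pCycle &&
        length(setdiff(compounds, sub)) >= 1L
      if (cyclic) {
        prod <- sample(setdiff(compounds, sub), 1L)
      } else {
        prod <- sprintf("C%03d", nextC); nextC <- nextC + 1L
        compounds <- c(compounds, prod)
        tip <- prod
      }
      u <- stats::runif(1)
      ecs <- if (u < spec$pMissingEc) character() else
        if (u < spec$pMissingEc + spec$pMultiEc)
          sample(spec$ecAlphabet, 2L) else sample(spec$ecAlphabet, 1L)
      reactions[[i]] <- list(reaction_id = sprintf("R%02d", i),
                             ec_labels = ecs,
                             substrates = sub, products = prod,
                             reversible = stats::runif(1) < spec$pReversible)
    }
    produced <- unique(unlist(lapply(reactions, function(r)
      if (r$reversible) c(r$substrates, r$products) else r$products)))
    external <- setdiff(unique(unlist(lapply(reactions, `[[`, "substrates"))),
                        produced)
    links <- external[stats::runif(length(external)) < spec$pCrossLink]
    list(reactions = reactions, links = links)
  })
  xml <- reactionsToKGML(plan$reactions, plan$links, spec$organism,
                         spec$mapId)
  truth <- traceEssPaths(plan$reactions, plan$links)
  list(xml = xml, reactions = plan$reactions, compoundLinks = plan$links,
       truth = truth)
}

#' Reference ESS tracer (exhaustive, adjacency-matrix based)
#'
#' Independent reimplementation of root selection, breadth-first tree
#' growth and leaf-to-root path tracing, operating on a plain reaction list
#' via an explicit adjacency matrix and layer-by-layer frontier expansion.
#' Used as the validation oracle for the graph/BFS pipeline; intended for
#' small pathways only.
#'
#' @param reactions list of reaction entries (as in
#'   \linkS4class{PathwayModel}).
#' @param compoundLinks character vector of cross-map compound ids.
#' @return data.frame \code{root, leaf, ecs} (semicolon-joined tuples,
#'   length >= 2), sorted by (root, leaf).
#' @export
traceEssPaths <- function(reactions, compoundLinks = character()) {
  if (!length(reactions))
    return(data.frame(root = character(), leaf = character(),
                      ecs = character(), stringsAsFactors = FALSE))
  rid <- vapply(reactions, `[[`, character(1), "reaction_id")
  names(reactions) <- rid
  # expanded sides
  subsOf <- lapply(reactions, function(r)
    if (r$reversible) unique(c(r$substrates, r$products)) else r$substrates)
  prodsOf <- lapply(reactions, function(r)
    if (r$reversible) unique(c(r$substrates, r$products)) else r$products)
  # nodes
  nodeId <- character(); nodeEc <- character(); nodeRx <- character()
  for (r in reactions) {
    ecs <- unique(parseEC(r$ec_labels))
    if (!length(ecs)) ecs <- EC_UNKNOWN
    nodeId <- c(nodeId, paste(r$reaction_id, ecs, sep = "|"))
    nodeEc <- c(nodeEc, ecs)
    nodeRx <- c(nodeRx, rep(r$reaction_id, length(ecs)))
  }
  ord <- order(nodeId)
  nodeId <- nodeId[ord]; nodeEc <- nodeEc[ord]; nodeRx <- nodeRx[ord]
  n <- length(nodeId)
  A <- matrix(FALSE, n, n, dimnames = list(nodeId, nodeId))
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v || nodeRx[u] == nodeRx[v]) next
    A[u, v] <- length(intersect(prodsOf[[nodeRx[u]]],
                                subsOf[[nodeRx[v]]])) > 0
  }
  # roots
  roots <- character()
  for (u in seq_len(n)) {
    subs <- subsOf[[nodeRx[u]]]
    othersProduce <- unique(unlist(prodsOf[setdiff(rid, nodeRx[u])]))
    critA <- any(!(subs %in% othersProduce))
    degree <- sum(A[u, ] | A[, u]) # distinct neighbours either direction
    critB <- any(subs %in% compoundLinks) && degree <= 2
    if (critA || critB) roots <- c(roots, nodeId[u])
  }
  roots <- sort(roots)
  out <- list()
  for (root in roots) {
    visited <- root
    parent <- character()
    layer <- root
    while (length(layer)) {
      nxt <- character()
      for (u in layer) {
        nb <- nodeId[A[u, ]]
        for (v in sort(nb)) {
          if (!(v %in% visited)) {
            visited <- c(visited, v)
            parent[v] <- u
            nxt <- c(nxt, v)
          }
        }
      }
      layer <- nxt
    }
    leaves <- sort(setdiff(visited, parent))
    ecOf <- setNames(nodeEc, nodeId)
    for (leaf in leaves) {
      path <- leaf
      while (path[1] != root) path <- c(parent[[path[1]]], path)
      if (length(path) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        root = root, leaf = leaf, ecs = joinEcs(unname(ecOf[path])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(root = character(), leaf = character(),
                      ecs = character(), stringsAsFactors = FALSE)
  out <- out[order(out$root, out$leaf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Specification of a planted-structure nrESS database
#'
#' The generator plants \code{nFamilies} families of mutated copies of seed
#' sequences inside a pool of random background sequences, with organism
#' provenance placed at a chosen panel coverage. It is constructed so the
#' planted labels are an exact oracle at the 0.3 operating threshold under
#' the uniform matrix with gap cost 1:
#' \itemize{
#'   \item family seeds are rejection-sampled until pairwise alignment
#'     scores exceed \code{minSeedSeparation};
#'   \item each member mutates \code{Binomial(length, pMut)} positions (at
#'     least 1, so members differ from their seed), capped at
#'     \code{floor(0.375 * length)}, always to a different EC of the same
#'     first-level class (column cost at most 2/3), so the member-vs-seed
#'     score is at most \code{(2/3) * 0.375 = 0.25 < 0.3};
#'   \item background sequences are uniform draws from the alphabet at
#'     lengths disjoint from (and much longer than) family lengths, so with
#'     gap cost 1 the unavoidable gap columns alone push any
#'     family-vs-background score far above the threshold.
#' }
#'
#' @param nFamilies,familySize number and size of planted families.
#' @param pMut per-position mutation probability within a family.
#' @param nBackground number of background sequences.
#' @param familyLengthRange,backgroundLengthRange inclusive length ranges.
#' @param panelSize organism panel size.
#' @param plantedCoverage fraction of the panel covered by each family's
#'   provenance.
#' @param minSeedSeparation minimum pairwise seed alignment score.
#' @param ecAlphabet EC alphabet.
#' @param seed integer seed.
#' @return list of class \code{"PlantedDatabaseSpec"}.
#' @export
plantedDatabaseSpec <- function(nFamilies = 20L, familySize = 10L,
                                pMut = 0.1, nBackground = 300L,
                                familyLengthRange = c(4L, 6L),
                                backgroundLengthRange = c(10L, 14L),
                                panelSize = 40L, plantedCoverage = 0.8,
                                minSeedSeparation = 0.7,
                                ecAlphabet = defaultEcAlphabet(),
                                seed = 1L) {
  stopifnot(pMut >= 0, pMut <= 1, plantedCoverage > 0, plantedCoverage <= 1,
            length(ecAlphabet) >= 4)
  structure(list(nFamilies = as.integer(nFamilies),
                 familySize = as.integer(familySize), pMut = pMut,
                 nBackground = as.integer(nBackground),
                 familyLengthRange = as.integer(familyLengthRange),
                 backgroundLengthRange = as.integer(backgroundLengthRange),
                 panelSize = as.integer(panelSize),
                 plantedCoverage = plantedCoverage,
                 minSeedSeparation = minSeedSeparation,
                 ecAlphabet = ecAlphabet, seed = as.integer(seed)),
            class = "PlantedDatabaseSpec")
}

# mutate one family member: k positions to a same-class sibling EC
# (column cost at most 2/3 under the uniform matrix)
mutateMember <- function(seedSeq, k, alphabet) {
  if (k == 0L) return(seedSeq)
  pos <- sample(seq_along(seedSeq), k)
  for (p in pos) {
    cl <- strsplit(seedSeq[p], ".", fixed = TRUE)[[1]][1]
    sibs <- setdiff(alphabet[startsWith(alphabet, paste0(cl, "."))],
                    seedSeq[p])
    if (!length(sibs))
      stop("alphabet too small for requested diversity", call. = FALSE)
    seedSeq[p] <- sample(sibs, 1L)
  }
  seedSeq
}

#' Generate a planted-structure nrESS database
#'
#' See \code{\link{plantedDatabaseSpec}} for the construction and the
#' guarantees that make the returned family labels a test oracle. Every
#' family is assigned one dedicated map id (\code{"1xxxx"}) and a provenance
#' organism set covering \code{plantedCoverage} of the panel; background
#' sequences get 1-3 random organisms on background maps (\code{"2xxxx"}).
#'
#' @param spec a \code{\link{plantedDatabaseSpec}}.
#' @return list with \code{db} (an \linkS4class{NRESSDatabase}),
#'   \code{labels} (data.frame \code{nr_id, family, role}; family 0 marks
#'   background), \code{panel} (organism panel), and \code{spec}.
#' @export
generatePlantedDatabase <- function(spec) {
  stopifnot(inherits(spec, "PlantedDatabaseSpec"))
  alphabet <- spec$ecAlphabet
  wm <- buildWeightMatrix(alphabet)
  panel <- sprintf("org%02d", seq_len(spec$panelSize))
  nCov <- ceiling(spec$plantedCoverage * spec$panelSize)

  res <- withSeed(spec$seed, {
    seen <- character()
    ecs <- character(); family <- integer(); role <- character()
    org <- list(); map <- character()

    randSeq <- function(range) {
      len <- sample(seq(range[1], range[2]), 1L)
      sample(alphabet, len, replace = TRUE)
    }

    seeds <- list()
    for (f in seq_len(spec$nFamilies)) {
      repeat {
        cand <- randSeq(spec$familyLengthRange)
        sep <- all(vapply(seeds, function(s)
          alignmentScore(alignESS(cand, s, wm)) > spec$minSeedSeparation,
          logical(1)))
        if (sep && !(joinEcs(cand) %in% seen)) break
      }
      seeds[[f]] <- cand
      famMap <- sprintf("1%04d", f)
      famOrgs <- sort(sample(panel, nCov))
      addSeq <- function(s, r) {
        ecs <<- c(ecs, joinEcs(s)); seen <<- c(seen, joinEcs(s))
        family <<- c(family, f); role <<- c(role, r)
        org[[length(org) + 1L]] <<- famOrgs; map <<- c(map, famMap)
      }
      addSeq(cand, "seed")
      cap <- floor(0.375 * length(cand))
      for (m in seq_len(spec$familySize - 1L)) {
        tries <- 0L
        repeat {
          k <- min(max(stats::rbinom(1L, length(cand), spec$pMut), 1L), cap)
          memb <- mutateMember(cand, k, alphabet)
          if (!(joinEcs(memb) %in% seen)) break
          tries <- tries + 1L
          if (tries > 200L)
            stop("alphabet too small for requested diversity", call. = FALSE)
        }
        addSeq(memb, "member")
      }
    }
    for (b in seq_len(spec$nBackground)) {
      repeat {
        cand <- randSeq(spec$backgroundLengthRange)
        if (!(joinEcs(cand) %in% seen)) break
      }
      ecs <- c(ecs, joinEcs(cand)); seen <- c(seen, joinEcs(cand))
      family <- c(family, 0L); role <- c(role, "background")
      org[[length(org) + 1L]] <- sort(sample(panel, sample(1:3, 1L)))
      map <- c(map, sprintf("2%04d", sample(10L, 1L)))
    }
    list(ecs = ecs, family = family, role = role, org = org, map = map)
  })

  nrIds <- sprintf("nr%06d", seq_along(res$ecs))
  sequences <- data.frame(nr_id = nrIds, ecs = res$ecs,
                          stringsAsFactors = FALSE)
  prov <- do.call(rbind, lapply(seq_along(nrIds), function(k)
    data.frame(nr_id = nrIds[k], organism = res$org[[k]],
               map_id = res$map[k], stringsAsFactors = FALSE)))
  rownames(prov) <- NULL
  db <- new("NRESSDatabase", sequences = sequences, provenance = prov)
  labels <- data.frame(nr_id = nrIds, family = res$family, role = res$role,
                       stringsAsFactors = FALSE)
  list(db = db, labels = labels, panel = panel, spec = spec)
}

#' Generate a planted block-structured map similarity matrix
#'
#' Directly plants \code{nBlocks} groups of maps whose shared-alignment
#' count profiles are concentrated within their own block, with weak noise
#' between blocks, so average-linkage clustering at the planted cut
#' recovers the blocks exactly.
#'
#' @param nBlocks,mapsPerBlock block structure.
#' @param withinMean,betweenMean Poisson means of within- and between-block
#'   shared-alignment counts.
#' @param seed integer seed.
#' @return list with \code{msm} (a \linkS4class{MapSimilarityMatrix}),
#'   \code{labels} (named integer block assignment) and \code{cutFraction}
#'   (the planted dendrogram cut, 0.5).
#' @export
generatePlantedMapBlocks <- function(nBlocks = 3L, mapsPerBlock = 5L,
                                     withinMean = 30, betweenMean = 0.5,
                                     seed = 1L) {
  maps <- as.vector(vapply(seq_len(nBlocks), function(b)
    sprintf("%03d%02d", b, seq_len(mapsPerBlock)), character(mapsPerBlock)))
  block <- rep(seq_len(nBlocks), each = mapsPerBlock)
  n <- length(maps)
  counts <- withSeed(seed, {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      lam <- if (block[i] == block[j]) withinMean else betweenMean
      v <- stats::rpois(1, lam) + if (block[i] == block[j]) 5 else 0
      m[i, j] <- v; m[j, i] <- v
    }
    m
  })
  dimnames(counts) <- list(maps, maps)
  rs <- rowSums(counts)
  normalized <- counts
  nz <- rs > 0
  normalized[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  msm <- new("MapSimilarityMatrix", maps = maps, counts = counts,
             normalized = normalized)
  list(msm = msm, labels = setNames(block, maps), cutFraction = 0.5)
}

#' Conservation test fixture: one map planted at a chosen panel coverage
#'
#' Four sequences on one map, each differing from the others in at most two
#' third-level EC substitutions arranged so that every clade EC occurs in at
#' least one identical aligned column of some pair (conserved proportion 1
#' when the pairs pass the coverage filter). Placing the provenance on
#' \code{coverage} of the panel switches the map between the
#' \code{conserved} (high coverage) and \code{non_conserved} (low coverage)
#' categories.
#'
#' @param nOrganisms panel size; default 40.
#' @param coverage fraction of the panel carrying the map's sequences.
#' @param mapId map id; default \code{"00300"}.
#' @return list with \code{db} (an \linkS4class{NRESSDatabase}),
#'   \code{panel} and \code{mapId}.
#' @export
generateConservationFixture <- function(nOrganisms = 40L, coverage = 0.8,
                                        mapId = "00300") {
  A <- "2.7.1"; A2 <- "2.7.3"; B <- "4.1.2"; B2 <- "4.1.3"
  core <- c("1.2.1", "2.7.2", "5.3.1")
  seqs <- c(joinEcs(c(A, B, core)), joinEcs(c(A2, B, core)),
            joinEcs(c(A2, B2, core)), joinEcs(c(A, B2, core)))
  panel <- sprintf("org%02d", seq_len(nOrganisms))
  orgs <- panel[seq_len(max(1L, ceiling(coverage * nOrganisms)))]
  nrIds <- sprintf("nr%06d", seq_along(seqs))
  sequences <- data.frame(nr_id = nrIds, ecs = seqs, stringsAsFactors = FALSE)
  prov <- do.call(rbind, lapply(nrIds, function(id)
    data.frame(nr_id = id, organism = orgs, map_id = mapId,
               stringsAsFactors = FALSE)))
  rownames(prov) <- NULL
  list(db = new("NRESSDatabase", sequences = sequences, provenance = prov),
       panel = panel, mapId = mapId)
}
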