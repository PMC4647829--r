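#' Parse a KGML pathway document
#'
#' Reads a KGML (KEGG Markup Language) XML document into a
#' \linkS4class{PathwayModel}. Only the elements the sequence-extraction
#' pipeline needs are interpreted:
#' \itemize{
#'   \item \code{<reaction>} elements with their \code{<substrate>} /
#'     \code{<product>} children and the \code{type="reversible"} attribute;
#'   \item \code{<entry>} elements of enzyme-like type (\code{enzyme},
#'     \code{gene}, \code{ortholog}) carrying a \code{reaction} attribute,
#'     used to attach EC labels (tokens of the entry \code{name}) to
#'     reactions;
#'   \item \code{<entry type="compound">} elements with a \code{link}
#'     attribute, recorded as compounds entering from another metabolic map.
#' }
#' All other KGML content is ignored. Compound ids are the raw KGML id
#' strings with a leading \code{"cpd:"}/\code{"gl:"} prefix stripped; no
#' chemical normalisation is applied.
#'
#' Malformed XML fails fast with the parser's location message; a well-formed
#' document with no reactions yields a valid model with an empty reaction
#' list (and no sequences downstream).
#'
#' @param xml path to a KGML file, or a KGML document as a single string.
#' @param organism,mapId optional overrides; by default taken from the
#'   pathway element's \code{org} and \code{number} attributes, falling back
#'   to the \code{<org><mapid>.xml} file-name convention.
#' @return a \linkS4class{PathwayModel}.
#' @export
parseKGML <- function(xml, organism = NULL, mapId = NULL) {
  doc <- xml2::read_xml(xml)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing"))
    stop("not a KGML document: missing <pathway> root", call. = FALSE)

  org <- organism %||% xml2::xml_attr(root, "org")
  num <- mapId %||% xml2::xml_attr(root, "number")
  if ((is.na(org) || is.na(num)) && is.character(xml) && file.exists(xml)) {
    base <- sub("\\.xml$", "", basename(xml))
    if (grepl("^[a-zA-Z]+[0-9]{5}$", base)) {
      if (is.na(org)) org <- sub("[0-9]{5}$", "", base)
      if (is.na(num)) num <- sub("^[a-zA-Z]+", "", base)
    }
  }
  if (is.na(org) || !nzchar(org)) org <- "unk"
  if (is.na(num) || !nzchar(num)) stop("pathway map id missing", call. = FALSE)

  stripPrefix <- function(x) sub("^(cpd:|gl:|dr:)", "", x)

  # EC labels per reaction name, from enzyme-like entries
  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  ecByReaction <- list()
  compoundLinks <- character()
  for (e in entries) {
    type <- xml2::xml_attr(e, "type")
    if (isTRUE(type %in% c("enzyme", "gene", "ortholog"))) {
      rns <- xml2::xml_attr(e, "reaction")
      if (is.na(rns)) next
      toks <- strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]]
      ecs <- toks[grepl("^ec:", toks)]
      if (!length(ecs)) next
      for (rn in strsplit(rns, "\\s+")[[1]]) {
        ecByReaction[[rn]] <- c(ecByReaction[[rn]], sub("^ec:", "", ecs))
      }
    } else if (isTRUE(type == "compound") && !is.na(xml2::xml_attr(e, "link"))) {
      nm <- strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]]
      compoundLinks <- c(compoundLinks, stripPrefix(nm))
    }
  }

  rxNodes <- xml2::xml_find_all(doc, "/pathway/reaction")
  reactions <- lapply(rxNodes, function(r) {
    rid <- xml2::xml_attr(r, "name")
    if (is.na(rid)) rid <- xml2::xml_attr(r, "id")
    subs <- stripPrefix(xml2::xml_attr(
      xml2::xml_find_all(r, "./substrate"), "name"))
    prods <- stripPrefix(xml2::xml_attr(
      xml2::xml_find_all(r, "./product"), "name"))
    list(reaction_id = rid,
         ec_labels = unique(ecByReaction[[rid]] %||% character()),
         substrates = unique(subs),
         products = unique(prods),
         reversible = identical(xml2::xml_attr(r, "type"), "reversible"))
  })

  new("PathwayModel", organism = org, mapId = num, reactions = reactions,
      compoundLinks = unique(compoundLinks))
}

# effective substrate/product sets of a reaction: a reversible reaction acts
# as two opposite directed reactions sharing one node
reactionSides <- function(r) {
  if (isTRUE(r$reversible)) {
    list(substrates = unique(c(r$substrates, r$products)),
         products = unique(c(r$substrates, r$products)))
  } else {
    list(substrates = r$substrates, products = r$products)
  }
}

#' Build the directed enzyme graph of a pathway
#'
#' One node per (reaction, distinct 3-level EC) pair; isozymes (several raw
#' EC labels truncating to the same 3-level EC on one reaction) collapse into
#' one node, and a reaction without any EC label gets a single node with the
#' \code{"9.9.9"} sentinel. A directed edge \code{u -> v} labelled with
#' compound \code{c} exists when \code{c} is a product of \code{u}'s
#' reaction and a substrate of \code{v}'s reaction; reversible reactions
#' contribute both orientations through the same node. Self-loops and edges
#' between nodes of the same reaction are excluded.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @param excludeCompounds optional character vector of compound ids (e.g.
#'   currency metabolites) to ignore when forming edges; default none.
#' @return a \linkS4class{MetabolicGraph}.
#' @export
buildEnzymeGraph <- function(model, excludeCompounds = character()) {
  stopifnot(is(model, "PathwayModel"))
  nodes <- data.frame(node_id = character(), ec = character(),
                      reaction_id = character(), stringsAsFactors = FALSE)
  for (r in model@reactions) {
    ecs <- unique(parseEC(r$ec_labels))
    if (!length(ecs)) ecs <- EC_UNKNOWN
    nodes <- rbind(nodes, data.frame(
      node_id = paste(r$reaction_id, ecs, sep = "|"),
      ec = ecs, reaction_id = r$reaction_id, stringsAsFactors = FALSE))
  }
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL

  sides <- lapply(model@reactions, reactionSides)
  names(sides) <- vapply(model@reactions, `[[`, character(1), "reaction_id")

  from <- character(); to <- character(); comp <- character()
  if (nrow(nodes) > 1) {
    for (ui in seq_len(nrow(nodes))) {
      u <- nodes[ui, ]
      pu <- setdiff(sides[[u$reaction_id]]$products, excludeCompounds)
      if (!length(pu)) next
      for (vi in seq_len(nrow(nodes))) {
        v <- nodes[vi, ]
        if (u$node_id == v$node_id || u$reaction_id == v$reaction_id) next
        sv <- sides[[v$reaction_id]]$substrates
        for (c in intersect(pu, sv)) {
          from <- c(from, u$node_id); to <- c(to, v$node_id)
          comp <- c(comp, c)
        }
      }
    }
  }
  edges <- data.frame(from = from, to = to, compound = comp,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, edges$compound), , drop = FALSE]
  rownames(edges) <- NULL
  new("MetabolicGraph", nodes = nodes, edges = edges,
      compoundLinks = model@compoundLinks,
      produced = lapply(sides, `[[`, "products"),
      consumed = lapply(sides, `[[`, "substrates"))
}

#' Dump a MetabolicGraph as TSV tables
#'
#' Writes \code{<prefix>.edges.tsv} (\code{from to compound}) and
#' \code{<prefix>.nodes.tsv} (\code{node_id ec reaction}).
#'
#' @param graph a \linkS4class{MetabolicGraph}.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
writeGraphTables <- function(graph, prefix) {
  ep <- paste0(prefix, ".edges.tsv")
  np <- paste0(prefix, ".nodes.tsv")
  utils::write.table(graph@edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph@nodes, np, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = ep, nodes = np))
}
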