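chainKGML <- function(n, reversible = logical(n), ecs = NULL,
                      links = character(), org = "tst", map = "00050") {
  # linear chain C1 -> C2 -> ... with optional per-reaction reversibility
  if (is.null(ecs)) ecs <- sprintf("%d.%d.%d", (seq_len(n) - 1) %% 6 + 1, 1, 1)
  lines <- c(sprintf('<pathway name="path:%s%s" org="%s" number="%s">',
                     org, map, org, map))
  for (cp in seq_len(n + 1)) {
    link <- if (sprintf("C%d", cp) %in% links) ' link="path:map99999"' else ""
    lines <- c(lines, sprintf(
      '<entry id="%d" name="cpd:C%d" type="compound"%s/>', cp, cp, link))
  }
  for (i in seq_len(n)) {
    lines <- c(lines,
      sprintf('<entry id="%d" name="ec:%s" type="enzyme" reaction="R%d"/>',
              100 + i, ecs[i], i),
      sprintf('<reaction id="R%d" type="%s">', i,
              if (reversible[i]) "reversible" else "irreversible"),
      sprintf('<substrate id="0" name="cpd:C%d"/>', i),
      sprintf('<product id="0" name="cpd:C%d"/>', i + 1),
      '</reaction>')
  }
  paste(c(lines, "</pathway>"), collapse = "\n")
}

test_that("criterion A selects nodes whose substrate is produced nowhere in the map", {
  g <- buildEnzymeGraph(parseKGML(chainKGML(3)))
  # only R1 consumes a compound (C1) produced by no reaction
  expect_identical(selectInitializationNodes(g), "R1|1.1.1")
})

test_that("criterion B requires a cross-map substrate and degree at most 2", {
  # star: R2, R3, R4 all consume C2 produced by R1; R1's substrate C1 is
  # cross-linked. R1 has 3 neighbours -> criterion B fails, but criterion A
  # still holds (C1 produced nowhere). Remove criterion A by making a
  # producer of C1: R5 produces C1 from C9 (C9 cross-linked, R5 degree 1).
  xml <- paste(
    '<pathway name="path:tst00051" org="tst" number="00051">',
    '<entry id="1" name="cpd:C1" type="compound" link="path:map00001"/>',
    '<entry id="2" name="cpd:C9" type="compound" link="path:map00002"/>',
    '<entry id="11" name="ec:1.1.1" type="enzyme" reaction="R1"/>',
    '<entry id="12" name="ec:2.1.1" type="enzyme" reaction="R2"/>',
    '<entry id="13" name="ec:3.1.1" type="enzyme" reaction="R3"/>',
    '<entry id="14" name="ec:4.1.1" type="enzyme" reaction="R4"/>',
    '<entry id="15" name="ec:5.1.1" type="enzyme" reaction="R5"/>',
    '<reaction id="R1" type="irreversible">',
    '<substrate id="0" name="cpd:C1"/><product id="0" name="cpd:C2"/>',
    '</reaction>',
    '<reaction id="R2" type="irreversible">',
    '<substrate id="0" name="cpd:C2"/><product id="0" name="cpd:C3"/>',
    '</reaction>',
    '<reaction id="R3" type="irreversible">',
    '<substrate id="0" name="cpd:C2"/><product id="0" name="cpd:C4"/>',
    '</reaction>',
    '<reaction id="R4" type="irreversible">',
    '<substrate id="0" name="cpd:C2"/><product id="0" name="cpd:C5"/>',
    '</reaction>',
    '<reaction id="R5" type="irreversible">',
    '<substrate id="0" name="cpd:C9"/><product id="0" name="cpd:C1"/>',
    '</reaction>',
    '</pathway>', sep = "\n")
  g <- buildEnzymeGraph(parseKGML(xml))
  roots <- selectInitializationNodes(g)
  # R1 consumes cross-linked C1 but has 3 neighbours (R2,R3,R4) and its C1
  # is produced by R5, so neither criterion holds for R1
  expect_false("R1|1.1.1" %in% roots)
  # R5 consumes cross-linked C9 (produced nowhere -> A holds anyway) with
  # degree 1 -> selected
  expect_true("R5|5.1.1" %in% roots)
})

test_that("a fully cyclic map with no external links yields no roots and no ESS", {
  xml <- paste(
    '<pathway name="path:tst00052" org="tst" number="00052">',
    '<entry id="11" name="ec:1.1.1" type="enzyme" reaction="R1"/>',
    '<entry id="12" name="ec:2.1.1" type="enzyme" reaction="R2"/>',
    '<entry id="13" name="ec:3.1.1" type="enzyme" reaction="R3"/>',
    '<reaction id="R1" type="irreversible">',
    '<substrate id="0" name="cpd:C1"/><product id="0" name="cpd:C2"/>',
    '</reaction>',
    '<reaction id="R2" type="irreversible">',
    '<substrate id="0" name="cpd:C2"/><product id="0" name="cpd:C3"/>',
    '</reaction>',
    '<reaction id="R3" type="irreversible">',
    '<substrate id="0" name="cpd:C3"/><product id="0" name="cpd:C1"/>',
    '</reaction>',
    '</pathway>', sep = "\n")
  g <- buildEnzymeGraph(parseKGML(xml))
  expect_identical(selectInitializationNodes(g), character())
})

test_that("BFS trees have the expected leaves and truncate cycles", {
  g <- buildEnzymeGraph(parseKGML(chainKGML(4)))
  tree <- buildBfsTree(g, "R1|1.1.1")
  expect_identical(tree@leaves, "R4|4.1.1")
  expect_length(tree@parent, 3L)
  expect_error(buildBfsTree(g, "absent"), "not in graph")

  # cycle reachable from the root: no node repeated
  xml <- paste(
    '<pathway name="path:tst00053" org="tst" number="00053">',
    '<entry id="11" name="ec:1.1.1" type="enzyme" reaction="R1"/>',
    '<entry id="12" name="ec:2.1.1" type="enzyme" reaction="R2"/>',
    '<entry id="13" name="ec:3.1.1" type="enzyme" reaction="R3"/>',
    '<reaction id="R1" type="irreversible">',
    '<substrate id="0" name="cpd:C0"/><product id="0" name="cpd:C1"/>',
    '</reaction>',
    '<reaction id="R2" type="irreversible">',
    '<substrate id="0" name="cpd:C1"/><product id="0" name="cpd:C2"/>',
    '</reaction>',
    '<reaction id="R3" type="irreversible">',
    '<substrate id="0" name="cpd:C2"/><product id="0" name="cpd:C1"/>',
    '</reaction>',
    '</pathway>', sep = "\n")
  g2 <- buildEnzymeGraph(parseKGML(xml))
  tree2 <- buildBfsTree(g2, "R1|1.1.1")
  expect_identical(sort(c(tree2@root, names(tree2@parent))),
                   sort(graphNodes(g2)$node_id))
  expect_false(anyDuplicated(names(tree2@parent)) > 0)
})

test_that("leaf-to-root tracing yields one ESS per branch, dropping singletons", {
  # root with a long and a short branch
  xml <- paste(
    '<pathway name="path:tst00054" org="tst" number="00054">',
    '<entry id="10" name="ec:2.7.1" type="enzyme" reaction="R0"/>',
    '<entry id="11" name="ec:4.1.2" type="enzyme" reaction="R1"/>',
    '<entry id="12" name="ec:1.2.1" type="enzyme" reaction="R2"/>',
    '<entry id="13" name="ec:2.7.2" type="enzyme" reaction="R3"/>',
    '<entry id="14" name="ec:5.3.1" type="enzyme" reaction="R4"/>',
    '<reaction id="R0" type="irreversible">',
    '<substrate id="0" name="cpd:C0"/><product id="0" name="cpd:C1"/>',
    '<product id="0" name="cpd:C5"/>',
    '</reaction>',
    '<reaction id="R1" type="irreversible">',
    '<substrate id="0" name="cpd:C1"/><product id="0" name="cpd:C2"/>',
    '</reaction>',
    '<reaction id="R2" type="irreversible">',
    '<substrate id="0" name="cpd:C2"/><product id="0" name="cpd:C3"/>',
    '</reaction>',
    '<reaction id="R3" type="irreversible">',
    '<substrate id="0" name="cpd:C3"/><product id="0" name="cpd:C4"/>',
    '</reaction>',
    '<reaction id="R4" type="irreversible">',
    '<substrate id="0" name="cpd:C5"/><product id="0" name="cpd:C6"/>',
    '</reaction>',
    '</pathway>', sep = "\n")
  g <- buildEnzymeGraph(parseKGML(xml))
  tree <- buildBfsTree(g, "R0|2.7.1")
  ess <- extractESS(tree, g)
  expect_setequal(ess$ecs,
                  c("2.7.1;4.1.2;1.2.1;2.7.2", "2.7.1;5.3.1"))

  # isolated root -> zero ESS
  g1 <- buildEnzymeGraph(parseKGML(chainKGML(1)))
  t1 <- buildBfsTree(g1, "R1|1.1.1")
  expect_identical(nrow(extractESS(t1, g1)), 0L)

  # chain of 4 -> single ESS of length 4
  g4 <- buildEnzymeGraph(parseKGML(chainKGML(4)))
  e4 <- extractESS(buildBfsTree(g4, "R1|1.1.1"), g4)
  expect_identical(nrow(e4), 1L)
  expect_length(strsplit(e4$ecs, ";")[[1]], 4L)
})

test_that("database build pools maps with provenance and reports zero-yield maps", {
  dir <- tempfile(); dir.create(dir)
  writeLines(chainKGML(3, org = "aaa", map = "00050"),
             file.path(dir, "aaa00050.xml"))
  writeLines(chainKGML(3, org = "bbb", map = "00050"),
             file.path(dir, "bbb00050.xml"))
  writeLines('<pathway name="path:ccc00060" org="ccc" number="00060"/>',
             file.path(dir, "ccc00060.xml"))
  db <- buildESSDatabase(dir)
  e <- essEntries(db)
  expect_identical(nrow(e), 2L)           # one chain ESS per organism
  expect_setequal(e$organism, c("aaa", "bbb"))
  expect_identical(db@zeroYield$organism, "ccc")

  # unreadable file: skipped in default mode, fatal in strict mode
  writeLines("<pathway", file.path(dir, "zzz00070.xml"))
  expect_warning(db2 <- buildESSDatabase(dir), "skipping")
  expect_length(db2@skipped, 1L)
  expect_error(suppressWarnings(buildESSDatabase(dir, strict = TRUE)))
})

test_that("database build is independent of file ordering", {
  dir1 <- tempfile(); dir.create(dir1)
  dir2 <- tempfile(); dir.create(dir2)
  for (k in 1:3) {
    sp <- pathwaySpec(nReactions = 6, pBranch = 0.4, seed = k,
                      organism = sprintf("o%02d", k), mapId = "00001")
    xml <- generateToyPathway(sp)$xml
    writeLines(xml, file.path(dir1, sprintf("o%02d00001.xml", k)))
    writeLines(xml, file.path(dir2, sprintf("o%02d00001.xml", k)))
  }
  db1 <- buildESSDatabase(list.files(dir1, full.names = TRUE))
  db2 <- buildESSDatabase(rev(list.files(dir2, full.names = TRUE)))
  expect_identical(essEntries(db1), essEntries(db2))
})

test_that("deduplication collapses identical tuples and conserves provenance", {
  e <- data.frame(
    organism = c("aaa", "bbb", "aaa"),
    map_id = c("00010", "00010", "00020"),
    root = "r", leaf = "l",
    ecs = c("1.1.1;2.2.2", "1.1.1;2.2.2", "3.3.3;4.4.4"),
    stringsAsFactors = FALSE)
  db <- new("ESSDatabase", entries = e,
            zeroYield = data.frame(organism = character(),
                                   map_id = character()),
            skipped = character())
  nr <- deduplicateESS(db)
  sq <- nrSequences(nr)
  expect_identical(nrow(sq), 2L)
  prov <- nrProvenance(nr)
  sharedId <- sq$nr_id[sq$ecs == "1.1.1;2.2.2"]
  expect_setequal(prov$organism[prov$nr_id == sharedId], c("aaa", "bbb"))
  # every original entry is covered by some provenance record
  expect_identical(nrow(prov), 3L)

  # all-distinct database: identity mapping
  e2 <- e; e2$ecs <- c("1.1.1;2.2.2", "1.1.1;3.3.3", "3.3.3;4.4.4")
  nr2 <- deduplicateESS(new("ESSDatabase", entries = e2,
                            zeroYield = db@zeroYield, skipped = character()))
  expect_identical(nrow(nrSequences(nr2)), 3L)
})

test_that("summaries report exact length histogram, mean and mode", {
  e <- data.frame(organism = "a", map_id = "00010", root = "r", leaf = "l",
                  ecs = c("1.1.1;2.2.2", "1.1.1;2.2.2;3.3.3",
                          "1.1.1;2.2.2;4.4.4", "1.1.1;2.2.2;3.3.3;4.4.4"),
                  stringsAsFactors = FALSE)
  db <- new("ESSDatabase", entries = e,
            zeroYield = data.frame(organism = character(),
                                   map_id = character()),
            skipped = character())
  s <- summarizeESS(db)
  expect_equal(s$mean, 3.0)
  expect_identical(s$mode, 3L)
  expect_identical(unname(s$lengths[c("2", "3", "4")]), c(1L, 2L, 1L))
})

test_that("extracted ESS never repeat a node within one sequence", {
  for (s in 1:10) {
    sp <- pathwaySpec(nReactions = 8, pBranch = 0.4, pReversible = 0.3,
                      pCycle = 0.25, seed = s)
    tp <- generateToyPathway(sp)
    g <- buildEnzymeGraph(parseKGML(tp$xml))
    for (r in selectInitializationNodes(g)) {
      tree <- buildBfsTree(g, r)
      expect_false(anyDuplicated(names(tree@parent)) > 0)
    }
  }
})
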