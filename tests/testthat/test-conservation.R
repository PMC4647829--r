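panel40 <- sprintf("org%02d", 1:40)

test_that("conserved pairs require both a low score and high panel coverage", {
  db <- makeNrDb(c("1.1.1;2.7.1", "1.1.1;2.7.2", "3.5.1;4.1.1"),
                 list(panel40[1:35], panel40[1:35], panel40[1:4]),
                 list("00010", "00010", "00010"))
  tab <- makeTable(i = c("nr000001", "nr000001", "nr000002"),
                   j = c("nr000002", "nr000003", "nr000003"),
                   score = c(0.2, 0.2, 0.4))
  cp <- conservedPairs(tab, db, 0.3, panel40, 0.75)
  # pair 1-2: score 0.2, union 35/40 -> kept
  # pair 1-3: score 0.2, union 35/40 (union includes orgs 1..35) -> kept
  # pair 2-3: score 0.4 -> rejected on score
  expect_identical(nrow(cp), 2L)
  expect_true(all(cp$score <= 0.3))

  # low-coverage union rejected
  db2 <- makeNrDb(c("1.1.1;2.7.1", "1.1.1;2.7.2"),
                  list(panel40[1:5], panel40[3:8]),
                  list("00010", "00010"))
  tab2 <- makeTable("nr000001", "nr000002", 0.2)
  expect_identical(nrow(conservedPairs(tab2, db2, 0.3, panel40, 0.75)), 0L)

  # strict per-sequence mode is more conservative than the union mode
  db3 <- makeNrDb(c("1.1.1;2.7.1", "1.1.1;2.7.2"),
                  list(panel40[1:20], panel40[21:40]),
                  list("00010", "00010"))
  tab3 <- makeTable("nr000001", "nr000002", 0.2)
  expect_identical(nrow(conservedPairs(tab3, db3, 0.3, panel40, 0.75)), 1L)
  expect_identical(nrow(conservedPairs(tab3, db3, 0.3, panel40, 0.75,
                                       coverageMode = "each")), 0L)

  # provenance outside the panel errors
  expect_error(conservedPairs(tab3, db3, 0.3, panel40[1:10], 0.75),
               "outside the panel")
})

test_that("the MMFCD keeps only pairs sharing a metabolic map", {
  db <- makeNrDb(c("1.1.1;2.7.1", "1.1.1;2.7.2", "1.1.1;2.7.3"),
                 list(panel40, panel40, panel40),
                 list("00010", "00010", "00230"))
  tab <- makeTable(i = c("nr000001", "nr000001"),
                   j = c("nr000002", "nr000003"),
                   score = c(0.1, 0.1))
  cp <- conservedPairs(tab, db, 0.3, panel40, 0.75)
  mm <- mmfcdPairs(cp)
  expect_identical(nrow(mm), 1L)
  expect_identical(mm$shared_maps, "00010")
  expect_identical(nrow(mmfcdPairs(cp[0, ])), 0L)
})

test_that("category boundaries match the four-way classification", {
  expect_identical(classifyMap(0.75), "conserved")
  expect_identical(classifyMap(0.70), "conserved")
  expect_identical(classifyMap(0.50), "moderately")
  expect_identical(classifyMap(0.30), "moderately")
  expect_identical(classifyMap(0.29), "barely")
  expect_identical(classifyMap(1e-6), "barely")
  expect_identical(classifyMap(0.0), "non_conserved")
  expect_error(classifyMap(1.2), "0, 1")
})

test_that("map conservation counts identical aligned columns against the clade EC set", {
  # two sequences differing in one third-level digit: identical columns
  # carry 2 of the 4 clade ECs -> 0.5, moderately conserved
  db <- makeNrDb(c("1.1.1;2.7.1;3.5.1", "1.1.1;2.7.2;3.5.1"),
                 list(panel40[1:35], panel40[1:35]),
                 list("00052", "00052"))
  m <- buildWeightMatrix(c("1.1.1", "2.7.1", "2.7.2", "3.5.1"))
  tab <- alignAllPairs(db, m)
  cp <- conservedPairs(tab, db, 0.3, panel40, 0.75)
  rep <- mapConservation(mmfcdPairs(cp), db, "00052", m)
  expect_setequal(rep@conservedEcs, c("1.1.1", "3.5.1"))
  expect_identical(length(rep@cladeEcs), 4L)
  expect_equal(rep@proportion, 0.5)
  expect_identical(rep@category, "moderately")

  # identity alignments conserve everything
  dbId <- makeNrDb(c("1.1.1;2.7.1", "1.1.1;2.7.1;3.5.1"),
                   list(panel40[1:35], panel40[1:35]),
                   list("00053", "00053"))
  tabId <- alignAllPairs(dbId, m)
  cpId <- conservedPairs(tabId, dbId, 0.5, panel40, 0.75)
  repId <- mapConservation(mmfcdPairs(cpId), dbId, "00053", m,
                           gap = 1.0)
  expect_setequal(repId@conservedEcs, c("1.1.1", "2.7.1"))

  # a map with no MMFCD pairs is non_conserved
  repNone <- mapConservation(mmfcdPairs(cp[0, ]), db, "00052", m)
  expect_equal(repNone@proportion, 0)
  expect_identical(repNone@category, "non_conserved")

  expect_error(mapConservation(mmfcdPairs(cp), db, "99999", m),
               "clade ECs")
})

test_that("identically aligned unknown enzymes never count as conserved", {
  db <- makeNrDb(c("9.9.9;2.7.1;3.5.1", "9.9.9;2.7.2;3.5.1"),
                 list(panel40[1:35], panel40[1:35]),
                 list("00054", "00054"))
  m <- buildWeightMatrix(c("2.7.1", "2.7.2", "3.5.1"))
  tab <- alignAllPairs(db, m)
  cp <- conservedPairs(tab, db, 0.3, panel40, 0.75)
  rep <- mapConservation(mmfcdPairs(cp), db, "00054", m)
  expect_false(EC_UNKNOWN %in% rep@conservedEcs)
  expect_false(EC_UNKNOWN %in% rep@cladeEcs)
})

test_that("threshold monotonicity: looser scores grow and stricter coverage shrinks the set", {
  fx <- generateConservationFixture(40, 0.8)
  m <- buildWeightMatrix(unique(unlist(strsplit(nrSequences(fx$db)$ecs,
                                                ";"))))
  tab <- alignAllPairs(fx$db, m)
  n1 <- nrow(conservedPairs(tab, fx$db, 0.1, fx$panel, 0.75))
  n2 <- nrow(conservedPairs(tab, fx$db, 0.3, fx$panel, 0.75))
  n3 <- nrow(conservedPairs(tab, fx$db, 0.3, fx$panel, 0.9))
  expect_lte(n1, n2)
  expect_lte(n3, n2)
})

test_that("panel coverage switches a planted map between conserved and non_conserved", {
  hi <- generateConservationFixture(40, 0.8)
  m <- buildWeightMatrix(unique(unlist(strsplit(nrSequences(hi$db)$ecs,
                                                ";"))))
  tabHi <- alignAllPairs(hi$db, m)
  cpHi <- conservedPairs(tabHi, hi$db, 0.3, hi$panel, 0.75)
  repHi <- mapConservation(mmfcdPairs(cpHi), hi$db, hi$mapId, m)
  expect_identical(repHi@category, "conserved")
  expect_gte(repHi@proportion, 0.7)

  lo <- generateConservationFixture(40, 0.1)
  tabLo <- alignAllPairs(lo$db, m)
  cpLo <- conservedPairs(tabLo, lo$db, 0.3, lo$panel, 0.75)
  repLo <- mapConservation(mmfcdPairs(cpLo), lo$db, lo$mapId, m)
  expect_identical(repLo@category, "non_conserved")
})
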