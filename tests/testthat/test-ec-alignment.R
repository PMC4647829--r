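test_that("EC parsing truncates, maps placeholders and rejects malformed input", {
  expect_identical(parseEC("2.7.1.11"), "2.7.1")
  expect_identical(parseEC("ec:4.1.2.13"), "4.1.2")
  expect_identical(parseEC(""), EC_UNKNOWN)
  expect_identical(parseEC("-"), EC_UNKNOWN)
  expect_identical(parseEC(c("1.1.1", "2.7.1.2")), c("1.1.1", "2.7.1"))
  expect_error(parseEC("2.7"), "fewer than 3 levels")
  expect_error(parseEC("2.7.x"), "non-numeric")
})

test_that("the uniform weight matrix follows the EC hierarchy and sentinel rules", {
  m <- buildWeightMatrix(c("1.1.1", "1.1.2", "1.2.1", "2.7.1"))
  expect_equal(ecDistance(m, "1.1.1", "1.1.1"), 0)
  expect_equal(ecDistance(m, "1.1.1", "1.1.2"), 1 / 3)
  expect_equal(ecDistance(m, "1.2.1", "1.1.1"), 2 / 3)
  expect_equal(ecDistance(m, "1.2.1", "2.7.1"), 1)
  expect_equal(ecDistance(m, EC_UNKNOWN, "1.1.1"), 1)
  expect_equal(ecDistance(m, EC_UNKNOWN, EC_UNKNOWN), 0)
  expect_error(ecDistance(m, "5.5.5", "1.1.1"), "catalogue")
})

test_that("the entropy matrix respects hierarchy bounds and needs counts", {
  cat <- c("1.1.1", "1.1.2", "1.2.1", "2.7.1", "2.7.2")
  expect_error(buildWeightMatrix(cat, mode = "entropy"), "counts")
  counts <- c("1.1.1" = 50, "1.1.2" = 30, "1.2.1" = 10, "2.7.1" = 40,
              "2.7.2" = 5)
  m <- buildWeightMatrix(cat, mode = "entropy", counts = counts)
  d <- as.matrix(m)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(d) == 0))
  expect_equal(max(abs(d - t(d))), 0)
  expect_equal(ecDistance(m, "1.1.1", "2.7.1"), 1)  # first level differs
  expect_equal(ecDistance(m, EC_UNKNOWN, "1.1.1"), 1)
  # same-subclass pair measured inside a smaller class than a cross-subclass
  # pair of the same first level
  expect_lt(ecDistance(m, "1.1.1", "1.1.2"), ecDistance(m, "1.1.1", "1.2.1"))
  expect_gt(ecDistance(m, "1.1.1", "1.1.2"), 0)
})

test_that("alignment reproduces hand-enumerated costs and scores", {
  m <- buildWeightMatrix(c("2.7.1", "4.1.2", "4.1.3", "1.2.1", "3.5.1",
                           "6.3.1", "1.1.1"))
  idem <- alignESS(c("2.7.1", "4.1.2"), c("2.7.1", "4.1.2"), m)
  expect_equal(alignmentScore(idem), 0)

  one <- alignESS(c("2.7.1", "4.1.2", "1.2.1"),
                  c("2.7.1", "4.1.3", "1.2.1"), m)
  expect_equal(alignmentCost(one), 1 / 3)
  expect_equal(alignmentScore(one), 1 / 9)

  far <- alignESS(c("2.7.1", "4.1.2", "1.2.1"),
                  c("3.5.1", "6.3.1", "1.1.1"), m)
  expect_equal(alignmentScore(far), (1 + 1 + 2 / 3) / 3)

  # projecting out gaps recovers the inputs
  aln <- alignESS(c("2.7.1", "4.1.2", "1.2.1", "3.5.1"),
                  c("2.7.1", "1.2.1"), m)
  cols <- alignmentColumns(aln)
  expect_identical(cols$a[!is.na(cols$a)],
                   c("2.7.1", "4.1.2", "1.2.1", "3.5.1"))
  expect_identical(cols$b[!is.na(cols$b)], c("2.7.1", "1.2.1"))
  expect_false(any(is.na(cols$a) & is.na(cols$b)))

  expect_error(alignESS(c("9.8.7"), c("2.7.1"), m), "catalogue")
  expect_error(alignESS(character(), c("2.7.1"), m), "empty")
})

test_that("dynamic programming matches exhaustive enumeration on random pairs", {
  alphabet <- defaultEcAlphabet()[1:10]
  m <- buildWeightMatrix(alphabet)
  set.seed(41)
  for (k in 1:200) {
    a <- sample(alphabet, sample(1:6, 1), replace = TRUE)
    b <- sample(alphabet, sample(1:6, 1), replace = TRUE)
    dp <- alignESS(a, b, m)
    bf <- bruteForceAlignment(a, b, m)
    expect_equal(alignmentCost(dp), bf$cost, tolerance = 1e-10)
  }
})

test_that("scores are symmetric, in [0,1], zero on identity and one on disjoint classes", {
  alphabet <- defaultEcAlphabet()
  m <- buildWeightMatrix(alphabet)
  set.seed(42)
  for (k in 1:250) {
    a <- sample(alphabet, sample(2:7, 1), replace = TRUE)
    b <- sample(alphabet, sample(2:7, 1), replace = TRUE)
    sab <- alignmentScore(alignESS(a, b, m))
    sba <- alignmentScore(alignESS(b, a, m))
    expect_equal(sab, sba, tolerance = 1e-10)
    expect_gte(sab, 0)
    expect_lte(sab, 1)
    expect_equal(alignmentScore(alignESS(a, a, m)), 0)
  }
  # equal-length, no shared first-level class -> score exactly 1
  classA <- alphabet[startsWith(alphabet, "1.")]
  classB <- alphabet[startsWith(alphabet, "2.")]
  set.seed(43)
  for (k in 1:50) {
    len <- sample(2:6, 1)
    a <- sample(classA, len, replace = TRUE)
    b <- sample(classB, len, replace = TRUE)
    expect_equal(alignmentScore(alignESS(a, b, m)), 1)
  }
})

test_that("appending an identical EC to both sequences never increases the score", {
  alphabet <- defaultEcAlphabet()
  m <- buildWeightMatrix(alphabet)
  set.seed(44)
  for (k in 1:100) {
    a <- sample(alphabet, sample(2:6, 1), replace = TRUE)
    b <- sample(alphabet, sample(2:6, 1), replace = TRUE)
    x <- sample(alphabet, 1)
    s0 <- alignmentScore(alignESS(a, b, m))
    s1 <- alignmentScore(alignESS(c(a, x), c(b, x), m))
    expect_lte(s1, s0 + 1e-10)
  }
})

test_that("all-against-all scores every unordered pair exactly once", {
  expect_equal(expectedPairCount(2), 1)
  expect_equal(expectedPairCount(500), 124750)
  db <- makeNrDb(c("1.1.1;2.7.1", "1.1.1;2.7.2", "3.5.1;4.1.1;5.3.1"),
                 list("a", "a", "b"), list("00010", "00010", "00020"))
  m <- buildWeightMatrix(c("1.1.1", "2.7.1", "2.7.2", "3.5.1", "4.1.1",
                           "5.3.1"))
  tab <- alignAllPairs(db, m)
  r <- alignmentRecords(tab)
  expect_identical(nrow(r), 3L)
  expect_true(all(r$i < r$j))
  expect_identical(alignmentSettings(tab)$n_pairs, 3)
  # ceiling filters storage but not the pair count
  tab2 <- alignAllPairs(db, m, keepCeiling = 0.2)
  expect_identical(alignmentSettings(tab2)$n_pairs, 3)
  expect_true(all(alignmentRecords(tab2)$score <= 0.2 + 1e-12))
  # n < 2 warns and returns an empty table
  db1 <- makeNrDb("1.1.1;2.7.1", list("a"), list("00010"))
  expect_warning(tab3 <- alignAllPairs(db1, m), "fewer than 2")
  expect_identical(nrow(alignmentRecords(tab3)), 0L)
})

test_that("weight matrix TSV export writes 6-decimal distances", {
  m <- buildWeightMatrix(c("1.1.1", "1.1.2"))
  f <- tempfile(fileext = ".tsv")
  writeWeightMatrix(m, f)
  tab <- read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(tab[tab$ec == "1.1.1", "1.1.2"], 0.333333)
})
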