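test_that("edit distance matches the textbook recurrence and its axioms", {
  expect_identical(levenshteinDistance("ACGT", "ACGT"), 0L)
  expect_identical(levenshteinDistance("AC", "A"), 1L)
  # frozen from the recurrence oracle: two substitutions, no transposition
  expect_identical(oracleEditCross("ACGT", "AGCT")[1L, 1L], 2)
  expect_identical(levenshteinDistance("ACGT", "AGCT"), 2L)
  expect_identical(levenshteinDistance("", "ACG"), 3L)

  withr::with_seed(4L, {
    strs <- vapply(sample(0:5, 30, replace = TRUE), function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), "")
  })
  d <- outer(strs, strs, levenshteinDistance)
  expect_equal(unname(d), oracleEditCross(strs, strs))
  expect_identical(d, t(d))
  # triangle inequality over all triples
  for (k in seq_along(strs))
    expect_true(all(d <= outer(d[, k], d[k, ], `+`)))
})

test_that("sequence similarity follows 1 - dis/(len_i + len_j)", {
  seqs <- c(c1 = "ACGT", c2 = "ACGT", c3 = "A", c4 = "AC")
  cc <- simMatrix(sequenceSimilarityMatrix(seqs, names(seqs)))
  expect_equal(cc["c1", "c2"], 1)
  expect_equal(cc["c3", "c4"], 1 - 1 / 3)
  expect_equal(diag(cc), stats::setNames(rep(1, 4), names(seqs)))

  # no shared symbols at equal length L: distance L, similarity 1/2
  dis <- c(p = "AAAA", q = "CCCC")
  expect_equal(simMatrix(sequenceSimilarityMatrix(dis))["p", "q"], 0.5)

  expect_error(sequenceSimilarityMatrix(seqs, c("c1", "missing")),
               "missing")
})

test_that("semantic contributions decay along shortest is_a paths", {
  # d -> p -> g and d -> q -> r -> g: max rule keeps the 2-hop path
  ont <- DiseaseOntology(list(d = c("p", "q"), p = "g", q = "r", r = "g"),
                         decay = 0.5)
  s <- semanticContributions(ont, "d")
  expect_equal(s[["d"]], 1)
  expect_equal(s[["p"]], 0.5)
  expect_equal(s[["g"]], 0.25)
  expect_setequal(names(s), c("d", "p", "q", "r", "g"))
  # non-increasing along every child -> parent edge inside the closure
  for (ch in names(s)) for (par in termParents(ont)[[ch]])
    expect_lte(s[[par]], s[[ch]])
  expect_error(semanticContributions(ont, "nope"), "not in the ontology")
})

test_that("semantic similarity reproduces closed forms on small DAGs", {
  ont <- DiseaseOntology(list(d1 = "p", d2 = "p"), decay = 0.5)
  dd <- simMatrix(semanticSimilarityMatrix(ont, c("d1", "d2")))
  expect_equal(dd["d1", "d1"], 1)
  # siblings under a sole parent: (0.5 + 0.5) / (1.5 + 1.5)
  expect_equal(dd["d1", "d2"], 1 / 3)

  ont2 <- DiseaseOntology(list(a = "r1", b = "r2"), decay = 0.5)
  dd2 <- simMatrix(semanticSimilarityMatrix(ont2, c("a", "b")))
  expect_equal(dd2["a", "b"], 0)
})

test_that("GIP bandwidth is the inverse mean squared profile norm", {
  ids <- list(c("c1", "c2"), c("d1", "d2"))
  eye <- CircAssoc(matrix(c(1, 0, 0, 1), 2, 2, dimnames = ids))
  expect_equal(gipBandwidth(eye, "disease"), 1)
  expect_equal(gipBandwidth(eye, "circ"), 1)
  ones <- CircAssoc(matrix(1, 2, 2, dimnames = ids))
  expect_equal(gipBandwidth(ones, "circ"), 1 / 2)
  zero <- CircAssoc(matrix(0, 2, 2, dimnames = ids))
  expect_error(gipBandwidth(zero, "circ"), "all-zero")
})

test_that("GIP kernels hit the closed form and the kernel contract", {
  ids <- list(c("c1", "c2"), c("d1", "d2"))
  eye <- CircAssoc(matrix(c(1, 0, 0, 1), 2, 2, dimnames = ids))
  kc <- simMatrix(gipSimilarityMatrix(eye, "circ"))
  expect_equal(kc["c1", "c2"], exp(-2))
  expect_equal(dim(kc), c(2L, 2L))
  kd <- simMatrix(gipSimilarityMatrix(eye, "disease"))
  expect_equal(dim(kd), c(2L, 2L))

  # identical profiles give exactly 1; empty-vs-empty likewise
  a <- matrix(0, 3, 2, dimnames = list(c("c1", "c2", "c3"), c("d1", "d2")))
  a[1, 1] <- a[2, 1] <- 1
  k <- simMatrix(gipSimilarityMatrix(CircAssoc(a), "circ"))
  expect_equal(k["c1", "c2"], 1)
  b <- gipBandwidth(CircAssoc(a), "circ")
  expect_equal(k["c1", "c3"], exp(-b))  # empty profile vs one association

  # symmetric, unit diagonal, entries in (0, 1], PSD, on seeded matrices
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- matrix(rbinom(60, 1, 0.3), 10, 6,
                  dimnames = list(sprintf("c%02d", 1:10),
                                  sprintf("d%d", 1:6)))
    })
    if (sum(m) == 0) m[1, 1] <- 1
    for (axis in c("circ", "disease")) {
      v <- simMatrix(gipSimilarityMatrix(CircAssoc(m), axis))
      expect_identical(v, t(v))
      expect_equal(unname(diag(v)), rep(1, nrow(v)))
      expect_true(all(v > 0 & v <= 1))
      expect_gte(min(eigen(v, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
    }
  }
})
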