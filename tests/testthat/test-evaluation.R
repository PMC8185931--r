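test_that("threshold-sweep AUC matches pairwise concordance", {
  expect_equal(rocAuc(c(0.9, 0.1), c(1, 0))$auc, 1)
  expect_equal(rocAuc(c(0.1, 0.9), c(1, 0))$auc, 0)
  r <- rocAuc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)  # 3 of 4 positive/negative pairs concordant
  expect_equal(r$auc, oracleAucConcordance(c(0.8, 0.6, 0.4, 0.2),
                                           c(1, 0, 1, 0)))
  expect_error(rocAuc(c(1, 2), c(1, 1)), "both a positive and a negative")

  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(3:12, 1)
      sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # heavy ties
      lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
      expect_equal(rocAuc(sc, lb)$auc, oracleAucConcordance(sc, lb))
    }
  })
})

test_that("ROC curves are monotone from (0,0) to (1,1) and complementary", {
  withr::with_seed(12, {
    sc <- runif(20)
    lb <- c(0, 1, rbinom(18, 1, 0.4))
  })
  r <- rocAuc(sc, lb)
  expect_equal(r$tpr[[1L]], 0)
  expect_equal(r$fpr[[1L]], 0)
  expect_equal(r$tpr[[length(r$tpr)]], 1)
  expect_equal(r$fpr[[length(r$fpr)]], 1)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  # trapezoid integral consistency
  expect_equal(r$auc, sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2))
  # tie-free scores: reversing the ranking mirrors the AUC
  expect_equal(rocAuc(sc, lb)$auc + rocAuc(-sc, lb)$auc, 1)
})

test_that("leave-one-out separates a constructed two-positive toy", {
  a <- matrix(0, 6, 3, dimnames = list(sprintf("c%d", 1:6),
                                       sprintf("d%d", 1:3)))
  a["c1", "d1"] <- a["c2", "d1"] <- 1
  cc <- matrix(0.1, 6, 6, dimnames = list(rownames(a), rownames(a)))
  diag(cc) <- 1
  cc["c1", "c2"] <- cc["c2", "c1"] <- 0.95
  rep <- loocv(CircAssoc(a), SimilarityMatrix(cc, "CC"),
               toySimilarity(colnames(a), 0.1, "DD"))
  expect_equal(rep$perRunAuc, 1)
  expect_length(rep$perRunAuc, 1L)
  expect_identical(rep$nRepeats, 1L)
})

test_that("leave-one-out beats a label-shuffled baseline on planted data", {
  inst <- simulateInstance(nc = 30, nd = 12, rank = 2, density = 0.05,
                           seed = 7)
  rep <- loocv(inst$assoc, inst$CC, inst$DD)
  n1 <- sum(assocMatrix(inst$assoc))
  n0 <- sum(assocMatrix(inst$assoc) == 0)
  pooled <- c(rep$roc$tpr, rep$roc$fpr)  # touch the stored curve
  expect_true(all(is.finite(pooled)))
  # shuffle control: same pooled scores, labels permuted
  full <- dmccdaPredict(inst$assoc, inst$CC, inst$DD)
  neg <- scoreMatrix(full)[assocMatrix(inst$assoc) == 0]
  withr::with_seed(7, {
    shuffled <- mean(replicate(20, {
      lab <- sample(c(rep(1, n1), rep(0, n0)))
      rocAuc(c(scoreMatrix(full)[assocMatrix(inst$assoc) == 1], neg), lab)$auc
    }))
  })
  expect_gt(rep$perRunAuc, shuffled)
})

test_that("repeated five-fold CV is reproducible and fold masks partition", {
  inst <- simulateInstance(nc = 25, nd = 10, seed = 4, density = 0.08)
  r1 <- kfoldCv(inst$assoc, inst$CC, inst$DD, repeats = 2, seed = 99)
  r2 <- kfoldCv(inst$assoc, inst$CC, inst$DD, repeats = 2, seed = 99)
  expect_identical(r1$perRunAuc, r2$perRunAuc)
  expect_length(r1$perRunAuc, 2L)
  expect_equal(r1$meanAuc, mean(r1$perRunAuc))
  expect_equal(r1$stdAuc, stats::sd(r1$perRunAuc))

  single <- kfoldCv(inst$assoc, inst$CC, inst$DD, repeats = 1, seed = 1)
  expect_length(single$perRunAuc, 1L)
  expect_true(is.na(single$stdAuc))

  folds <- withr::with_seed(123, dmccda:::.foldAssign(23, 5))
  expect_setequal(unlist(folds), 1:23)
  expect_equal(sum(lengths(folds)), 23L)
  expect_true(all(lengths(folds) %in% 4:5))
})

test_that("CV AUC spread is small on a planted instance", {
  inst <- simulateInstance(nc = 30, nd = 12, rank = 2, density = 0.06,
                           seed = 11)
  r <- kfoldCv(inst$assoc, inst$CC, inst$DD, repeats = 10, seed = 2)
  expect_lt(r$stdAuc, 0.1)
})

test_that("new-node protocol recovers known partners of a zeroed column", {
  inst <- simulateInstance(nc = 30, nd = 10, seed = 6, density = 0.08)
  a <- assocMatrix(inst$assoc)
  d <- names(which.max(colSums(a)))
  full <- newNodeEval(inst$assoc, inst$CC, inst$DD, disease = d,
                      topK = nrow(a))
  expect_equal(full$hits, full$nKnown)  # exhaustive window finds them all

  top <- newNodeEval(inst$assoc, inst$CC, inst$DD, disease = d, topK = 10)
  expect_equal(top$nullMean, 10 * top$nKnown / nrow(a))
  expect_lte(top$hits, top$nKnown)

  empty <- names(which.min(colSums(a)))
  if (sum(a[, empty]) == 0)
    expect_error(newNodeEval(inst$assoc, inst$CC, inst$DD, disease = empty),
                 "no known association")
  expect_error(newNodeEval(inst$assoc, inst$CC, inst$DD, disease = "nope"),
               "unknown disease")
})
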