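.assoc <- function(m, cids = sprintf("c%d", seq_len(nrow(m))),
                   dids = sprintf("d%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(cids, dids)
  CircAssoc(m)
}

test_that("space update multiplies by similarity and normalizes by A norms", {
  a <- .assoc(matrix(c(1, 1, 0, 1), 2, 2))
  cc <- SimilarityMatrix(matrix(c(1, .5, .5, 1), 2, 2,
                                dimnames = list(c("c1", "c2"),
                                                c("c1", "c2"))), "CC")
  dd <- SimilarityMatrix(matrix(c(1, .5, .5, 1), 2, 2,
                                dimnames = list(c("d1", "d2"),
                                                c("d1", "d2"))), "DD")
  up <- spaceUpdate(a, cc, dd)
  # hand product: CC %*% A column 1 is (1.5, 1.5), column norm sqrt(2)
  expect_equal(unname(up$Ac[, "d1"]), c(1.5, 1.5) / sqrt(2))

  # identity similarity turns a one-hot column into itself
  eyeC <- toySimilarity(c("c1", "c2"), off = 0)
  oneHot <- .assoc(matrix(c(1, 0, 0, 1), 2, 2))
  upI <- spaceUpdate(oneHot, eyeC, dd)
  expect_equal(upI$Ac, assocMatrix(oneHot))

  # all-zero columns/rows of A stay exactly zero (new-node consistency)
  z <- .assoc(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  upZ <- spaceUpdate(z, toySimilarity(sprintf("c%d", 1:3), .4),
                     toySimilarity(sprintf("d%d", 1:3), .4))
  expect_identical(unname(upZ$Ac[, 3]), c(0, 0, 0))
  expect_identical(unname(upZ$Ad[3, ]), c(0, 0, 0))

  expect_error(spaceUpdate(a, dd, dd), "CC axis")
})

test_that("blocks splice kernel and scores and round-trip the extraction", {
  a <- matrix(seq_len(6) / 10, 3, 2,
              dimnames = list(c("c1", "c2", "c3"), c("d1", "d2")))
  kc <- toySimilarity(c("c1", "c2", "c3"), .2, "KC")
  b <- buildBlock(a, kc, "circ")
  expect_equal(dim(b@M), c(3L, 5L))
  expect_identical(b@scoreCols, 4:5)
  expect_equal(extractScores(b), a)

  kd <- toySimilarity(c("d1", "d2"), .2, "KD")
  b2 <- buildBlock(a, kd, "disease")
  expect_equal(dim(b2@M), c(2L, 5L))
  expect_equal(extractScores(b2), a)  # transpose round trip

  expect_error(buildBlock(a, kd, "circ"), "disagree")
})

test_that("singular-value shrinkage matches the eigen-route closed form", {
  expect_equal(svtShrink(diag(c(3, 1)), 2), diag(c(1, 0)))
  x <- matrix(c(2, -1, 0, 4), 2, 2)
  expect_identical(svtShrink(x, 0), x)
  expect_error(svtShrink(matrix(c(1, NA), 1, 2), 1), "non-finite")

  for (seed in 1:10) {
    withr::with_seed(seed, x <- matrix(rnorm(25), 5, 5))
    tau <- 0.3 * seed / 10
    expect_equal(svtShrink(x, tau), oracleSvtEigen(x, tau),
                 tolerance = 1e-10)
  }

  # symmetric input gives symmetric output
  withr::with_seed(9, s <- crossprod(matrix(rnorm(16), 4, 4)))
  out <- svtShrink(s, 0.5)
  expect_lt(max(abs(out - t(out))), 1e-10)
})

test_that("shrinkage output locally minimizes the proximal objective", {
  withr::with_seed(21, x <- matrix(rnorm(16), 4, 4))
  tau <- 0.4
  out <- svtShrink(x, tau)
  f0 <- nuclearNorm(out) + 1 / (2 * tau) * sum((out - x) ^ 2)
  withr::with_seed(22, {
    for (i in 1:200) {
      pert <- out + matrix(rnorm(16, sd = 1e-3), 4, 4)
      expect_gte(nuclearNorm(pert) + 1 / (2 * tau) * sum((pert - x) ^ 2),
                 f0 - 1e-12)
    }
  })
})

test_that("bounded completion honors the box and the fidelity limit", {
  withr::with_seed(5, {
    u <- runif(6)
    v <- runif(4)
  })
  rank1 <- outer(u, v)  # already within [0, 1]
  fit <- bnnrComplete(rank1, CompletionConfig(alphaAdmm = 1e6))
  expect_lt(max(abs(fit$W - rank1)), 1e-3)

  withr::with_seed(6, b <- matrix(runif(80), 8, 10))
  f <- bnnrComplete(b)
  expect_true(all(f$W >= -1e-12 & f$W <= 1 + 1e-12))
  expect_true(f$converged)
  expect_lt(f$primalResidual, 1e-6)

  # bit-identical reruns: the solver is deterministic
  f2 <- bnnrComplete(b)
  expect_identical(f$W, f2$W)
  expect_identical(f$iterations, f2$iterations)

  expect_error(bnnrComplete(matrix(c(1, Inf), 1, 2)), "non-finite")
})

test_that("primal residual falls below tol before maxIter on random blocks", {
  for (seed in 1:5) {
    withr::with_seed(seed, b <- matrix(runif(140), 10, 14))
    f <- bnnrComplete(b)
    expect_true(f$converged)
    expect_lt(f$iterations, 300L)
    expect_lt(f$primalResidual, 1e-6)  # ||M1 - W||_F relative to ||M1||_F
  }
})

test_that("score integration is the convex blend of the two spaces", {
  dn <- list(c("c1", "c2"), c("d1", "d2"))
  ac <- matrix(1, 2, 2, dimnames = dn)
  ad <- matrix(0, 2, 2, dimnames = dn)
  expect_identical(integrateScores(ac, ad, 1), ac)
  expect_identical(integrateScores(ac, ad, 0), ad)
  expect_equal(unname(integrateScores(ac, ad, 0.7)[1, 1]), 0.7)
  expect_error(integrateScores(ac, matrix(0, 3, 2)), "share shape")
})
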