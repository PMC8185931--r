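# Independent oracles used to certify the numerical core. Each one takes
# a route different from the implementation it checks: the edit-distance
# oracle evaluates the textbook recurrence directly, the SVT oracle
# obtains singular triplets from an eigendecomposition of the Gram
# matrix, the convex-solver oracle is a Davis-Yin splitting of the
# bounded completion problem, and the AUC oracle counts concordant
# positive/negative pairs.

# Textbook edit-distance recurrence d[i,j] = min(d[i-1,j]+1, d[i,j-1]+1,
# d[i-1,j-1]+cost), evaluated for every ordered pair of A x B at once
# (pairs grouped by length so each DP cell is one vectorized operation).
oracleEditCross <- function(A, B) {
  la <- nchar(A)
  lb <- nchar(B)
  out <- matrix(NA_real_, length(A), length(B))
  for (m in sort(unique(la))) for (n in sort(unique(lb))) {
    ia <- which(la == m)
    ib <- which(lb == n)
    ca <- if (m) matrix(unlist(strsplit(A[ia], "")), length(ia), m,
                        byrow = TRUE)
    cb <- if (n) matrix(unlist(strsplit(B[ib], "")), length(ib), n,
                        byrow = TRUE)
    npair <- length(ia) * length(ib)
    rowPrev <- lapply(0:n, function(j) rep(j, npair))
    for (i in seq_len(m)) {
      rowCur <- vector("list", n + 1L)
      rowCur[[1L]] <- rep(i, npair)
      for (j in seq_len(n)) {
        cost <- as.numeric(outer(ca[, i], cb[, j], `!=`))
        rowCur[[j + 1L]] <- pmin(rowPrev[[j + 1L]] + 1, rowCur[[j]] + 1,
                                 rowPrev[[j]] + cost)
      }
      rowPrev <- rowCur
    }
    out[ia, ib] <- matrix(rowPrev[[n + 1L]], length(ia), length(ib))
  }
  out
}

# All strings over {A,C,G,T} of length 0..maxLen.
allDnaStrings <- function(maxLen) {
  bases <- c("A", "C", "G", "T")
  out <- ""
  level <- ""
  for (l in seq_len(maxLen)) {
    level <- as.vector(outer(level, bases, paste0))
    out <- c(out, level)
  }
  out
}

# Singular-value soft-threshold computed from an eigendecomposition of
# t(X) X (never calls svd()).
oracleSvtEigen <- function(X, tau) {
  e <- eigen(crossprod(X), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  keep <- d > 1e-12
  v <- e$vectors[, keep, drop = FALSE]
  d <- d[keep]
  shrunk <- pmax(d - tau, 0)
  X %*% v %*% ((shrunk / d) * t(v))
}

nuclearNorm <- function(X) sum(svd(X)$d)

# Objective of the bounded completion problem (fidelity weight alpha).
bnnrObjective <- function(X, M0, alpha) {
  nuclearNorm(X) + alpha / 2 * sum((X - M0) ^ 2)
}

# Davis-Yin three-operator splitting for
#   min ||X||_* + (alpha/2)||X - M0||_F^2  s.t.  0 <= X <= 1
# (box prox, nuclear-norm prox, smooth fidelity gradient).
dySolve <- function(M0, alpha = 1, gamma = 1 / alpha, maxIter = 20000L,
                    tol = 1e-13) {
  z <- M0
  xg <- M0
  for (k in seq_len(maxIter)) {
    s <- svd(z)
    d <- pmax(s$d - gamma, 0)
    xgNew <- s$u %*% (d * t(s$v))
    xf <- pmin(pmax(2 * xgNew - z - gamma * alpha * (xgNew - M0), 0), 1)
    z <- z + xf - xgNew
    if (k > 1L && sqrt(sum((xgNew - xg) ^ 2)) < tol) {
      xg <- xgNew
      break
    }
    xg <- xgNew
  }
  pmin(pmax(xg, 0), 1)
}

# Mann-Whitney pairwise concordance AUC (ties count one half).
oracleAucConcordance <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, `>`) + 0.5 * outer(sp, sn, `==`)
  mean(cmp)
}

# Small deterministic fixture builders -----------------------------------

toySimilarity <- function(ids, off = 0.1, kind = "custom") {
  m <- matrix(off, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  SimilarityMatrix(m, kind)
}

writeTempLines <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext,
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
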