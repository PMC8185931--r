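# Numerical core: similarity-driven association updates, block splicing,
# and the bounded-nuclear-norm matrix completion solved by ADMM with
# singular-value thresholding.

.frob <- function(x) sqrt(sum(x * x))

#' Similarity-driven association updates (circRNA and disease space)
#'
#' Updates the binary association matrix from each side by similarity
#' multiplication, `Ac = CC %*% A` and `Ad = A %*% DD`, then controls the
#' value range by network-consistency normalization: each column j of Ac
#' is divided by the Euclidean norm of A's column j and each row i of Ad
#' by the Euclidean norm of A's row i (all-zero columns/rows stay zero).
#' This propagates known associations to similar circRNAs/diseases, which
#' is what lets a disease with no known partner inherit signal from its
#' semantic neighbours.
#'
#' @param assoc a [CircAssoc-class] object.
#' @param CC circRNA [SimilarityMatrix-class] on the circRNA axis.
#' @param DD disease [SimilarityMatrix-class] on the disease axis.
#' @return list with elements `Ac` and `Ad`, both nc x nd matrices.
#' @export
spaceUpdate <- function(assoc, CC, DD) {
  stopifnot(is(assoc, "CircAssoc"), is(CC, "SimilarityMatrix"),
            is(DD, "SimilarityMatrix"))
  a <- assocMatrix(assoc)
  cc <- simMatrix(CC)
  dd <- simMatrix(DD)
  if (!identical(rownames(cc), rownames(a)))
    stop("CC axis does not match the circRNA axis of the associations")
  if (!identical(rownames(dd), colnames(a)))
    stop("DD axis does not match the disease axis of the associations")
  colNorm <- sqrt(colSums(a ^ 2))
  rowNorm <- sqrt(rowSums(a ^ 2))
  ac <- cc %*% a
  ac <- sweep(ac, 2L, ifelse(colNorm > 0, colNorm, 1), `/`)
  ac[, colNorm == 0] <- 0
  ad <- a %*% dd
  ad <- sweep(ad, 1L, ifelse(rowNorm > 0, rowNorm, 1), `/`)
  ad[rowNorm == 0, ] <- 0
  dimnames(ac) <- dimnames(a)
  dimnames(ad) <- dimnames(a)
  list(Ac = ac, Ad = ad)
}

#' Splice an updated association matrix with its GIP kernel
#'
#' Forms the block handed to the completion solver. In circRNA space the
#' block is `[KC | Ac]` (nc x (nc + nd)); in disease space `[KD | Ad^T]`
#' (nd x (nd + nc)). The association sub-block occupies the trailing
#' columns and [extractScores()] recovers it (transposing back in disease
#' space).
#'
#' @param scores updated association matrix (nc x nd), e.g. `Ac` or `Ad`
#'   from [spaceUpdate()].
#' @param K the matching [SimilarityMatrix-class] kernel (KC or KD).
#' @param space "circ" or "disease".
#' @return A [BlockMatrix-class] object.
#' @export
buildBlock <- function(scores, K, space = c("circ", "disease")) {
  space <- match.arg(space)
  stopifnot(is(K, "SimilarityMatrix"))
  k <- simMatrix(K)
  sub <- if (space == "circ") scores else t(scores)
  if (nrow(k) != nrow(sub))
    stop("kernel and association sub-block row counts disagree (",
         nrow(k), " vs ", nrow(sub), ")")
  m <- cbind(k, sub)
  new("BlockMatrix", M = m,
      scoreCols = as.integer(ncol(k) + seq_len(ncol(sub))), space = space)
}

#' Extract the association sub-block from a (completed) block
#'
#' @param block the [BlockMatrix-class] that defined the splice.
#' @param M optional completed matrix of the block's shape; defaults to
#'   the block's own matrix.
#' @return An nc x nd matrix (transposed back for the disease space).
#' @export
extractScores <- function(block, M = block@M) {
  stopifnot(is(block, "BlockMatrix"))
  if (!identical(dim(M), dim(block@M)))
    stop("completed matrix shape does not match the block")
  sub <- M[, block@scoreCols, drop = FALSE]
  if (block@space == "disease") t(sub) else sub
}

#' Singular-value soft-thresholding
#'
#' Proximal operator of the nuclear norm: each singular value is shrunk
#' by `tau` and negative results set to zero, `U max(S - tau, 0) V^T`.
#'
#' @param X finite numeric matrix.
#' @param tau non-negative threshold.
#' @return Matrix of the same shape.
#' @examples
#' svtShrink(diag(c(3, 1)), 2)  # diag(1, 0)
#' @export
svtShrink <- function(X, tau) {
  if (!all(is.finite(X))) stop("non-finite entries in the matrix to shrink")
  stopifnot(length(tau) == 1L, is.finite(tau), tau >= 0)
  if (tau == 0) return(X)
  s <- svd(X)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(X), ncol(X), dimnames = dimnames(X)))
  out <- s$u[, keep, drop = FALSE] %*%
    (d[keep] * t(s$v[, keep, drop = FALSE]))
  dimnames(out) <- dimnames(X)
  out
}

#' Bounded-nuclear-norm completion of a block by ADMM
#'
#' Solves `min ||M1||_* + (alpha/2) ||M1 - M||_F^2  s.t.  0 <= M1 <= 1`
#' for the block matrix M (the projection in the objective is over the
#' universal index set, so every entry participates in the fidelity term).
#' The splitting introduces a box-constrained copy W with multiplier Y and
#' alternates: a clipped stationarity update of W, a singular-value
#' soft-thresholding update of M1 at threshold `1/beta`, and the
#' multiplier step `Y <- Y + beta (M1 - W)`. Iteration stops when both the
#' relative change of M1 and the relative primal residual
#' `||M1 - W||_F / ||M1||_F` fall below `tol`, or at `maxIter`. The
#' box-feasible W is returned as the recovered matrix.
#'
#' @param block a [BlockMatrix-class] (or plain finite matrix).
#' @param config a [CompletionConfig-class]; `alphaAdmm`, `betaAdmm`,
#'   `tol` and `maxIter` are used.
#' @return list with `W` (recovered matrix), `M1`, `Y`, `iterations`,
#'   `residual` (relative M1 change), `primalResidual` (relative
#'   `||M1 - W||_F`), `converged`, and `trace` (per-iteration residuals).
#' @export
bnnrComplete <- function(block, config = CompletionConfig()) {
  m0 <- if (is(block, "BlockMatrix")) block@M else block
  stopifnot(is.matrix(m0), is(config, "CompletionConfig"))
  if (!all(is.finite(m0))) stop("non-finite entries in the completion block")
  alpha <- config@alphaAdmm
  beta <- config@betaAdmm
  m1 <- m0
  w <- m0
  y <- matrix(0, nrow(m0), ncol(m0))
  trace <- matrix(NA_real_, config@maxIter, 2L,
                  dimnames = list(NULL, c("residual", "primalResidual")))
  converged <- FALSE
  res <- prim <- Inf
  for (k in seq_len(config@maxIter)) {
    w <- (alpha * m0 + y + beta * m1) / (alpha + beta)
    w[w < 0] <- 0
    w[w > 1] <- 1
    m1new <- svtShrink(w - y / beta, 1 / beta)
    y <- y + beta * (m1new - w)
    denom <- max(.frob(m1new), .Machine$double.eps)
    res <- .frob(m1new - m1) / denom
    prim <- .frob(m1new - w) / denom
    m1 <- m1new
    trace[k, ] <- c(res, prim)
    if (!is.finite(res) || !is.finite(prim))
      stop("ADMM diverged at iteration ", k, "; residual trace: ",
           paste(sprintf("%.3g", utils::head(stats::na.omit(trace[, 1L]), 10L)),
                 collapse = ", "))
    if (res < config@tol && prim < config@tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(w) <- dimnames(m0)
  list(W = w, M1 = m1, Y = y, iterations = k, residual = res,
       primalResidual = prim, converged = converged,
       trace = trace[seq_len(k), , drop = FALSE])
}

#' Blend the two per-space score matrices
#'
#' `Ascore = alphaMix * AcStar + (1 - alphaMix) * AdStar`, the convex
#' combination of the circRNA-space and disease-space recoveries.
#'
#' @param acStar,adStar score matrices of identical shape and identifier
#'   ordering.
#' @param alphaMix weight of the circRNA space, in [0, 1].
#' @return The blended score matrix.
#' @export
integrateScores <- function(acStar, adStar, alphaMix = 0.7) {
  stopifnot(alphaMix >= 0, alphaMix <= 1)
  if (!identical(dim(acStar), dim(adStar)) ||
      !identical(dimnames(acStar), dimnames(adStar)))
    stop("per-space score matrices must share shape and identifiers")
  alphaMix * acStar + (1 - alphaMix) * adStar
}
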