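# ROC/AUC machinery and the three evaluation protocols: global leave-one-
# out cross-validation, repeated five-fold cross-validation, and the
# new-node column-zeroing protocol.

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a classification threshold (predict
#' positive at or above the threshold), computes the true and false
#' positive rates `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)` at
#' each, and integrates TPR over FPR by the trapezoidal rule. Tied scores
#' enter a single threshold step, so the AUC equals the Mann-Whitney
#' concordance probability with ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of the same length, both classes present.
#' @return list with `thresholds` (descending distinct scores), `tpr`,
#'   `fpr` (each starting at 0 and ending at 1) and `auc`.
#' @examples
#' rocAuc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("both a positive and a negative label are required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)  # index of the last tied score per step
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(thresholds = s[last], tpr = tpr, fpr = fpr, auc = auc)
}

.positivePairs <- function(assoc) {
  which(assocMatrix(assoc) == 1, arr.ind = TRUE)
}

.maskPairs <- function(assoc, pairs) {
  a <- assocMatrix(assoc)
  a[pairs] <- 0
  CircAssoc(a)
}

#' Global leave-one-out cross-validation
#'
#' Each known association in turn is removed from the matrix, the model is
#' retrained on the remainder (the Gaussian kernels are recomputed from
#' the masked matrix) and the held-out pair's score recorded. All held-out
#' scores (label 1) are pooled with the scores of every never-known pair
#' from the full-data model (label 0) into a single ROC/AUC.
#'
#' @param assoc a [CircAssoc-class] with at least two known associations.
#' @param CC,DD similarity matrices, see [dmccdaPredict()].
#' @param config a [CompletionConfig-class].
#' @return list (cross-validation report) with `perRunAuc` (length 1),
#'   `meanAuc`, `stdAuc` (`NA` for a single run), `nFolds`, `nRepeats`,
#'   `seed` (`NA`: the protocol is deterministic) and `roc`.
#' @export
loocv <- function(assoc, CC, DD, config = CompletionConfig()) {
  pos <- .positivePairs(assoc)
  if (nrow(pos) < 2L) stop("leave-one-out needs at least two known pairs")
  full <- dmccdaPredict(assoc, CC, DD, config)
  negScores <- scoreMatrix(full)[assocMatrix(assoc) == 0]
  posScores <- vapply(seq_len(nrow(pos)), function(i) {
    masked <- .maskPairs(assoc, pos[i, , drop = FALSE])
    scoreMatrix(dmccdaPredict(masked, CC, DD, config))[pos[i, 1L], pos[i, 2L]]
  }, 1)
  roc <- rocAuc(c(posScores, negScores),
                c(rep(1, length(posScores)), rep(0, length(negScores))))
  list(perRunAuc = roc$auc, meanAuc = roc$auc, stdAuc = NA_real_,
       nFolds = nrow(pos), nRepeats = 1L, seed = NA_integer_, roc = roc)
}

# Split row indices 1..n into k near-equal folds after a seeded shuffle.
.foldAssign <- function(n, k) {
  perm <- sample.int(n)
  split(perm, rep_len(seq_len(k), n))
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are shuffled (with a repeat-specific
#' substream of the master seed) and split into `k` folds; each fold is
#' masked out, the model retrained on the remainder, and the fold's pairs
#' scored by the retrained model. The k folds of one repeat are pooled
#' with the candidate (never-known) pair scores into a single AUC, giving
#' one AUC per repeat.
#'
#' @param assoc a [CircAssoc-class] with at least `k` known associations.
#' @param CC,DD similarity matrices, see [dmccdaPredict()].
#' @param config a [CompletionConfig-class].
#' @param k number of folds (default 5).
#' @param repeats number of repeated partitions (default 100).
#' @param seed master seed; each repeat draws its own substream so repeats
#'   are independently reproducible.
#' @param rescoreCandidates if `TRUE`, candidate pairs are rescored by
#'   each fold's retrained model and pooled per fold; by default they are
#'   scored once by the full-data model.
#' @return list (cross-validation report) with `perRunAuc` (length
#'   `repeats`), `meanAuc`, `stdAuc`, `nFolds`, `nRepeats`, `seed`,
#'   `rescoreCandidates`.
#' @export
kfoldCv <- function(assoc, CC, DD, config = CompletionConfig(), k = 5L,
                    repeats = 100L, seed = 1L, rescoreCandidates = FALSE) {
  pos <- .positivePairs(assoc)
  if (nrow(pos) < k) stop("need at least k known pairs for k-fold CV")
  negMask <- assocMatrix(assoc) == 0
  if (!rescoreCandidates) {
    full <- dmccdaPredict(assoc, CC, DD, config)
    negScores <- scoreMatrix(full)[negMask]
  }
  repSeeds <- withr::with_seed(seed,
                               sample.int(.Machine$integer.max - 1L, repeats))
  perRunAuc <- vapply(seq_len(repeats), function(r) {
    folds <- withr::with_seed(repSeeds[[r]], .foldAssign(nrow(pos), k))
    posScores <- numeric(0)
    negPool <- if (rescoreCandidates) numeric(0) else negScores
    for (f in folds) {
      masked <- .maskPairs(assoc, pos[f, , drop = FALSE])
      sc <- scoreMatrix(dmccdaPredict(masked, CC, DD, config))
      posScores <- c(posScores, sc[pos[f, , drop = FALSE]])
      if (rescoreCandidates) negPool <- c(negPool, sc[negMask])
    }
    rocAuc(c(posScores, negPool),
           c(rep(1, length(posScores)), rep(0, length(negPool))))$auc
  }, 1)
  list(perRunAuc = perRunAuc, meanAuc = mean(perRunAuc),
       stdAuc = if (repeats > 1L) stats::sd(perRunAuc) else NA_real_,
       nFolds = as.integer(k), nRepeats = as.integer(repeats),
       seed = as.integer(seed), rescoreCandidates = rescoreCandidates)
}

#' New-node evaluation for one disease
#'
#' Simulates a disease with no known circRNA partner: the disease's column
#' is zeroed, the model retrained (Gaussian kernels recomputed from the
#' zeroed matrix, so only sequence/semantic similarity can carry signal
#' into the column), the column ranked, and the number of originally known
#' partners inside the top k counted.
#'
#' @param assoc a [CircAssoc-class] object.
#' @param CC,DD similarity matrices, see [dmccdaPredict()].
#' @param config a [CompletionConfig-class].
#' @param disease a disease identifier with at least one known partner.
#' @param topK size of the ranking window (default 10).
#' @return list with `disease`, `topK`, `hits` (known partners recovered
#'   in the top k), `nKnown`, `nullMean` (hypergeometric expectation
#'   `topK * nKnown / nc` under random ranking), and `ranking` (the top-k
#'   `data.frame`).
#' @export
newNodeEval <- function(assoc, CC, DD, config = CompletionConfig(),
                        disease, topK = 10L) {
  stopifnot(is(assoc, "CircAssoc"))
  if (!disease %in% diseaseIds(assoc))
    stop("unknown disease identifier '", disease, "'")
  a <- assocMatrix(assoc)
  known <- a[, disease] == 1
  if (!any(known))
    stop("disease '", disease, "' has no known association to recover")
  a2 <- a
  a2[, disease] <- 0
  res <- dmccdaPredict(CircAssoc(a2), CC, DD, config)
  ranking <- rankCandidates(res, assoc, disease, k = topK)
  hits <- sum(ranking$known)
  list(disease = disease, topK = min(as.integer(topK), nrow(a)),
       hits = hits, nKnown = sum(known),
       nullMean = min(topK, nrow(a)) * sum(known) / nrow(a),
       ranking = ranking)
}
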