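# End-to-end orchestration: from an association matrix plus sequence and
# semantic similarities to the blended score matrix, with the two ablation
# modes exposed as configuration switches.

.checkAxes <- function(assoc, CC, DD) {
  if (!identical(rownames(simMatrix(CC)), circIds(assoc)))
    stop("CC axis does not match the circRNA axis of the associations")
  if (!identical(rownames(simMatrix(DD)), diseaseIds(assoc)))
    stop("DD axis does not match the disease axis of the associations")
}

#' Predict circRNA-disease association scores
#'
#' Runs the double-matrix-completion pipeline: (1) compute the Gaussian
#' interaction profile kernels KC and KD from the association matrix
#' actually supplied (so masked/cross-validation matrices get their own
#' kernels); (2) update the associations by similarity multiplication and
#' normalization ([spaceUpdate()]); (3) splice each updated matrix with
#' its kernel ([buildBlock()]); (4) recover each block by
#' bounded-nuclear-norm completion ([bnnrComplete()]); (5) extract the
#' association sub-blocks and blend them with weight `alphaMix`
#' ([integrateScores()]).
#'
#' Ablation modes: `"mult-only"` stops after step (2) and blends the
#' normalized Ac/Ad directly (no completion, no kernels); `"mc-only"`
#' skips step (2) and completes blocks spliced from the raw association
#' matrix.
#'
#' @param assoc a [CircAssoc-class] object.
#' @param CC circRNA sequence [SimilarityMatrix-class].
#' @param DD disease semantic [SimilarityMatrix-class].
#' @param config a [CompletionConfig-class].
#' @return A [DmccdaResult-class] object.
#' @examples
#' inst <- simulateInstance(nc = 20, nd = 8, seed = 1)
#' res <- dmccdaPredict(inst$assoc, inst$CC, inst$DD)
#' res
#' @export
dmccdaPredict <- function(assoc, CC, DD, config = CompletionConfig()) {
  stopifnot(is(assoc, "CircAssoc"), is(config, "CompletionConfig"))
  .checkAxes(assoc, CC, DD)
  a <- assocMatrix(assoc)
  stage <- "similarity update"
  out <- tryCatch({
    if (config@mode == "mult-only") {
      up <- spaceUpdate(assoc, CC, DD)
      list(acStar = up$Ac, adStar = up$Ad,
           diagnostics = list())
    } else {
      stage <- "GIP kernels"
      kc <- gipSimilarityMatrix(assoc, "circ")
      kd <- gipSimilarityMatrix(assoc, "disease")
      if (config@mode == "mc-only") {
        ac <- a
        ad <- a
      } else {
        stage <- "similarity update"
        up <- spaceUpdate(assoc, CC, DD)
        ac <- up$Ac
        ad <- up$Ad
      }
      stage <- "matrix completion (circRNA space)"
      bC <- buildBlock(ac, kc, "circ")
      fitC <- bnnrComplete(bC, config)
      stage <- "matrix completion (disease space)"
      bD <- buildBlock(ad, kd, "disease")
      fitD <- bnnrComplete(bD, config)
      list(acStar = extractScores(bC, fitC$W),
           adStar = extractScores(bD, fitD$W),
           diagnostics = list(
             circ = fitC[c("iterations", "residual", "primalResidual",
                           "converged")],
             disease = fitD[c("iterations", "residual", "primalResidual",
                              "converged")]))
    }
  }, error = function(e) {
    stop("dmccdaPredict failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  acStar <- out$acStar
  adStar <- out$adStar
  dimnames(acStar) <- dimnames(a)
  dimnames(adStar) <- dimnames(a)
  scores <- integrateScores(acStar, adStar, config@alphaMix)
  new("DmccdaResult", scores = scores, acStar = acStar, adStar = adStar,
      diagnostics = out$diagnostics, config = config)
}

#' Rank candidate circRNAs for one disease
#'
#' Orders the score column of a disease by descending score (ties broken
#' by circRNA identifier) and returns the top k with a flag for pairs
#' already known in the supplied association matrix.
#'
#' @param result a [DmccdaResult-class] object.
#' @param assoc the [CircAssoc-class] defining known pairs.
#' @param disease a disease identifier present on the disease axis.
#' @param k number of candidates to return (clamped to the number of
#'   circRNAs).
#' @return `data.frame` with columns `circRNA`, `score`, `known`.
#' @export
rankCandidates <- function(result, assoc, disease, k = 10L) {
  stopifnot(is(result, "DmccdaResult"), is(assoc, "CircAssoc"), k >= 1L)
  if (!disease %in% diseaseIds(result))
    stop("unknown disease identifier '", disease, "'")
  if (!identical(dimnames(scoreMatrix(result)), dimnames(assocMatrix(assoc))))
    stop("result and association identifiers disagree")
  s <- scoreMatrix(result)[, disease]
  ord <- order(-s, names(s), method = "radix")
  k <- min(as.integer(k), length(s))
  top <- ord[seq_len(k)]
  data.frame(circRNA = names(s)[top], score = unname(s[top]),
             known = as.integer(assocMatrix(assoc)[top, disease]),
             stringsAsFactors = FALSE)
}
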