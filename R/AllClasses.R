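#' @import methods
NULL

#' Binary circRNA-disease association matrix
#'
#' Container for the adjacency matrix A of the bipartite association
#' network: rows are circRNAs, columns are diseases, and an entry is 1
#' exactly when the pair has been experimentally verified. Row and column
#' names carry the circRNA and disease identifiers; both axes must be
#' uniquely named so the index/identifier mapping is a bijection.
#'
#' @slot assoc numeric matrix of 0/1 values with unique dimnames.
#'
#' @seealso [CircAssoc()], [readAssociations()], [circIds()], [diseaseIds()]
#' @export
setClass("CircAssoc", representation(assoc = "matrix"))

setValidity("CircAssoc", function(object) {
  a <- object@assoc
  msg <- character()
  if (!is.numeric(a))
    msg <- c(msg, "association matrix must be numeric")
  else if (!all(a %in% c(0, 1)))
    msg <- c(msg, "association matrix entries must be 0 or 1")
  dn <- dimnames(a)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
    msg <- c(msg, "both axes must carry identifiers (dimnames)")
  else {
    if (anyDuplicated(dn[[1L]])) msg <- c(msg, "duplicated circRNA identifiers")
    if (anyDuplicated(dn[[2L]])) msg <- c(msg, "duplicated disease identifiers")
    if (any(!nzchar(c(dn[[1L]], dn[[2L]])))) msg <- c(msg, "empty identifier")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CircAssoc object
#'
#' @param assoc 0/1 matrix with circRNA row names and disease column names.
#' @return A [CircAssoc-class] object.
#' @examples
#' a <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("d1", "d2")))
#' CircAssoc(a)
#' @export
CircAssoc <- function(assoc) {
  storage.mode(assoc) <- "double"
  new("CircAssoc", assoc = assoc)
}

#' Square similarity matrix keyed to one identifier axis
#'
#' Symmetric matrix with unit diagonal and entries in [0, 1], used for all
#' four similarity sources: circRNA sequence similarity (CC), disease
#' semantic similarity (DD), and the Gaussian interaction profile kernels
#' (KC for circRNAs, KD for diseases).
#'
#' @slot values symmetric numeric matrix, unit diagonal, entries in [0, 1],
#'   with identical row and column names.
#' @slot kind one of "CC", "DD", "KC", "KD" or "custom".
#'
#' @seealso [SimilarityMatrix()], [sequenceSimilarityMatrix()],
#'   [semanticSimilarityMatrix()], [gipSimilarityMatrix()]
#' @export
setClass("SimilarityMatrix",
         representation(values = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  tol <- 1e-8
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (!isTRUE(all(is.finite(v)))) msg <- c(msg, "entries must be finite")
  else {
    if (max(abs(v - t(v))) > tol) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(diag(v) - 1)) > tol) msg <- c(msg, "diagonal must be 1")
    if (min(v) < -tol || max(v) > 1 + tol)
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  dn <- dimnames(v)
  if (is.null(dn) || is.null(dn[[1L]]))
    msg <- c(msg, "axis identifiers (dimnames) required")
  else if (!identical(dn[[1L]], dn[[2L]]))
    msg <- c(msg, "row and column identifiers must agree")
  if (length(object@kind) != 1L)
    msg <- c(msg, "kind must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values symmetric numeric matrix in [0, 1] with unit diagonal and
#'   identical row/column names.
#' @param kind label for the similarity source ("CC", "DD", "KC", "KD", or
#'   "custom").
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, kind = "custom") {
  storage.mode(values) <- "double"
  new("SimilarityMatrix", values = values, kind = kind)
}

#' Disease ontology DAG
#'
#' Directed acyclic graph of disease terms under is_a relations, together
#' with the semantic decay factor used by Wang's semantic similarity: each
#' step from a term to a parent multiplies the semantic contribution by
#' `decay`.
#'
#' @slot terms character vector of term identifiers (e.g. DOIDs).
#' @slot parents named list mapping every term to the character vector of
#'   its direct is_a parents (empty for roots).
#' @slot decay semantic decay factor in (0, 1).
#'
#' @seealso [DiseaseOntology()], [readOntology()], [semanticContributions()]
#' @export
setClass("DiseaseOntology",
         representation(terms = "character", parents = "list",
                        decay = "numeric"))

setValidity("DiseaseOntology", function(object) {
  msg <- character()
  if (anyDuplicated(object@terms)) msg <- c(msg, "duplicated terms")
  if (!setequal(names(object@parents), object@terms))
    msg <- c(msg, "parents list must be named by exactly the terms")
  bad <- setdiff(unlist(object@parents, use.names = FALSE), object@terms)
  if (length(bad))
    msg <- c(msg, paste0("unknown parent term(s): ",
                         paste(utils::head(bad, 3L), collapse = ", ")))
  if (length(object@decay) != 1L || !is.finite(object@decay) ||
      object@decay <= 0 || object@decay >= 1)
    msg <- c(msg, "decay must be a single value in (0, 1)")
  if (!length(msg)) {
    cyc <- .findCycle(object@parents)
    if (!is.null(cyc))
      msg <- c(msg, paste0("is_a relation contains a cycle: ",
                           paste(cyc, collapse = " -> ")))
  }
  if (length(msg)) msg else TRUE
})

# Kahn peel: returns NULL if acyclic, else one cycle as a term sequence.
.findCycle <- function(parents) {
  deg <- vapply(parents, length, 1L)  # out-degree towards parents
  children <- new.env(parent = emptyenv())
  for (ch in names(parents)) for (p in parents[[ch]]) {
    children[[p]] <- c(children[[p]], ch)
  }
  queue <- names(deg)[deg == 0L]
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    for (ch in children[[t]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  left <- names(deg)[deg > 0L]
  if (!length(left)) return(NULL)
  # walk parent pointers inside the leftover set until a repeat closes a loop
  path <- left[[1L]]
  repeat {
    nxt <- intersect(parents[[path[length(path)]]], left)[[1L]]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
  }
}

#' Construct a DiseaseOntology
#'
#' @param parents named list mapping each term to the character vector of
#'   its direct is_a parents; parents not appearing as names are added as
#'   root terms.
#' @param decay semantic decay factor in (0, 1); 0.5 is the conventional
#'   value for Wang's method.
#' @return A [DiseaseOntology-class] object.
#' @examples
#' ont <- DiseaseOntology(list(d1 = "root", d2 = "root"))
#' ontologyTerms(ont)
#' @export
DiseaseOntology <- function(parents, decay = 0.5) {
  parents <- lapply(parents, as.character)
  roots <- setdiff(unlist(parents, use.names = FALSE), names(parents))
  for (r in roots) parents[[r]] <- character()
  new("DiseaseOntology", terms = names(parents), parents = parents,
      decay = decay)
}

#' DMCCDA model configuration
#'
#' Hyperparameters of the bounded-nuclear-norm ADMM solver and the final
#' score integration, plus the ablation mode switch.
#'
#' @slot alphaAdmm fidelity weight of the completion objective (> 0).
#' @slot betaAdmm ADMM penalty coefficient (> 0).
#' @slot tol relative convergence threshold of the ADMM loop.
#' @slot maxIter iteration cap of the ADMM loop.
#' @slot alphaMix weight of the circRNA-space score matrix in the final
#'   blend, in [0, 1]; the disease space receives 1 - alphaMix.
#' @slot mode "full" for the complete model, "mult-only" to skip matrix
#'   completion (similarity multiplication alone), "mc-only" to skip the
#'   similarity multiplication (completion of raw-association blocks).
#'
#' @seealso [CompletionConfig()], [dmccdaPredict()]
#' @export
setClass("CompletionConfig",
         representation(alphaAdmm = "numeric", betaAdmm = "numeric",
                        tol = "numeric", maxIter = "integer",
                        alphaMix = "numeric", mode = "character"))

setValidity("CompletionConfig", function(object) {
  msg <- character()
  chk1 <- function(x) length(x) == 1L && is.finite(x)
  if (!chk1(object@alphaAdmm) || object@alphaAdmm <= 0)
    msg <- c(msg, "alphaAdmm must be a single positive value")
  if (!chk1(object@betaAdmm) || object@betaAdmm <= 0)
    msg <- c(msg, "betaAdmm must be a single positive value")
  if (!chk1(object@tol) || object@tol <= 0)
    msg <- c(msg, "tol must be a single positive value")
  if (length(object@maxIter) != 1L || is.na(object@maxIter) ||
      object@maxIter < 1L)
    msg <- c(msg, "maxIter must be >= 1")
  if (!chk1(object@alphaMix) || object@alphaMix < 0 || object@alphaMix > 1)
    msg <- c(msg, "alphaMix must lie in [0, 1]")
  if (length(object@mode) != 1L ||
      !object@mode %in% c("full", "mult-only", "mc-only"))
    msg <- c(msg, "mode must be one of 'full', 'mult-only', 'mc-only'")
  if (length(msg)) msg else TRUE
})

#' Construct a CompletionConfig
#'
#' @param alphaAdmm fidelity weight of the completion objective; default 1.
#' @param betaAdmm ADMM penalty coefficient; default 10.
#' @param tol relative convergence threshold; default 1e-6.
#' @param maxIter ADMM iteration cap; default 300.
#' @param alphaMix circRNA-space weight of the final score blend; default
#'   0.7 (the disease space gets 0.3).
#' @param mode "full", "mult-only" or "mc-only" (ablations).
#' @return A [CompletionConfig-class] object.
#' @export
CompletionConfig <- function(alphaAdmm = 1, betaAdmm = 10, tol = 1e-6,
                             maxIter = 300L, alphaMix = 0.7, mode = "full") {
  new("CompletionConfig", alphaAdmm = as.numeric(alphaAdmm),
      betaAdmm = as.numeric(betaAdmm), tol = as.numeric(tol),
      maxIter = as.integer(maxIter), alphaMix = as.numeric(alphaMix),
      mode = mode)
}

#' Spliced matrix block for one completion space
#'
#' Horizontal splice of a Gaussian interaction profile kernel with the
#' similarity-updated association matrix; the completion solver operates on
#' the whole block and the association scores are read back out of the
#' `scoreCols` columns.
#'
#' @slot M numeric block matrix.
#' @slot scoreCols integer column indices holding the association sub-block.
#' @slot space "circ" (rows are circRNAs) or "disease" (rows are diseases;
#'   the association sub-block is stored transposed).
#'
#' @seealso [buildBlock()], [extractScores()], [bnnrComplete()]
#' @export
setClass("BlockMatrix",
         representation(M = "matrix", scoreCols = "integer",
                        space = "character"))

setValidity("BlockMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@M))) msg <- c(msg, "block entries must be finite")
  if (!length(object@scoreCols) ||
      any(object@scoreCols < 1L | object@scoreCols > ncol(object@M)))
    msg <- c(msg, "scoreCols out of range")
  if (length(object@space) != 1L || !object@space %in% c("circ", "disease"))
    msg <- c(msg, "space must be 'circ' or 'disease'")
  if (length(msg)) msg else TRUE
})

#' Result of a DMCCDA prediction run
#'
#' Holds the blended score matrix together with the per-space recovered
#' score matrices and solver diagnostics.
#'
#' @slot scores blended score matrix Ascore (circRNAs x diseases).
#' @slot acStar circRNA-space recovered score matrix.
#' @slot adStar disease-space recovered score matrix.
#' @slot diagnostics list of per-space ADMM iteration counts and residuals.
#' @slot config the [CompletionConfig-class] used.
#'
#' @seealso [dmccdaPredict()], [rankCandidates()], [scoreMatrix()]
#' @export
setClass("DmccdaResult",
         representation(scores = "matrix", acStar = "matrix",
                        adStar = "matrix", diagnostics = "list",
                        config = "CompletionConfig"))

setValidity("DmccdaResult", function(object) {
  msg <- character()
  if (!all(is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (!identical(dim(object@scores), dim(object@acStar)) ||
      !identical(dim(object@scores), dim(object@adStar)))
    msg <- c(msg, "scores, acStar and adStar must share a shape")
  am <- object@config@alphaMix
  blend <- am * object@acStar + (1 - am) * object@adStar
  if (max(abs(blend - object@scores)) > 1e-10)
    msg <- c(msg, "scores must equal the alphaMix blend of acStar and adStar")
  if (length(msg)) msg else TRUE
})
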