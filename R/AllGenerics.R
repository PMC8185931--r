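#' Accessors for identifier axes and matrices
#'
#' `circIds()` and `diseaseIds()` return the ordered identifier vectors of
#' the circRNA and disease axes; `assocMatrix()` the underlying 0/1 matrix;
#' `simMatrix()` the numeric similarity matrix; `scoreMatrix()` the blended
#' prediction matrix of a result; `ontologyTerms()` and `termParents()` the
#' term set and direct-parent map of an ontology.
#'
#' @param x a package object ([CircAssoc-class], [SimilarityMatrix-class],
#'   [DiseaseOntology-class] or [DmccdaResult-class]).
#' @return A character vector, matrix or list as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("circIds", function(x) standardGeneric("circIds"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' @rdname accessors
#' @export
setGeneric("simMatrix", function(x) standardGeneric("simMatrix"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname accessors
#' @export
setGeneric("termParents", function(x) standardGeneric("termParents"))

#' @rdname accessors
setMethod("circIds", "CircAssoc", function(x) rownames(x@assoc))

#' @rdname accessors
setMethod("diseaseIds", "CircAssoc", function(x) colnames(x@assoc))

#' @rdname accessors
setMethod("assocMatrix", "CircAssoc", function(x) x@assoc)

#' @rdname accessors
setMethod("simMatrix", "SimilarityMatrix", function(x) x@values)

#' @rdname accessors
setMethod("circIds", "DmccdaResult", function(x) rownames(x@scores))

#' @rdname accessors
setMethod("diseaseIds", "DmccdaResult", function(x) colnames(x@scores))

#' @rdname accessors
setMethod("scoreMatrix", "DmccdaResult", function(x) x@scores)

#' @rdname accessors
setMethod("ontologyTerms", "DiseaseOntology", function(x) x@terms)

#' @rdname accessors
setMethod("termParents", "DiseaseOntology", function(x) x@parents)

setMethod("show", "CircAssoc", function(object) {
  a <- object@assoc
  cat(sprintf("CircAssoc: %d circRNAs x %d diseases, %d known associations (%.2f%% dense)\n",
              nrow(a), ncol(a), sum(a), 100 * mean(a)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d x %d, range [%.4f, %.4f]\n",
              object@kind, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "DiseaseOntology", function(object) {
  nroot <- sum(vapply(object@parents, length, 1L) == 0L)
  cat(sprintf("DiseaseOntology: %d terms, %d root(s), decay = %g\n",
              length(object@terms), nroot, object@decay))
})

setMethod("show", "CompletionConfig", function(object) {
  cat(sprintf(paste0("CompletionConfig: mode=%s alphaAdmm=%g betaAdmm=%g ",
                     "tol=%g maxIter=%d alphaMix=%g\n"),
              object@mode, object@alphaAdmm, object@betaAdmm, object@tol,
              object@maxIter, object@alphaMix))
})

setMethod("show", "DmccdaResult", function(object) {
  d <- object@diagnostics
  cat(sprintf("DmccdaResult: %d circRNAs x %d diseases (mode %s)\n",
              nrow(object@scores), ncol(object@scores), object@config@mode))
  for (sp in names(d)) {
    cat(sprintf("  %s space: %d iterations, residual %.3g\n",
                sp, d[[sp]]$iterations, d[[sp]]$residual))
  }
})

setMethod("show", "BlockMatrix", function(object) {
  cat(sprintf("BlockMatrix (%s space): %d x %d, score columns %d..%d\n",
              object@space, nrow(object@M), ncol(object@M),
              min(object@scoreCols), max(object@scoreCols)))
})
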