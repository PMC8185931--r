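# The four similarity sources feeding the model: Levenshtein-based circRNA
# sequence similarity (CC), Wang-style ontology semantic similarity (DD),
# and Gaussian interaction profile kernels over association profiles
# (KC for circRNAs, KD for diseases).

#' Levenshtein edit distance between nucleotide strings
#'
#' Unit-cost edit distance (insertions, deletions, substitutions), the
#' minimum number of single-character operations turning one sequence into
#' the other.
#'
#' @param a,b character vectors of sequences (recycled pairwise).
#' @return Integer vector of distances.
#' @examples
#' levenshteinDistance("ACGT", "AGCT")  # 2 substitutions
#' @export
levenshteinDistance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  ua <- unique(a)
  ub <- unique(b)
  d <- utils::adist(ua, ub, ignore.case = FALSE)
  as.integer(d[cbind(match(a, ua), match(b, ub))])
}

#' circRNA sequence similarity matrix (CC)
#'
#' For sequences i and j, similarity is
#' `1 - dis(i, j) / (len(i) + len(j))` with `dis` the Levenshtein
#' distance, so identical sequences score 1 and similarity never drops
#' below 0 (the distance cannot exceed the longer length).
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector
#'   of normalized sequences.
#' @param ids optional circRNA identifier ordering for the matrix axes;
#'   defaults to the (lexicographically sorted) sequence names. Every id
#'   must have a sequence.
#' @return A [SimilarityMatrix-class] of kind "CC".
#' @export
sequenceSimilarityMatrix <- function(seqs, ids = NULL) {
  s <- as.character(seqs)
  if (is.null(names(s))) names(s) <- names(seqs)
  if (is.null(names(s)) || anyDuplicated(names(s)))
    stop("sequences must carry unique names")
  if (is.null(ids)) ids <- .sortIds(names(s))
  missing <- setdiff(ids, names(s))
  if (length(missing))
    stop("no sequence for circRNA identifier(s): ",
         paste(missing, collapse = ", "))
  s <- s[ids]
  if (any(!nzchar(s))) stop("empty sequence(s) supplied")
  d <- utils::adist(s, s)
  len <- nchar(s)
  cc <- 1 - d / outer(len, len, `+`)
  diag(cc) <- 1
  cc <- (cc + t(cc)) / 2
  dimnames(cc) <- list(ids, ids)
  SimilarityMatrix(cc, kind = "CC")
}

# Ancestor closure of `term` with the minimal hop count to each ancestor.
# Under the max-recursion of Wang's contribution with a constant decay,
# the contribution of ancestor t is decay^(shortest is_a path length).
.ancestorHops <- function(ont, term) {
  hops <- stats::setNames(0L, term)
  frontier <- term
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    nxt <- setdiff(unique(unlist(ont@parents[frontier], use.names = FALSE)),
                   names(hops))
    if (length(nxt)) hops[nxt] <- lvl
    frontier <- nxt
  }
  hops
}

#' Semantic contributions of a disease's ancestors
#'
#' Wang-style semantic contribution: the disease itself contributes 1 and
#' each term t in its ancestor closure contributes
#' `max(decay * S(child))` over t's children on paths to the disease —
#' i.e. `decay` raised to the shortest is_a hop count from the disease
#' up to t.
#'
#' @param ont a [DiseaseOntology-class] object.
#' @param term a term present in the ontology.
#' @return Named numeric vector over the ancestor closure (term included),
#'   values in (0, 1] with the term itself at 1.
#' @export
semanticContributions <- function(ont, term) {
  stopifnot(is(ont, "DiseaseOntology"))
  if (!term %in% ontologyTerms(ont))
    stop("term '", term, "' not in the ontology")
  hops <- .ancestorHops(ont, term)
  stats::setNames(ont@decay ^ as.numeric(hops), names(hops))
}

#' Disease semantic similarity matrix (DD)
#'
#' Wang's method: the similarity of two diseases is the summed semantic
#' contribution of their shared ancestors relative to the total
#' contribution of each disease's own ancestor closure,
#' `sum_{t in Ti ∩ Tj} (Si(t) + Sj(t)) / (sum Si + sum Sj)`.
#'
#' @param ont a [DiseaseOntology-class] object.
#' @param ids disease identifiers (ontology terms) forming the matrix axes.
#' @return A [SimilarityMatrix-class] of kind "DD".
#' @export
semanticSimilarityMatrix <- function(ont, ids) {
  stopifnot(is(ont, "DiseaseOntology"))
  missing <- setdiff(ids, ontologyTerms(ont))
  if (length(missing))
    stop("term(s) absent from the ontology: ", paste(missing, collapse = ", "))
  contrib <- lapply(ids, function(d) semanticContributions(ont, d))
  total <- vapply(contrib, sum, 1)
  n <- length(ids)
  dd <- diag(1, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
    num <- sum(contrib[[i]][shared]) + sum(contrib[[j]][shared])
    dd[i, j] <- dd[j, i] <- num / (total[[i]] + total[[j]])
  }
  dimnames(dd) <- list(ids, ids)
  SimilarityMatrix(dd, kind = "DD")
}

#' Gaussian interaction profile kernel bandwidth
#'
#' The kernel bandwidth is the original bandwidth divided by the mean
#' squared Euclidean norm of the interaction profiles on that axis
#' (rows of the association matrix for circRNAs, columns for diseases).
#'
#' @param assoc a [CircAssoc-class] object.
#' @param axis "circ" or "disease".
#' @param betaPrime original bandwidth, > 0; 1 by convention.
#' @return The positive bandwidth.
#' @export
gipBandwidth <- function(assoc, axis = c("circ", "disease"), betaPrime = 1) {
  stopifnot(is(assoc, "CircAssoc"), betaPrime > 0)
  axis <- match.arg(axis)
  a <- assocMatrix(assoc)
  sq <- if (axis == "circ") rowSums(a ^ 2) else colSums(a ^ 2)
  meanSq <- mean(sq)
  if (meanSq == 0)
    stop("all-zero association matrix: GIP bandwidth undefined")
  betaPrime / meanSq
}

#' Gaussian interaction profile kernel similarity (KC / KD)
#'
#' `exp(-beta * ||IP(i) - IP(j)||^2)` over binary interaction profiles,
#' with the bandwidth from [gipBandwidth()]. Nodes with empty profiles
#' (new nodes) are allowed; only a fully zero association matrix is an
#' error.
#'
#' @inheritParams gipBandwidth
#' @return A [SimilarityMatrix-class] of kind "KC" (circ axis) or "KD"
#'   (disease axis).
#' @export
gipSimilarityMatrix <- function(assoc, axis = c("circ", "disease"),
                                betaPrime = 1) {
  axis <- match.arg(axis)
  beta <- gipBandwidth(assoc, axis, betaPrime)
  a <- assocMatrix(assoc)
  p <- if (axis == "circ") a else t(a)
  sq <- rowSums(p ^ 2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0  # numerical guard
  k <- exp(-beta * d2)
  diag(k) <- 1
  k <- (k + t(k)) / 2
  ids <- if (axis == "circ") rownames(a) else colnames(a)
  dimnames(k) <- list(ids, ids)
  SimilarityMatrix(k, kind = if (axis == "circ") "KC" else "KD")
}
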