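# Seeded generator of desk-scale instances carrying the structure the
# model assumes: a sparse binary bipartite association matrix driven by a
# planted non-negative low-rank process, similarity matrices correlated
# with the same latent factors, cluster-structured sequences and a random
# disease ontology.

.clip01 <- function(x) pmin(pmax(x, 0), 1)

.cosineRows <- function(m) {
  n <- sqrt(rowSums(m ^ 2))
  n[n == 0] <- 1
  s <- tcrossprod(m / n)
  diag(s) <- 1
  s
}

#' Simulate a synthetic association instance
#'
#' Draws non-negative latent factors U (nc x rank) and V (nd x rank),
#' forms the ground-truth affinity `U V^T` rescaled to [0, 1], and marks
#' the top `density` fraction of pairs as known associations (exact
#' count, deterministic tie-break). The circRNA and disease similarity
#' matrices are cosine similarities of the U and V rows, perturbed by
#' symmetric Gaussian jitter of scale `noise`, clipped to [0, 1] with the
#' unit diagonal restored — so the guilt-by-association signal the model
#' exploits exists by construction, at a controlled strength.
#'
#' @param nc,nd numbers of circRNAs and diseases.
#' @param rank latent dimension (<= min(nc, nd)).
#' @param density fraction of pairs marked as known, in (0, 1); must
#'   yield at least 2 positives.
#' @param noise standard deviation of the similarity jitter.
#' @param seed integer seed; the instance is a pure function of the
#'   arguments.
#' @return list with `assoc` ([CircAssoc-class]), `CC`, `DD`
#'   ([SimilarityMatrix-class]), `truth` (the rescaled affinity matrix),
#'   and `clusters` (per-axis latent cluster assignments, the argmax
#'   factor of each row).
#' @examples
#' inst <- simulateInstance(nc = 30, nd = 10, seed = 1)
#' inst$assoc
#' @export
simulateInstance <- function(nc = 60L, nd = 20L, rank = 3L, density = 0.05,
                             noise = 0.05, seed = 1L) {
  stopifnot(rank >= 1L, rank <= min(nc, nd), density > 0, density < 1,
            noise >= 0)
  nPos <- round(density * nc * nd)
  if (nPos < 2L)
    stop("density ", density, " yields fewer than 2 positives on ",
         nc, " x ", nd)
  withr::with_seed(as.integer(seed), {
    u <- matrix(abs(stats::rnorm(nc * rank)), nc, rank)
    v <- matrix(abs(stats::rnorm(nd * rank)), nd, rank)
    jc <- matrix(stats::rnorm(nc * nc, sd = noise), nc, nc)
    jd <- matrix(stats::rnorm(nd * nd, sd = noise), nd, nd)
  })
  cids <- sprintf("circ%03d", seq_len(nc))
  dids <- sprintf("disease%03d", seq_len(nd))
  truth <- u %*% t(v)
  truth <- (truth - min(truth)) / (max(truth) - min(truth))
  dimnames(truth) <- list(cids, dids)
  a <- matrix(0, nc, nd, dimnames = list(cids, dids))
  a[order(-truth, seq_along(truth))[seq_len(nPos)]] <- 1
  cc <- .clip01(.cosineRows(u) + (jc + t(jc)) / 2)
  dd <- .clip01(.cosineRows(v) + (jd + t(jd)) / 2)
  diag(cc) <- 1
  diag(dd) <- 1
  dimnames(cc) <- list(cids, cids)
  dimnames(dd) <- list(dids, dids)
  list(assoc = CircAssoc(a),
       CC = SimilarityMatrix(cc, "CC"),
       DD = SimilarityMatrix(dd, "DD"),
       truth = truth,
       clusters = list(circ = stats::setNames(max.col(u), cids),
                       disease = stats::setNames(max.col(v), dids)))
}

#' Generate cluster-structured circRNA sequences
#'
#' One random prototype sequence per latent circRNA cluster; each cluster
#' member is the prototype with independent per-base substitutions at
#' `mutRate` (always to a different base), so within-cluster sequence
#' similarity exceeds between-cluster similarity for small mutation
#' rates.
#'
#' @param clusters named integer vector of circRNA cluster assignments,
#'   e.g. `simulateInstance(...)$clusters$circ`.
#' @param seqLen prototype sequence length.
#' @param mutRate per-base substitution probability in [0, 1].
#' @param seed integer seed.
#' @return A named [Biostrings::DNAStringSet], one record per circRNA.
#' @export
mutateSequences <- function(clusters, seqLen = 200L, mutRate = 0.05,
                            seed = 1L) {
  stopifnot(seqLen >= 1L, mutRate >= 0, mutRate <= 1, length(clusters) >= 1L,
            !is.null(names(clusters)))
  bases <- c("A", "C", "G", "T")
  seqs <- withr::with_seed(as.integer(seed), {
    protos <- lapply(sort(unique(clusters)), function(cl)
      sample(bases, seqLen, replace = TRUE))
    names(protos) <- as.character(sort(unique(clusters)))
    vapply(seq_along(clusters), function(i) {
      s <- protos[[as.character(clusters[[i]])]]
      hit <- stats::runif(seqLen) < mutRate
      if (any(hit))
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(bases, b), 1L), "")
      paste(s, collapse = "")
    }, "")
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(clusters)
  out
}

#' Generate a random rooted disease ontology
#'
#' Builds a complete rooted tree of the given depth and branching factor
#' and assigns its leaves to the disease axis, grouped by latent cluster
#' when cluster assignments are supplied (diseases of one cluster occupy
#' consecutive leaves, hence share low ancestors), so semantically close
#' diseases are also close in the planted association process.
#'
#' @param nd number of diseases to place on leaves.
#' @param depth tree depth (>= 1); the tree has `branching^depth` leaves,
#'   which must be at least `nd`.
#' @param branching children per internal node.
#' @param seed integer seed (used only to shuffle cluster blocks).
#' @param decay semantic decay factor, see [DiseaseOntology()].
#' @param clusters optional named integer vector of disease cluster
#'   assignments; names become the disease identifiers.
#' @return list with `ontology` ([DiseaseOntology-class]) and `mapping`
#'   (named character: disease identifier -> leaf term).
#' @export
randomOntology <- function(nd, depth = 3L, branching = 2L, seed = 1L,
                           decay = 0.5, clusters = NULL) {
  stopifnot(depth >= 1L, branching >= 1L, nd >= 1L)
  nLeaves <- branching ^ depth
  if (nLeaves < nd)
    stop("tree with depth ", depth, " and branching ", branching,
         " has only ", nLeaves, " leaves for ", nd, " diseases")
  parents <- list(root = character())
  level <- "root"
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      kids <- sprintf("%s.%d", p, seq_len(branching))
      for (k in kids) parents[[k]] <- p
      nxt <- c(nxt, kids)
    }
    level <- nxt
  }
  leaves <- level
  if (is.null(clusters)) {
    ids <- sprintf("disease%03d", seq_len(nd))
    ord <- seq_len(nd)
  } else {
    stopifnot(length(clusters) == nd, !is.null(names(clusters)))
    ids <- names(clusters)
    ord <- withr::with_seed(as.integer(seed),
                            order(clusters, sample.int(nd)))
  }
  mapping <- stats::setNames(leaves[seq_len(nd)], ids[ord])
  mapping <- mapping[ids]
  list(ontology = DiseaseOntology(parents, decay = decay), mapping = mapping)
}
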