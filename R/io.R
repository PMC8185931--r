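# Readers/writers for the plain-text interchange formats: association pair
# lists, FASTA sequences, ontology files (OBO or edge-list TSV), similarity
# matrices and ranked score tables. All identifier axes are sorted with the
# radix (C-locale) method so file order never leaks into matrix order.

.sortIds <- function(x) sort(unique(x), method = "radix")

#' Read circRNA-disease association pairs
#'
#' Reads a two-column TSV of (circRNA identifier, disease identifier)
#' pairs, collapses duplicate pairs to a single association, and builds the
#' binary adjacency matrix with both axes sorted lexicographically.
#'
#' @param path path to a TSV file; lines starting with `#` and blank lines
#'   are ignored; extra columns beyond the first two are ignored.
#' @return A [CircAssoc-class] object.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("c1\td1", "c1\td1", "c2\td2"), f)
#' readAssociations(f)
#' @export
readAssociations <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!any(keep)) stop("no association pairs found in '", path, "'")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineNo <- which(keep)
  bad <- which(vapply(fields, function(f) length(f) < 2L ||
                        !nzchar(f[[1L]]) || !nzchar(f[[2L]]), TRUE))
  if (length(bad))
    stop("malformed association row at line ", lineNo[bad[[1L]]],
         " of '", path, "' (need two tab-separated identifiers)")
  circ <- vapply(fields, `[[`, "", 1L)
  dis <- vapply(fields, `[[`, "", 2L)
  cids <- .sortIds(circ)
  dids <- .sortIds(dis)
  a <- matrix(0, length(cids), length(dids), dimnames = list(cids, dids))
  a[cbind(match(circ, cids), match(dis, dids))] <- 1
  CircAssoc(a)
}

#' Write association pairs back to TSV
#'
#' Inverse of [readAssociations()]: emits one (circRNA, disease) row per
#' known association, in row-major axis order.
#'
#' @param x a [CircAssoc-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(x, path) {
  stopifnot(is(x, "CircAssoc"))
  idx <- which(x@assoc == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  writeLines(paste(circIds(x)[idx[, 1L]], diseaseIds(x)[idx[, 2L]],
                   sep = "\t"), path)
  invisible(path)
}

#' Read circRNA sequences from FASTA
#'
#' Parses a FASTA file, takes the first whitespace-delimited header token
#' as the circRNA identifier, upper-cases the sequence and normalizes U to
#' T so RNA- and DNA-convention files agree before edit-distance
#' computation.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
readCircFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  seqs <- toupper(seqs)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for identifier(s): ",
         paste(ids[empty], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

# Minimal OBO reader: [Term] stanzas with id:, is_a: and is_obsolete lines.
# Obsolete terms are dropped; is_a targets may carry a trailing "! name".
.readObo <- function(lines) {
  starts <- which(trimws(lines) == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found")
  bounds <- c(starts, length(lines) + 1L)
  parents <- list()
  for (i in seq_along(starts)) {
    chunk <- lines[(bounds[[i]] + 1L):(bounds[[i + 1L]] - 1L)]
    chunk <- chunk[nzchar(trimws(chunk))]
    stanzaEnd <- grep("^\\[", trimws(chunk))
    if (length(stanzaEnd)) chunk <- chunk[seq_len(stanzaEnd[[1L]] - 1L)]
    getVals <- function(key) {
      hits <- grep(paste0("^", key, ":"), chunk, value = TRUE)
      trimws(sub("!.*$", "", sub(paste0("^", key, ":"), "", hits)))
    }
    if (any(grepl("true", getVals("is_obsolete")))) next
    id <- getVals("id")
    if (length(id) != 1L) stop("OBO [Term] stanza without a single id")
    parents[[id]] <- getVals("is_a")
  }
  known <- names(parents)
  bad <- setdiff(unlist(parents, use.names = FALSE), known)
  if (length(bad))
    stop("is_a reference(s) to unknown term(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  parents
}

#' Read a disease ontology
#'
#' Accepts either an OBO file (only `[Term]` stanzas with `id:` and `is_a:`
#' lines are used; obsolete terms are skipped) or a two-column TSV of
#' (child, parent) edges. The is_a relation must be acyclic.
#'
#' @param path path to an OBO or edge-list TSV file.
#' @param decay semantic decay factor in (0, 1), see
#'   [semanticContributions()].
#' @return A [DiseaseOntology-class] object.
#' @export
readOntology <- function(path, decay = 0.5) {
  lines <- readLines(path)
  if (any(trimws(lines) == "[Term]") || grepl("\\.obo$", path)) {
    parents <- .readObo(lines)
  } else {
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineNo <- which(keep)
    parents <- list()
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) == 1L && nzchar(f[[1L]])) {
        # isolated term with no parent edge
        if (is.null(parents[[f[[1L]]]])) parents[[f[[1L]]]] <- character()
        next
      }
      if (length(f) < 2L || !nzchar(f[[1L]]) || !nzchar(f[[2L]]))
        stop("malformed ontology edge at line ", lineNo[[i]],
             " of '", path, "'")
      parents[[f[[1L]]]] <- c(parents[[f[[1L]]]], f[[2L]])
    }
    if (!length(parents)) stop("no ontology terms found in '", path, "'")
  }
  DiseaseOntology(parents, decay = decay)
}

#' Write an ontology as a (child, parent) edge-list TSV
#'
#' @param ont a [DiseaseOntology-class] object.
#' @param path output file path. Root terms are written as single-column
#'   rows so the term set round-trips.
#' @return `path`, invisibly.
#' @export
writeOntology <- function(ont, path) {
  stopifnot(is(ont, "DiseaseOntology"))
  rows <- unlist(lapply(ontologyTerms(ont), function(t) {
    p <- ont@parents[[t]]
    if (length(p)) paste(t, p, sep = "\t") else t
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Write a ranked score table
#'
#' Emits every circRNA-disease pair with its prediction score and a flag
#' marking already-known associations, sorted by descending score with
#' ties broken by (circRNA, disease) lexicographic order — the ranking
#' used to shortlist candidate pairs for experimental follow-up.
#'
#' @param scores a [DmccdaResult-class] or a plain score matrix with the
#'   same dimnames as `mask`.
#' @param mask the [CircAssoc-class] the scores refer to.
#' @param path output TSV path.
#' @return The ranked `data.frame`, invisibly.
#' @export
writeScores <- function(scores, mask, path) {
  if (is(scores, "DmccdaResult")) scores <- scoreMatrix(scores)
  stopifnot(is(mask, "CircAssoc"))
  a <- assocMatrix(mask)
  if (!identical(dim(scores), dim(a)) ||
      !identical(dimnames(scores), dimnames(a)))
    stop("score matrix and association matrix shapes/identifiers disagree")
  df <- data.frame(
    circRNA = rep(rownames(a), times = ncol(a)),
    disease = rep(colnames(a), each = nrow(a)),
    score = as.vector(scores),
    known = as.integer(as.vector(a)),
    stringsAsFactors = FALSE)
  ord <- order(-df$score, df$circRNA, df$disease, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read/write a similarity matrix as header-addressed TSV
#'
#' The file carries identifiers in both the header row and the first
#' column, so precomputed similarities can bypass raw sequence/ontology
#' inputs.
#'
#' @param path TSV file path.
#' @param kind similarity kind label, see [SimilarityMatrix()].
#' @return `readSimilarity()` returns a [SimilarityMatrix-class];
#'   `writeSimilarity()` returns `path` invisibly.
#' @export
readSimilarity <- function(path, kind = "custom") {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  SimilarityMatrix(m, kind = kind)
}

#' @rdname readSimilarity
#' @param sim a [SimilarityMatrix-class] object.
#' @export
writeSimilarity <- function(sim, path) {
  stopifnot(is(sim, "SimilarityMatrix"))
  utils::write.table(simMatrix(sim), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
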