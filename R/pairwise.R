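#' Protein scoring scheme
#'
#' Substitution matrix plus affine gap penalties used by all local and
#' global protein alignments in the package. The default is BLOSUM62 with
#' BLAST's gap penalties (open 11, extend 1), modified so that the
#' ambiguity letter `X` scores 0 against everything (neutral handling) and
#' the stop letter `*` scores -4 (so translated-search alignments do not
#' silently cross stop codons).
#'
#' @param substitution symmetric integer substitution matrix with amino-acid
#'   row/column names, or `NULL` for the modified BLOSUM62 default.
#' @param gap_open,gap_extend non-negative gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(substitution)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    m <- BLOSUM62
    keep <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
              "P","S","T","W","Y","V","X","*")
    m <- m[keep, keep]
    m["X", ] <- 0L; m[, "X"] <- 0L
    m["*", ] <- -4L; m[, "*"] <- -4L; m["*", "*"] <- 1L
    substitution <- m
  }
  stopifnot(is.matrix(substitution),
            identical(rownames(substitution), colnames(substitution)),
            isTRUE(all.equal(substitution, t(substitution))),
            gap_open >= gap_extend, gap_extend >= 0)
  structure(list(substitution = substitution, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

# Restrict a sequence to letters the substitution matrix knows; unknowns -> X.
sanitize_aa <- function(x, scheme) {
  known <- rownames(scheme$substitution)
  ch <- strsplit(toupper(x), "")[[1]]
  ch[!ch %in% known] <- "X"
  paste(ch, collapse = "")
}

#' Best local alignment of two proteins
#'
#' Maximum-scoring Smith-Waterman local alignment under affine gaps,
#' standing in for a BLASTp hit. The empty alignment scores 0, so scores
#' are never negative.
#'
#' @param a,b protein sequences (single strings over the 20-letter alphabet;
#'   `X` allowed and scored 0 against everything).
#' @param scheme a [scoring_scheme()].
#' @return A list of class `local_hit` with elements `score`,
#'   `query_span` and `subject_span` (0-based half-open intervals on `a` and
#'   `b`), and `aligned` (the two gapped alignment strings).
#' @export
sw_align <- function(a, b, scheme = scoring_scheme()) {
  empty <- structure(list(score = 0, query_span = c(0L, 0L),
                          subject_span = c(0L, 0L),
                          aligned = c("", "")), class = "local_hit")
  if (nchar(a) == 0L || nchar(b) == 0L) return(empty)
  a <- sanitize_aa(a, scheme); b <- sanitize_aa(b, scheme)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scheme$substitution,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) return(empty)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  structure(list(
    score = sc,
    query_span = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
    subject_span = c(Biostrings::start(s) - 1L, Biostrings::end(s)),
    aligned = c(as.character(p), as.character(s))), class = "local_hit")
}

#' Rank database proteins against a query
#'
#' Scores every database member with [sw_align()] and orders hits by score
#' (descending), breaking ties by subject id (lexicographic), which makes
#' the ranking independent of database order.
#'
#' @param query protein sequence.
#' @param db named character vector of subject proteins (names are ids), or
#'   a `reference_db` (its sequences are used).
#' @param scheme a [scoring_scheme()].
#' @return data.frame with columns `subject_id`, `score` (and `og_label`
#'   when `db` carries labels), ordered best-first.
#' @export
rank_hits <- function(query, db, scheme = scoring_scheme()) {
  if (inherits(db, "reference_db")) {
    seqs <- setNames(db$entries$sequence, db$entries$protein_id)
    labels <- setNames(db$entries$og_label, db$entries$protein_id)
  } else {
    seqs <- db
    labels <- NULL
  }
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  scores <- vapply(seqs, function(s) sw_align(query, s, scheme)$score,
                   numeric(1))
  out <- data.frame(subject_id = names(seqs), score = unname(scores),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) out$og_label <- unname(labels[out$subject_id])
  out <- out[order(-out$score, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
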