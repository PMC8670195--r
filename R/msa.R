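# Progressive multiple alignment (MUSCLE-like first iteration): UPGMA guide
# tree on 3-mer count distances, then profile-profile global alignment with
# affine gaps along the guide tree. Deterministic: inputs are sorted by id
# before alignment and all DP tie-breaks are fixed.

msa_alphabet <- function() c("A","R","N","D","C","Q","E","G","H","I","L",
                             "K","M","F","P","S","T","W","Y","V","X","-")

# Substitution scores over the MSA alphabet: BLOSUM62-based, X and gap 0.
msa_submat <- function(scheme = scoring_scheme()) {
  ab <- msa_alphabet()
  m <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  known <- intersect(ab, rownames(scheme$substitution))
  m[known, known] <- scheme$substitution[known, known]
  m["-", ] <- 0; m[, "-"] <- 0
  m
}

# 1 - shared-3-mer fraction (shared = set intersection / smaller set).
kmer3_dist <- function(a, b) {
  km <- function(x) {
    n <- nchar(x)
    if (n < 3L) return(x)
    unique(substring(x, 1:(n - 2L), 3:n))
  }
  ka <- km(a); kb <- km(b)
  1 - length(intersect(ka, kb)) / max(1L, min(length(ka), length(kb)))
}

profile_of <- function(mat) {
  ab <- msa_alphabet()
  p <- apply(mat, 2, function(col) tabulate(match(col, ab), length(ab)))
  p / nrow(mat)
}

#' Progressive multiple alignment of proteins
#'
#' @param seqs named character vector of protein sequences (>= 2, no empty
#'   sequences). Input ids are sorted before alignment so the result does
#'   not depend on input order.
#' @param scheme a [scoring_scheme()] supplying substitution scores and gap
#'   penalties for the profile alignments.
#' @return list of class `multiple_alignment` with `rows` (named character
#'   vector of equal-length gapped sequences) and `ncol`.
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in MSA input")
  seqs <- vapply(seqs[order(names(seqs))], sanitize_aa, "", scheme = scheme)
  n <- length(seqs)
  smat <- msa_submat(scheme)
  alns <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  alns <- lapply(seq_along(alns), function(i) {
    rownames(alns[[i]]) <- names(seqs)[i]; alns[[i]]
  })
  if (n == 2L) {
    merged <- merge_profiles(alns[[1]], alns[[2]], smat, scheme)
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- kmer3_dist(seqs[[i]], seqs[[j]])
    hc <- hclust(as.dist(D), method = "average")
    nodes <- vector("list", n - 1)
    get_aln <- function(idx) if (idx < 0) alns[[-idx]] else nodes[[idx]]
    for (s in seq_len(n - 1)) {
      a <- get_aln(hc$merge[s, 1]); b <- get_aln(hc$merge[s, 2])
      nodes[[s]] <- merge_profiles(a, b, smat, scheme)
    }
    merged <- nodes[[n - 1]]
  }
  merged <- merged[names(seqs), , drop = FALSE]
  structure(list(rows = setNames(apply(merged, 1, paste, collapse = ""),
                                 rownames(merged)),
                 ncol = ncol(merged)),
            class = "multiple_alignment")
}

merge_profiles <- function(a, b, smat, scheme) {
  path <- cpp_profile_align(profile_of(a), profile_of(b), smat,
                            scheme$gap_open, scheme$gap_extend)
  L <- length(path)
  out <- matrix("-", nrow(a) + nrow(b), L)
  rownames(out) <- c(rownames(a), rownames(b))
  ia <- which(path != 2L); ib <- which(path != 1L)
  out[seq_len(nrow(a)), ia] <- a
  out[nrow(a) + seq_len(nrow(b)), ib] <- b
  out
}

#' @export
as.matrix.multiple_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, ""))
  rownames(m) <- names(x$rows)
  m
}

#' Write/read a gapped alignment as FASTA
#' @param aln a `multiple_alignment`.
#' @param path file path.
#' @return `path` (writer, invisibly) or a `multiple_alignment` (reader).
#' @export
write_alignment_fasta <- function(aln, path) {
  ss <- Biostrings::AAStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stopifnot(length(unique(Biostrings::width(ss))) == 1L)
  structure(list(rows = setNames(as.character(ss), names(ss)),
                 ncol = Biostrings::width(ss)[1]),
            class = "multiple_alignment")
}

#' Conserved-block cleaning of an alignment
#'
#' Simplified Gblocks-style cleaning based on identity fractions. A column
#' is conserved when its most frequent residue reaches fraction `c1`
#' (default 0.5 + 1/n) and its gap fraction is at most `max_gap_frac`
#' (relaxed mode; strict mode forbids gaps); highly conserved when it
#' reaches `c2`. Non-conserved columns are never retained, so any
#' non-conserved run separates blocks. In strict mode block flanks are
#' trimmed until highly conserved; relaxed mode (the default, mirroring
#' "smaller blocks / gaps within blocks / less strict flanks") only needs
#' conserved flanks. Blocks shorter than `min_block` are dropped.
#'
#' @param aln a `multiple_alignment`.
#' @param min_block minimum accepted block length (columns).
#' @param c1,c2 conserved / highly conserved identity fractions; `c1 = NULL`
#'   uses 0.5 + 1/n.
#' @param max_gap_frac maximum gap fraction of a retained column (relaxed).
#' @param max_noncons_run retained for interface compatibility; runs of
#'   non-conserved columns always separate blocks under these rules.
#' @param relaxed use the relaxed setting (default TRUE).
#' @return list of class `cleaned_alignment` with `alignment`, `retained`
#'   (ascending 1-based column indices) and `params`.
#' @export
clean_blocks <- function(aln, min_block = 5L, c1 = NULL, c2 = 0.85,
                         max_gap_frac = 0.5, max_noncons_run = 8L,
                         relaxed = TRUE) {
  mat <- as.matrix(aln)
  n <- nrow(mat)
  if (is.null(c1)) c1 <- 0.5 + 1 / n
  topfrac <- apply(mat, 2, function(col) {
    res <- col[col != "-"]
    if (!length(res)) 0 else max(table(res)) / n
  })
  gapfrac <- colMeans(mat == "-")
  gap_ok <- if (relaxed) gapfrac <= max_gap_frac else gapfrac == 0
  conserved <- topfrac >= c1 & gap_ok
  highly <- topfrac >= c2 & gap_ok
  retained <- integer(0)
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    if (!relaxed) {           # trim to highly conserved flanks
      while (s <= e && !highly[s]) s <- s + 1L
      while (e >= s && !highly[e]) e <- e - 1L
    }
    if (e - s + 1L >= min_block) retained <- c(retained, s:e)
  }
  structure(list(alignment = aln, retained = retained,
                 params = list(min_block = min_block, c1 = c1, c2 = c2,
                               max_gap_frac = max_gap_frac,
                               max_noncons_run = max_noncons_run,
                               relaxed = relaxed)),
            class = "cleaned_alignment")
}

#' Write the retained-column mask as a one-line TSV
#' @param cleaned a `cleaned_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_retained_mask <- function(cleaned, path) {
  writeLines(paste(cleaned$retained, collapse = "\t"), path)
  invisible(path)
}
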