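# Promoter extraction (fixed window upstream of the CDS start on the
# coding strand), log-odds PWM scanning on both strands, and per-OG mean
# TFBS frequency matrices.

#' Construct a nucleotide PWM
#' @param tf_family transcription-factor family name.
#' @param matrix width x 4 probability matrix (columns A, C, G, T; rows sum
#'   to 1).
#' @param background length-4 background probabilities (default uniform).
#' @param name optional matrix id (several matrices may share a family).
#' @return list of class `nuc_pwm`.
#' @export
nuc_pwm <- function(tf_family, matrix, background = rep(0.25, 4),
                    name = tf_family) {
  stopifnot(ncol(matrix) == 4L, all(abs(rowSums(matrix) - 1) < 1e-9),
            abs(sum(background) - 1) < 1e-9)
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(tf_family = tf_family, matrix = matrix,
                 background = background, name = name), class = "nuc_pwm")
}

#' Extract the promoter of a gene
#'
#' Returns `length` bp immediately 5' of the CDS start on the coding
#' strand: for a + strand gene the genomic window just upstream of the
#' first CDS base; for a - strand gene the reverse complement of the
#' window just downstream of the (genomic) CDS end. Truncated at the
#' chromosome edge with a warning.
#'
#' @param gene a [gene_model()] with a CDS.
#' @param genome DNAStringSet of chromosomes.
#' @param length promoter length in bp (default 2000).
#' @return promoter sequence as a character string (5' to 3' on the coding
#'   strand).
#' @export
extract_promoter <- function(gene, genome, length = 2000) {
  if (is.null(gene$cds) || nrow(gene$cds) == 0L)
    stop("gene ", gene$gene_id, " has no CDS")
  chrom <- genome[[gene$chromosome]]
  L <- xlen(chrom)
  if (gene$strand == "+") {
    s <- min(gene$cds[, 1])
    from <- max(0L, s - length)
    if (from > s - length)
      warning("promoter of ", gene$gene_id, " truncated at chromosome edge")
    if (s == 0L) return("")
    as.character(Biostrings::subseq(chrom, from + 1L, s))
  } else {
    e <- max(gene$cds[, 2])
    to <- min(L, e + length)
    if (to < e + length)
      warning("promoter of ", gene$gene_id, " truncated at chromosome edge")
    if (to == e) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(chrom, e + 1L, to)))
  }
}

# Log-odds score of every window of `seq` under the PWM; N contributes 0.
pwm_window_scores <- function(seq, pwm) {
  w <- nrow(pwm$matrix)
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  m <- length(x) - w + 1L
  if (m < 1L) return(numeric(0))
  lo <- log(pwm$matrix) -
    matrix(log(pwm$background), w, 4, byrow = TRUE)
  sc <- numeric(m)
  for (c in seq_len(w)) {
    v <- lo[c, x[c:(c + m - 1L)]]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

#' Count PWM hits in a promoter
#'
#' Scores every offset on both strands with the log-odds of the PWM
#' against its background (N scores as background, i.e. contributes 0) and
#' counts windows reaching `threshold_frac` of the maximum attainable
#' score. A window hit on both strands at the same offset counts once.
#'
#' @param seq promoter sequence (A/C/G/T/N).
#' @param pwm a [nuc_pwm()].
#' @param threshold_frac fraction of the maximum attainable log-odds score
#'   required for a hit (default 0.8).
#' @return integer hit count; hit window start offsets (0-based, forward
#'   coordinates) in attribute `offsets`.
#' @export
scan_promoter <- function(seq, pwm, threshold_frac = 0.8) {
  w <- nrow(pwm$matrix)
  if (nchar(seq) < w) return(structure(0L, offsets = integer(0)))
  lo <- log(pwm$matrix) -
    matrix(log(pwm$background), w, 4, byrow = TRUE)
  maxsc <- sum(apply(lo, 1, max))
  thr <- threshold_frac * maxsc
  fwd <- which(pwm_window_scores(seq, pwm) >= thr)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev_raw <- which(pwm_window_scores(rc, pwm) >= thr)
  # map reverse-strand window starts back to forward offsets
  rev <- nchar(seq) - w + 2L - rev_raw
  offs <- sort(unique(c(fwd, rev))) - 1L
  structure(length(offs), offsets = offs)
}

#' Per-OG mean TFBS frequency matrix
#'
#' Aggregates per-gene hit counts to the OG level: the cell (OG, TF
#' family) is the arithmetic mean of per-gene counts over the genes
#' assigned to that OG. Counts from several matrices of the same TF family
#' should be summed per family before calling (see
#' [promoter_hit_table()]). OGs with no counted gene are omitted.
#'
#' @param hit_counts data.frame gene_id, tf_family, count.
#' @param og_set an `og_assignment_set` or assignments data.frame.
#' @return numeric matrix, rows = OG labels, columns = TF families.
#' @export
og_tfbs_matrix <- function(hit_counts, og_set) {
  a <- og_set
  if (inherits(a, "og_assignment_set")) a <- a$assignments
  lab <- setNames(a$og_label, a$gene_id)
  hit_counts$og <- unname(lab[hit_counts$gene_id])
  if (anyNA(hit_counts$og))
    stop("hit counts for genes without an OG assignment")
  hit_counts <- hit_counts[hit_counts$og != "UNASSIGNED", , drop = FALSE]
  ogs <- sort(unique(hit_counts$og))
  fams <- sort(unique(hit_counts$tf_family))
  out <- matrix(0, length(ogs), length(fams), dimnames = list(ogs, fams))
  for (og in ogs) for (fam in fams) {
    sub <- hit_counts[hit_counts$og == og & hit_counts$tf_family == fam, ]
    genes <- unique(hit_counts$gene_id[hit_counts$og == og])
    tot <- setNames(rep(0, length(genes)), genes)
    tot[sub$gene_id] <- sub$count
    out[og, fam] <- mean(tot)
  }
  out
}

#' Scan all gene promoters with a PWM collection
#'
#' Extracts each gene's promoter, scans it with every PWM and sums hit
#' counts per TF family (several matrices of one family are added before
#' OG averaging).
#'
#' @param ann a `genome_annotation`.
#' @param genome DNAStringSet of chromosomes.
#' @param pwms list of [nuc_pwm()].
#' @param cfg a [pipeline_config()] (promoter_len used).
#' @param threshold_frac hit threshold fraction.
#' @return data.frame gene_id, tf_family, count.
#' @export
promoter_hit_table <- function(ann, genome, pwms, cfg = pipeline_config(),
                               threshold_frac = 0.8) {
  fams <- sort(unique(vapply(pwms, `[[`, "", "tf_family")))
  rows <- list()
  for (g in ann$genes) {
    if (g$status != "functional") next
    prom <- extract_promoter(g, genome, cfg$promoter_len)
    counts <- setNames(rep(0L, length(fams)), fams)
    for (p in pwms)
      counts[p$tf_family] <- counts[p$tf_family] +
        as.integer(scan_promoter(prom, p, threshold_frac))
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = g$gene_id, tf_family = fams, count = unname(counts),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read nucleotide PWMs in a minimal MEME-like text format
#'
#' `MOTIF <name> tf_family=<family> w=<width>` headers followed by `width`
#' rows of 4 tab-separated probabilities (A, C, G, T).
#'
#' @param pwms list of [nuc_pwm()].
#' @param path file path.
#' @return `path` invisibly (writer) or list of `nuc_pwm` (reader).
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("ALPHABET ACGT", con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s tf_family=%s w=%d", p$name, p$tf_family,
                       nrow(p$matrix)), con)
    for (r in seq_len(nrow(p$matrix)))
      writeLines(paste(formatC(p$matrix[r, ], format = "g", digits = 8),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pwms
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  heads <- grep("^MOTIF ", lines)
  out <- list()
  for (h in heads) {
    parts <- strsplit(lines[h], "\\s+")[[1]]
    fam <- sub("tf_family=", "", parts[3])
    w <- as.integer(sub("w=", "", parts[4]))
    mat <- do.call(rbind, lapply(lines[(h + 1):(h + w)], function(l)
      as.numeric(strsplit(l, "\t")[[1]])))
    out[[length(out) + 1]] <- nuc_pwm(fam, mat, name = parts[2])
  }
  out
}

#' Write a TFBS matrix as heatmap-ready TSV (rows OGs, columns TF families)
#' @param mat matrix from [og_tfbs_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tfbs_matrix <- function(mat, path) {
  df <- data.frame(og_label = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
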