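# Tandem-array detection (same OG, start-to-start distance <= 100 kb,
# chained transitively), WGD paralog pairing from externally supplied
# duplicated-block pairs, and per-chromosome distribution summaries.

# Coordinate/OG table for a set of genes: gene_id, chromosome, start, end,
# og_label (UNASSIGNED dropped).
gene_og_table <- function(genes, og_set) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes
  tab <- do.call(rbind, lapply(genes, function(g) data.frame(
    gene_id = g$gene_id, chromosome = g$chromosome,
    start = min(g$exons[, 1]), end = max(g$exons[, 2]),
    stringsAsFactors = FALSE)))
  a <- og_set
  if (inherits(a, "og_assignment_set")) a <- a$assignments
  lab <- setNames(a$og_label, a$gene_id)
  tab$og_label <- unname(lab[tab$gene_id])
  tab <- tab[!is.na(tab$og_label) & tab$og_label != "UNASSIGNED", ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Detect tandem duplication arrays
#'
#' Per chromosome and OG, genes are sorted by start; consecutive genes with
#' start-to-start distance at most `cfg$tandem_max_gap` (100 kb by default)
#' are chained transitively, and chains of two or more genes are reported
#' as tandem arrays. Unassigned genes are excluded.
#'
#' @param genes a `genome_annotation` or list of [gene_model()]s.
#' @param og_set an `og_assignment_set` (or its `assignments` data.frame).
#' @param cfg a [pipeline_config()].
#' @return data.frame with one row per array: chromosome, og_label,
#'   members (comma-separated gene ids ordered by start), n, start, end.
#' @export
detect_tandem_arrays <- function(genes, og_set, cfg = pipeline_config()) {
  tab <- gene_og_table(genes, og_set)
  out <- list()
  for (key in unique(paste(tab$chromosome, tab$og_label, sep = "\r"))) {
    sub <- tab[paste(tab$chromosome, tab$og_label, sep = "\r") == key, ,
               drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(sub$start) > cfg$tandem_max_gap))
    for (g in unique(grp)) {
      arr <- sub[grp == g, , drop = FALSE]
      if (nrow(arr) < 2L) next
      out[[length(out) + 1]] <- data.frame(
        chromosome = arr$chromosome[1], og_label = arr$og_label[1],
        members = paste(arr$gene_id, collapse = ","), n = nrow(arr),
        start = min(arr$start), end = max(arr$end),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), og_label = character(0),
                      members = character(0), n = integer(0),
                      start = numeric(0), end = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pair WGD paralogs from duplicated-block definitions
#'
#' Duplication blocks are an input (pairs of genomic intervals from a
#' published synteny analysis), not inferred. For each block pair, same-OG
#' genes with one member inside each side are paired; when one side offers
#' several candidates the partner with the highest local-alignment score is
#' chosen. A gene pairs at most once per block; pairs are deduplicated
#' across blocks.
#'
#' @param genes a `genome_annotation` or list of [gene_model()]s.
#' @param og_set an `og_assignment_set` or assignments data.frame.
#' @param blocks data.frame chrom1, start1, end1, chrom2, start2, end2,
#'   block_id (see [read_block_pairs()]).
#' @param scheme a [scoring_scheme()] for candidate disambiguation.
#' @return data.frame gene_a, gene_b, og_label, block_id.
#' @export
pair_wgd_paralogs <- function(genes, og_set, blocks,
                              scheme = scoring_scheme()) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes
  tab <- gene_og_table(genes, og_set)
  prot <- setNames(vapply(genes, function(g)
    if (is.na(g$protein)) "" else g$protein, ""),
    vapply(genes, `[[`, "", "gene_id"))
  inside <- function(row, chrom, s, e)
    row$chromosome == chrom & row$start >= s & row$end <= e
  pairs <- list()
  for (bi in seq_len(nrow(blocks))) {
    b <- blocks[bi, ]
    side1 <- tab[inside(tab, b$chrom1, b$start1, b$end1), , drop = FALSE]
    side2 <- tab[inside(tab, b$chrom2, b$start2, b$end2), , drop = FALSE]
    used1 <- character(0); used2 <- character(0)
    for (og in intersect(side1$og_label, side2$og_label)) {
      c1 <- setdiff(side1$gene_id[side1$og_label == og], used1)
      c2 <- setdiff(side2$gene_id[side2$og_label == og], used2)
      while (length(c1) && length(c2)) {
        if (length(c1) == 1L && length(c2) == 1L) {
          best <- c(c1[1], c2[1])
        } else {
          sc <- outer(c1, c2, Vectorize(function(x, y)
            sw_align(prot[[x]], prot[[y]], scheme)$score))
          ij <- which(sc == max(sc), arr.ind = TRUE)[1, ]
          best <- c(c1[ij[1]], c2[ij[2]])
        }
        if (best[1] == best[2]) break      # same gene cannot self-pair
        pairs[[length(pairs) + 1]] <- data.frame(
          gene_a = best[1], gene_b = best[2], og_label = og,
          block_id = as.character(b$block_id), stringsAsFactors = FALSE)
        used1 <- c(used1, best[1]); used2 <- c(used2, best[2])
        c1 <- setdiff(c1, best[1]); c2 <- setdiff(c2, best[2])
      }
    }
  }
  if (!length(pairs))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      og_label = character(0), block_id = character(0)))
  res <- unique(do.call(rbind, pairs))
  rownames(res) <- NULL
  res
}

#' Per-chromosome gene counts
#'
#' @param genes a `genome_annotation` or list of [gene_model()]s.
#' @return list with `counts` (data.frame chromosome, n, percent),
#'   `max_chromosomes`, `min_chromosomes`.
#' @export
chromosome_distribution <- function(genes) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes
  if (!length(genes))
    return(list(counts = data.frame(chromosome = character(0),
                                    n = integer(0), percent = numeric(0)),
                max_chromosomes = character(0),
                min_chromosomes = character(0)))
  chroms <- vapply(genes, `[[`, "", "chromosome")
  tb <- table(chroms)
  counts <- data.frame(chromosome = names(tb), n = as.integer(tb),
                       percent = 100 * as.integer(tb) / length(chroms),
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$chromosome), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       max_chromosomes = counts$chromosome[counts$n == max(counts$n)],
       min_chromosomes = counts$chromosome[counts$n == min(counts$n)])
}

#' Read / write duplication block pairs (8-column BED-pair TSV)
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, block_id, score.
#' Coordinates are 0-based half-open, as in BED.
#'
#' @param path file path.
#' @return data.frame of block pairs.
#' @export
read_block_pairs <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "block_id") %in% names(df)))
  df
}

#' @rdname read_block_pairs
#' @param blocks data.frame of block pairs.
#' @export
write_block_pairs <- function(blocks, path) {
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
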