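# Differential-expression candidate calling over the study's four
# contrasts: per-record up/down/ns status from the log2-ratio 1.5 / p 0.05
# thresholds, then per-gene senescence-associated and genotype-contrasting
# flags across contrasts.

#' The four expression comparisons
#' @return character vector of the closed comparison set.
#' @export
de_comparisons <- function() c("R453_PA_vs_A", "B481_PA_vs_A",
                               "R453_vs_B481_A", "R453_vs_B481_PA")

#' Call the status of one differential-expression record
#'
#' `up` when log2 ratio >= threshold and p below the p cut; `down` when
#' log2 ratio <= -threshold and p below the cut; `ns` otherwise. A missing
#' p-value yields `ns` with a warning. p-values are used as given (no
#' multiple-testing correction; see [categorize_expression()] for the
#' optional BH switch).
#'
#' @param log2_ratio numeric log2 expression ratio.
#' @param p_value p-value in `[0, 1]` (NA allowed).
#' @param cfg a [pipeline_config()].
#' @return `"up"`, `"down"` or `"ns"`.
#' @export
call_status <- function(log2_ratio, p_value, cfg = pipeline_config()) {
  if (is.na(p_value)) {
    warning("missing p-value; called ns")
    return("ns")
  }
  stopifnot(p_value >= 0, p_value <= 1)
  if (p_value < cfg$de_p_threshold) {
    if (log2_ratio >= cfg$de_lfc_threshold) return("up")
    if (log2_ratio <= -cfg$de_lfc_threshold) return("down")
  }
  "ns"
}

#' Categorise genes across the four expression contrasts
#'
#' Applies [call_status()] per record and derives per-gene flags:
#' `senescence_associated` when the gene is differential (not ns) in at
#' least one comparison, and `genotype_contrasting` when the two
#' post-anthesis vs anthesis statuses are up in one line and down in the
#' other (the pattern of contrasting regulation between early- and
#' delayed-senescence genotypes). Duplicate (gene, comparison) records are
#' an error. Record order never changes the calls.
#'
#' @param de data.frame with columns gene_id, comparison, log2_ratio,
#'   p_value (comparisons from [de_comparisons()]).
#' @param cfg a [pipeline_config()].
#' @param bh apply Benjamini-Hochberg correction to the p-values first
#'   (off by default: the published analysis used raw p-values).
#' @return data.frame: gene_id, one status column per comparison,
#'   senescence_associated, genotype_contrasting.
#' @export
categorize_expression <- function(de, cfg = pipeline_config(), bh = FALSE) {
  stopifnot(all(c("gene_id", "comparison", "log2_ratio", "p_value") %in%
                  names(de)))
  bad <- setdiff(unique(de$comparison), de_comparisons())
  if (length(bad)) stop("unknown comparison(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(de[, c("gene_id", "comparison")]))
    stop("duplicate (gene, comparison) records")
  if (bh) de$p_value <- stats::p.adjust(de$p_value, method = "BH")
  de <- de[order(de$gene_id, de$comparison), , drop = FALSE]
  status <- vapply(seq_len(nrow(de)), function(i)
    call_status(de$log2_ratio[i], de$p_value[i], cfg), "")
  genes <- sort(unique(de$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cmp in de_comparisons()) {
    s <- setNames(rep("ns", length(genes)), genes)
    sel <- de$comparison == cmp
    s[de$gene_id[sel]] <- status[sel]
    out[[cmp]] <- unname(s)
  }
  out$senescence_associated <- apply(
    out[, de_comparisons()], 1, function(r) any(r != "ns"))
  pa <- out[, c("R453_PA_vs_A", "B481_PA_vs_A")]
  out$genotype_contrasting <-
    (pa[[1]] == "up" & pa[[2]] == "down") |
    (pa[[1]] == "down" & pa[[2]] == "up")
  out
}

#' Read a differential-expression table (TSV)
#' @param path TSV with columns gene_id, comparison, log2_ratio, p_value.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "comparison", "log2_ratio", "p_value") %in%
                  names(df)))
  df
}

#' Write calls and a heatmap-ready wide matrix
#'
#' The wide matrix has one row per gene and one column per comparison,
#' holding the log2 ratio masked to NA where p >= the p cut (the heatmap
#' convention of showing only significant ratios).
#'
#' @param de long-format DE table.
#' @param calls result of [categorize_expression()].
#' @param path output TSV for the calls.
#' @param wide_path optional output TSV for the masked wide matrix.
#' @param cfg a [pipeline_config()].
#' @return `path`, invisibly.
#' @export
write_de_calls <- function(de, calls, path, wide_path = NULL,
                           cfg = pipeline_config()) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(wide_path)) {
    genes <- sort(unique(de$gene_id))
    wide <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (cmp in de_comparisons()) {
      v <- setNames(rep(NA_real_, length(genes)), genes)
      sel <- de$comparison == cmp & !is.na(de$p_value) &
        de$p_value < cfg$de_p_threshold
      v[de$gene_id[sel]] <- de$log2_ratio[sel]
      wide[[cmp]] <- unname(v)
    }
    write.table(wide, wide_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
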