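# Orthogroup assignment by best-hit consensus against a labelled reference
# database: a gene is assigned to an OG only when its k best hits (k = 3 by
# default) all carry that OG's label.

#' Assign one protein to an orthogroup
#'
#' Ranks the reference database with [rank_hits()] and applies the top-k
#' consensus rule: the query is assigned to label L only if its k best hits
#' all carry L. If the k-th place is tied in score, the whole score-tied
#' block must agree (conservative and database-order independent). A
#' database entry with the query's own id is excluded from ranking.
#'
#' @param query protein sequence.
#' @param db a `reference_db`.
#' @param k consensus size (default 3).
#' @param scheme a [scoring_scheme()].
#' @param query_id optional id used for self-hit exclusion.
#' @return list of class `og_assignment`: `gene_id`, `og_label` (or
#'   `"UNASSIGNED"`), `rule` (`"consensus"` or `"none"`) and `top_hits`
#'   (data.frame of the ranked hits inspected).
#' @export
assign_og <- function(query, db, k = 3L, scheme = scoring_scheme(),
                      query_id = NA_character_) {
  stopifnot(inherits(db, "reference_db"))
  entries <- db$entries
  if (!is.na(query_id)) entries <- entries[entries$protein_id != query_id, ,
                                           drop = FALSE]
  stopifnot(nrow(entries) >= k)
  unassigned <- function(hits) {
    structure(list(gene_id = query_id, og_label = "UNASSIGNED",
                   rule = "none", top_hits = hits),
              class = "og_assignment")
  }
  if (nchar(query) < 10L) {
    warning("query ", query_id, " shorter than 10 aa; unassigned")
    return(unassigned(NULL))
  }
  hits <- rank_hits(query, reference_db(entries, db$og_labels), scheme)
  cutoff <- hits$score[k]
  block <- hits[hits$score >= cutoff, , drop = FALSE]
  labels <- unique(block$og_label)
  if (length(labels) == 1L) {
    structure(list(gene_id = query_id, og_label = labels, rule = "consensus",
                   top_hits = head(hits, max(k, nrow(block)))),
              class = "og_assignment")
  } else {
    unassigned(head(hits, max(k, nrow(block))))
  }
}

#' Assign all functional genes of an annotation to orthogroups
#'
#' Applies [assign_og()] to every functional gene and summarises counts per
#' OG label, the number of distinct labels used and the unassigned genes.
#'
#' @param genes a `genome_annotation`, or a named list of [gene_model()]s,
#'   or a named character vector of proteins.
#' @param db a `reference_db`.
#' @param cfg a [pipeline_config()].
#' @param scheme a [scoring_scheme()].
#' @return list of class `og_assignment_set`: `assignments` (data.frame
#'   gene_id, og_label, rule), `per_og` (named counts), `n_distinct`,
#'   `unassigned` (gene ids), `details` (list of `og_assignment`).
#' @export
assign_all <- function(genes, db, cfg = pipeline_config(),
                       scheme = scoring_scheme()) {
  proteins <- as_protein_vector(genes)
  details <- lapply(names(proteins), function(id)
    assign_og(proteins[[id]], db, k = cfg$consensus_k, scheme = scheme,
              query_id = id))
  names(details) <- names(proteins)
  tab <- data.frame(
    gene_id = names(proteins),
    og_label = vapply(details, `[[`, "", "og_label"),
    rule = vapply(details, `[[`, "", "rule"),
    stringsAsFactors = FALSE, row.names = NULL)
  assigned <- tab$og_label[tab$og_label != "UNASSIGNED"]
  per_og <- if (length(assigned)) table(assigned) else table(character(0))
  structure(list(assignments = tab,
                 per_og = setNames(as.integer(per_og), names(per_og)),
                 n_distinct = length(unique(assigned)),
                 unassigned = tab$gene_id[tab$og_label == "UNASSIGNED"],
                 details = details),
            class = "og_assignment_set")
}

# Accept genome_annotation / gene_model list / named character vector and
# return named protein vector (functional genes only).
as_protein_vector <- function(genes) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes
  if (is.character(genes)) {
    stopifnot(!is.null(names(genes)))
    return(genes)
  }
  genes <- Filter(function(g) g$status == "functional" && !is.na(g$protein),
                  genes)
  setNames(vapply(genes, `[[`, "", "protein"),
           vapply(genes, `[[`, "", "gene_id"))
}

#' Annotate unassigned genes with their nearest tree cluster
#'
#' The tree-based rescue of unassigned genes is annotation only: each
#' unassigned gene gets the OG label of its nearest assigned leaf in the
#' tree (by patristic distance) as a `nearest_cluster` note; its label
#' stays `UNASSIGNED`.
#'
#' @param og_set an `og_assignment_set`.
#' @param tree a `phylo` whose tips include the unassigned genes.
#' @return data.frame gene_id, nearest_cluster for the unassigned genes.
#' @export
annotate_nearest_cluster <- function(og_set, tree) {
  tab <- og_set$assignments
  lab <- setNames(tab$og_label, tab$gene_id)
  d <- ape::cophenetic.phylo(tree)
  un <- intersect(og_set$unassigned, rownames(d))
  out <- data.frame(gene_id = un, nearest_cluster = NA_character_,
                    stringsAsFactors = FALSE)
  assigned_tips <- intersect(names(lab)[lab != "UNASSIGNED"], colnames(d))
  for (i in seq_along(un)) {
    if (!length(assigned_tips)) break
    dd <- d[un[i], assigned_tips]
    out$nearest_cluster[i] <- unname(lab[assigned_tips[which.min(dd)]])
  }
  out
}

#' Write an assignment table as TSV
#' @param og_set an `og_assignment_set`.
#' @param path output file.
#' @param k number of top hits to include.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(og_set, path, k = 3L) {
  tab <- og_set$assignments
  for (i in seq_len(k)) {
    tab[[paste0("top", i, "_subject")]] <-
      vapply(og_set$details, function(d)
        if (!is.null(d$top_hits) && nrow(d$top_hits) >= i)
          d$top_hits$subject_id[i] else NA_character_, character(1))
    tab[[paste0("top", i, "_label")]] <-
      vapply(og_set$details, function(d)
        if (!is.null(d$top_hits) && nrow(d$top_hits) >= i)
          d$top_hits$og_label[i] else NA_character_, character(1))
    tab[[paste0("top", i, "_score")]] <-
      vapply(og_set$details, function(d)
        if (!is.null(d$top_hits) && nrow(d$top_hits) >= i)
          d$top_hits$score[i] else NA_real_, numeric(1))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
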