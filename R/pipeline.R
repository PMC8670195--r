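# End-to-end runner: wires the modules together over one input set (real
# or simulated) and returns a single result object.

#' Run the full family-cataloguing pipeline
#'
#' Executes, in order: OG assignment of all functional genes, tandem-array
#' detection, WGD paralog pairing, per-chromosome distribution,
#' translated-search locus mining with pseudogene-evidence flags,
#' exon-structure classification (from planted or supplied subdomain
#' spans), promoter scanning with the PWM collection and per-OG TFBS
#' averaging, and differential-expression categorisation. Motif discovery
#' and iterative phylogenetic refinement are optional stages (they
#' dominate runtime) enabled by `motifs` and `phylogeny`.
#'
#' @param sim a `family_simulation`, or a list with elements `genome`,
#'   `annotation`, `ref_db`, `pwms`, `de_table`, `blocks` and optionally
#'   `subdomain_spans`.
#' @param cfg a [pipeline_config()].
#' @param scheme a [scoring_scheme()].
#' @param mine run locus mining (default TRUE).
#' @param motifs run motif discovery (default FALSE).
#' @param phylogeny run iterative refinement (default FALSE).
#' @return list of class `nacfam_result`.
#' @export
run_pipeline <- function(sim, cfg = pipeline_config(),
                         scheme = scoring_scheme(), mine = TRUE,
                         motifs = FALSE, phylogeny = FALSE) {
  ann <- sim$annotation
  og_set <- assign_all(ann, sim$ref_db, cfg, scheme)
  tandem <- detect_tandem_arrays(ann, og_set, cfg)
  wgd <- if (!is.null(sim$blocks))
    pair_wgd_paralogs(ann, og_set, sim$blocks, scheme) else NULL
  chrom_dist <- chromosome_distribution(ann)
  loci <- NULL
  if (mine) {
    queries <- if (inherits(sim, "family_simulation"))
      unlist(sim$founders) else as_protein_vector(ann)
    loci <- mine_loci(sim$genome, queries, scheme,
                      min_score = cfg$min_locus_score,
                      annotation = ann)
  }
  structures <- NULL
  if (!is.null(sim$subdomain_spans)) {
    lab <- setNames(og_set$assignments$og_label, og_set$assignments$gene_id)
    structures <- lapply(ann$genes, function(g) {
      og <- lab[[g$gene_id]]
      if (is.na(og) || og == "UNASSIGNED" ||
          is.null(sim$subdomain_spans[[og]])) return(NULL)
      classify_structure(g, sim$subdomain_spans[[og]])
    })
    structures <- Filter(Negate(is.null), structures)
  }
  hit_tab <- NULL; tfbs <- NULL
  if (!is.null(sim$pwms)) {
    hit_tab <- promoter_hit_table(ann, sim$genome, sim$pwms, cfg)
    keep <- hit_tab$gene_id %in%
      og_set$assignments$gene_id[og_set$assignments$og_label != "UNASSIGNED"]
    tfbs <- og_tfbs_matrix(hit_tab[keep, , drop = FALSE], og_set)
  }
  de_calls <- if (!is.null(sim$de_table))
    categorize_expression(sim$de_table, cfg) else NULL
  motif_models <- NULL; architectures <- NULL
  if (motifs) {
    prot <- as_protein_vector(ann)
    motif_models <- discover_motifs(prot, n = cfg$motif_count,
                                    wmin = cfg$motif_wmin,
                                    wmax = min(cfg$motif_wmax,
                                               min(nchar(prot))),
                                    seed = cfg$rng_seed)
    architectures <- architecture_table(motif_models, prot)
  }
  refinement <- NULL
  if (phylogeny) refinement <- iterative_refine(as_protein_vector(ann),
                                                cfg, scheme)
  structure(list(og = og_set, tandem_arrays = tandem, wgd_pairs = wgd,
                 chromosome_distribution = chrom_dist, loci = loci,
                 structures = structures, promoter_hits = hit_tab,
                 tfbs_matrix = tfbs, de_calls = de_calls,
                 motif_models = motif_models,
                 architectures = architectures,
                 refinement = refinement, cfg = cfg),
            class = "nacfam_result")
}

#' @export
print.nacfam_result <- function(x, ...) {
  a <- x$og$assignments
  cat("Family catalogue\n")
  cat(sprintf("  genes assigned: %d/%d into %d OGs (%d unassigned)\n",
              sum(a$og_label != "UNASSIGNED"), nrow(a), x$og$n_distinct,
              length(x$og$unassigned)))
  cat(sprintf("  tandem arrays: %d (%d genes)\n",
              nrow(x$tandem_arrays), sum(x$tandem_arrays$n)))
  if (!is.null(x$wgd_pairs))
    cat(sprintf("  WGD paralog pairs: %d\n", nrow(x$wgd_pairs)))
  if (!is.null(x$loci))
    cat(sprintf("  mined loci: %d (%d flagged pseudogene evidence)\n",
                nrow(x$loci), sum(!x$loci$intact)))
  if (!is.null(x$structures)) {
    labs <- table(vapply(x$structures, `[[`, "", "label"))
    cat("  exon structures:",
        paste(names(labs), as.integer(labs), sep = "=", collapse = " "),
        "\n")
  }
  if (!is.null(x$de_calls))
    cat(sprintf("  senescence-associated genes: %d\n",
                sum(x$de_calls$senescence_associated)))
  invisible(x)
}

#' @export
summary.nacfam_result <- function(object, ...) {
  print(object)
  cat("\nPer-OG gene counts:\n")
  print(object$og$per_og)
  if (!is.null(object$tfbs_matrix)) {
    cat("\nTFBS matrix (first columns):\n")
    print(round(object$tfbs_matrix[, seq_len(min(4,
      ncol(object$tfbs_matrix))), drop = FALSE], 2))
  }
  invisible(object)
}
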