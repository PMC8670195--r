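#' Pipeline configuration
#'
#' Bundles the analysis constants used across the pipeline. Defaults are the
#' study's published settings: top-3 best-hit consensus for OG assignment,
#' 100 kb tandem distance, 2000 bp promoters, 10 motifs of width 6-200 and
#' the log2-ratio 1.5 / p 0.05 differential-expression cut.
#'
#' @param consensus_k number of best hits that must agree for OG assignment.
#' @param tandem_max_gap maximum start-to-start distance (bp) between
#'   consecutive same-OG genes chained into a tandem array.
#' @param promoter_len promoter length in bp upstream of the CDS start.
#' @param motif_count number of motifs to discover.
#' @param motif_wmin,motif_wmax motif width bounds (aa). The full-scale
#'   upper bound is 200; desk-scale runs use 20.
#' @param de_lfc_threshold absolute log2-ratio cut for differential calls.
#' @param de_p_threshold p-value cut for differential calls.
#' @param refine_min_support minimum branch support for a cluster to be
#'   split off during iterative refinement.
#' @param refine_min_stem minimum stem branch length for a split; `NULL`
#'   means 2x the median internal branch length of the current tree.
#' @param refine_min_size minimum cluster size for a split.
#' @param min_locus_score minimum local-alignment score for a translated
#'   hit to seed a mined locus.
#' @param boot_reps bootstrap replicates used for branch support.
#' @param rng_seed integer seed used by seeded operations.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(consensus_k = 3L,
                            tandem_max_gap = 100000,
                            promoter_len = 2000,
                            motif_count = 10L,
                            motif_wmin = 6L,
                            motif_wmax = 200L,
                            de_lfc_threshold = 1.5,
                            de_p_threshold = 0.05,
                            refine_min_support = 0.95,
                            refine_min_stem = NULL,
                            refine_min_size = 3L,
                            min_locus_score = 50,
                            boot_reps = 100L,
                            rng_seed = 1L) {
  stopifnot(consensus_k >= 1L, tandem_max_gap > 0, promoter_len > 0,
            motif_count >= 0L, motif_wmin > 0L, motif_wmin <= motif_wmax,
            de_lfc_threshold > 0, de_p_threshold > 0,
            refine_min_support > 0, refine_min_size >= 1L,
            is.null(refine_min_stem) || refine_min_stem > 0)
  structure(list(consensus_k = as.integer(consensus_k),
                 tandem_max_gap = tandem_max_gap,
                 promoter_len = promoter_len,
                 motif_count = as.integer(motif_count),
                 motif_wmin = as.integer(motif_wmin),
                 motif_wmax = as.integer(motif_wmax),
                 de_lfc_threshold = de_lfc_threshold,
                 de_p_threshold = de_p_threshold,
                 refine_min_support = refine_min_support,
                 refine_min_stem = refine_min_stem,
                 refine_min_size = as.integer(refine_min_size),
                 min_locus_score = min_locus_score,
                 boot_reps = as.integer(boot_reps),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}
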