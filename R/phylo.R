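# Distance-based tree building (neighbor-joining + bootstrap support) and
# the iterative divergent-cluster refinement loop: align -> clean -> tree ->
# split sharply divergent, well-supported clusters -> re-analyse each part.
# NJ + bootstrap stands in for the original ML + aLRT engine; the iteration
# logic is independent of the tree engine.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ via ape, followed by a cleanup pass that clamps negative
#' branch-length estimates to 0, moving each deficit to the sibling branch
#' so path lengths through the parent are preserved.
#'
#' @param d symmetric numeric distance matrix (zero diagonal, >= 3 taxa)
#'   with row/column names.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) >= 3L, !is.null(rownames(d)))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  tr <- ape::nj(d)
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  for (e in which(tr$edge.length < 0)) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs))
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0   # sibling pushed negative: clamp
  tr
}

#' Normalised p-distance on retained columns
#'
#' Pairwise proportion of mismatching residues over the retained columns,
#' ignoring columns where either sequence has a gap. Pairs with no
#' comparable column get distance 1.
#'
#' @param cleaned a `cleaned_alignment` (or `multiple_alignment`, in which
#'   case all columns are used).
#' @param columns optional explicit column indices (used for bootstrap
#'   resampling; duplicates allowed).
#' @return symmetric distance matrix.
#' @export
p_distance <- function(cleaned, columns = NULL) {
  if (inherits(cleaned, "cleaned_alignment")) {
    mat <- as.matrix(cleaned$alignment)
    if (is.null(columns)) columns <- cleaned$retained
  } else {
    mat <- as.matrix(cleaned)
    if (is.null(columns)) columns <- seq_len(ncol(mat))
  }
  sub <- mat[, columns, drop = FALSE]
  n <- nrow(sub)
  d <- matrix(0, n, n, dimnames = list(rownames(sub), rownames(sub)))
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    ok <- sub[i, ] != "-" & sub[j, ] != "-"
    d[i, j] <- d[j, i] <-
      if (!any(ok)) 1 else mean(sub[i, ok] != sub[j, ok])
  }
  d
}

#' NJ tree with bootstrap branch support
#'
#' Builds the reference NJ tree from p-distances on the retained columns,
#' then resamples retained columns with replacement `n_reps` times; the
#' support of each internal edge is the fraction of replicate trees
#' containing the same bipartition, stored as internal-node labels.
#'
#' @param cleaned a `cleaned_alignment` with >= 4 sequences (with fewer the
#'   tree is returned without supports).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; fixed seed gives byte-identical supports.
#' @return a `phylo` with numeric `node.label` supports in `[0, 1]` (root
#'   label empty: the trivial all-leaves split is never reported).
#' @export
bootstrap_support <- function(cleaned, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(cleaned, "cleaned_alignment"), n_reps >= 1L)
  if (!length(cleaned$retained)) stop("no retained columns")
  ref <- nj_tree(p_distance(cleaned))
  n <- length(ref$tip.label)
  if (n < 4L) return(ref)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample(cleaned$retained, length(cleaned$retained), replace = TRUE)
    reps[[r]] <- nj_tree(p_distance(cleaned, columns = cols))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- counts / n_reps
  lab <- formatC(supp, digits = 3, format = "g")
  lab[1] <- ""                       # root: trivial split, not reported
  ref$node.label <- lab
  attr(ref, "support") <- supp
  ref
}

# Internal edge table: for each edge leading to an internal node, the leaf
# set below it, its length and its support (from node labels).
edge_clusters <- function(tree) {
  n <- length(tree$tip.label)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  res <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    tips <- ape::extract.clade(tree, child)$tip.label
    res[[length(res) + 1]] <- list(
      tips = tips, stem = tree$edge.length[e],
      support = if (length(supp)) supp[child - n] else NA_real_)
  }
  res
}

#' Iterative phylogenetic refinement of a sequence family
#'
#' Round 0 aligns, cleans and builds a supported tree for the whole set.
#' Clusters connected to the rest of the tree by a long stem (length at
#' least `refine_min_stem`, default 2x the median internal branch length),
#' with support at least `refine_min_support` and size at least
#' `refine_min_size`, are split off; each split set and the remainder
#' re-enter as new rounds while they have at least 8 members. Splitting the
#' divergent sequences away lets cleaning retain more columns for the
#' homogeneous subsets, which is the point of the iteration.
#'
#' @param seqs named character vector of proteins (>= 8).
#' @param cfg a [pipeline_config()] (refine_* and boot_reps fields used).
#' @param scheme a [scoring_scheme()].
#' @return list of `refinement_round` lists: `round`, `members`,
#'   `retained_positions`, `tree`, `split_clusters`.
#' @export
iterative_refine <- function(seqs, cfg = pipeline_config(),
                             scheme = scoring_scheme()) {
  stopifnot(length(seqs) >= 8L)
  rounds <- list()
  queue <- list(seqs)
  round_idx <- 0L
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    aln <- progressive_msa(cur, scheme)
    cleaned <- clean_blocks(aln)
    tree <- if (length(cleaned$retained))
      bootstrap_support(cleaned, n_reps = cfg$boot_reps,
                        seed = cfg$rng_seed + round_idx)
    else NULL
    splits <- list()
    if (!is.null(tree) && length(tree$tip.label) >= 4L) {
      cand <- edge_clusters(tree)
      stem_thr <- cfg$refine_min_stem
      if (is.null(stem_thr)) {
        internal_len <- vapply(cand, `[[`, 0, "stem")
        stem_thr <- 2 * median(internal_len)
      }
      ok <- Filter(function(cl) {
        sz <- length(cl$tips)
        sz >= cfg$refine_min_size && sz <= length(cur) - 2L &&
          is.finite(stem_thr) && cl$stem >= stem_thr &&
          !is.na(cl$support) && cl$support >= cfg$refine_min_support
      }, cand)
      ok <- ok[order(-vapply(ok, `[[`, 0, "stem"))]
      taken <- character(0)
      for (cl in ok) {
        if (length(intersect(cl$tips, taken))) next
        splits[[length(splits) + 1]] <- cl$tips
        taken <- c(taken, cl$tips)
      }
    }
    rounds[[length(rounds) + 1]] <- structure(
      list(round = round_idx, members = names(cur),
           retained_positions = length(cleaned$retained),
           tree = tree, split_clusters = splits),
      class = "refinement_round")
    if (length(splits)) {
      remainder <- setdiff(names(cur), unlist(splits))
      for (sp in splits)
        if (length(sp) >= 8L) queue <- c(queue, list(cur[sp]))
      if (length(remainder) >= 8L) queue <- c(queue, list(cur[remainder]))
    }
    round_idx <- round_idx + 1L
  }
  rounds
}

#' Summarise refinement rounds as a data.frame
#' @param rounds result of [iterative_refine()].
#' @return data.frame round, n_seqs, retained_positions, n_splits.
#' @export
refinement_summary <- function(rounds) {
  data.frame(
    round = vapply(rounds, `[[`, 0L, "round"),
    n_seqs = vapply(rounds, function(r) length(r$members), 0L),
    retained_positions = vapply(rounds, `[[`, 0L, "retained_positions"),
    n_splits = vapply(rounds, function(r) length(r$split_clusters), 0L))
}
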