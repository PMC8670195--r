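# Independent oracles and shared fixtures.
#
# The oracles deliberately avoid the implementation's algorithms: local
# alignment is scored by exhaustive enumeration of explicit alignments,
# PWM hits by a literal window loop.

.fixture_cache <- new.env()

# One default synthetic family shared across test files.
default_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_family(seed = 17)
  .fixture_cache$sim
}

mined_loci_cached <- function() {
  if (is.null(.fixture_cache$loci)) {
    sim <- default_sim()
    .fixture_cache$loci <- mine_loci(sim$genome, unlist(sim$founders),
                                     min_score = 80,
                                     annotation = sim$annotation)
  }
  .fixture_cache$loci
}

og_set_cached <- function() {
  if (is.null(.fixture_cache$og))
    .fixture_cache$og <- assign_all(default_sim()$annotation,
                                    default_sim()$ref_db)
  .fixture_cache$og
}

# Exhaustive local-alignment score: maximise over every substring pair and
# every explicit gapped alignment between them; affine gap runs cost
# open + len * extend. No dynamic programming involved.
oracle_local_score <- function(a, b, scheme = scoring_scheme()) {
  sub <- scheme$substitution
  go <- scheme$gap_open; ge <- scheme$gap_extend
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- 0
  rec <- function(i, i2, j, j2, prev, sc) {
    if (i > i2 && j > j2) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= i2 && j <= j2)
      rec(i + 1L, i2, j + 1L, j2, "M", sc + sub[A[i], B[j]])
    if (i <= i2)
      rec(i + 1L, i2, j, j2, "X",
          sc - ge - if (prev != "X") go else 0)
    if (j <= j2)
      rec(i, i2, j + 1L, j2, "Y",
          sc - ge - if (prev != "Y") go else 0)
    invisible()
  }
  for (i1 in seq_along(A)) for (i2 in i1:length(A))
    for (j1 in seq_along(B)) for (j2 in j1:length(B))
      rec(i1, i2, j1, j2, "M", 0)
  best
}

# Literal PWM hit count: score every window on both strands in a plain
# loop and count unions of forward offsets above the threshold.
oracle_scan_count <- function(seq, pwm, threshold_frac = 0.8) {
  w <- nrow(pwm$matrix)
  lo <- log(pwm$matrix) - matrix(log(pwm$background), w, 4, byrow = TRUE)
  maxsc <- sum(apply(lo, 1, max))
  score_at <- function(s, pos) {
    tot <- 0
    for (c in seq_len(w)) {
      base <- substr(s, pos + c - 1L, pos + c - 1L)
      k <- match(base, c("A", "C", "G", "T"))
      tot <- tot + if (is.na(k)) 0 else lo[c, k]
    }
    tot
  }
  L <- nchar(seq)
  if (L < w) return(0L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  offs <- integer(0)
  for (pos in seq_len(L - w + 1L)) {
    if (score_at(seq, pos) >= threshold_frac * maxsc)
      offs <- c(offs, pos)
    if (score_at(rc, pos) >= threshold_frac * maxsc)
      offs <- c(offs, L - w + 2L - pos)
  }
  length(unique(offs))
}

random_aa_string <- function(n, alphabet = c("A", "C", "D", "E"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# Small labelled reference database from explicit sequences.
toy_ref_db <- function(seqs, labels, species = "Vvin") {
  reference_db(data.frame(
    protein_id = names(seqs), species = species, og_label = labels,
    sequence = unname(seqs), stringsAsFactors = FALSE))
}

# A minimal genome annotation holding one synthetic gene.
toy_gene <- function(exons, strand = "+", chromosome = "chr1",
                     gene_id = "g1") {
  gene_model(gene_id, chromosome, strand, exons)
}
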