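# Neighbor-joining, bootstrap support and iterative refinement.

test_that("three-taxon branch lengths match the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 1, tolerance = 1e-9)  # (dAB + dAC - dBC) / 2
  expect_equal(len[["B"]], 1, tolerance = 1e-9)
  expect_equal(len[["C"]], 3, tolerance = 1e-9)
})

test_that("NJ rejects asymmetric matrices", {
  d <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
})

test_that("NJ recovers planted additive trees exactly", {
  tt <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  tr <- nj_tree(ape::cophenetic.phylo(tt))
  expect_equal(ape::dist.topo(ape::unroot(tt), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  d2 <- ape::cophenetic.phylo(tr)
  d1 <- ape::cophenetic.phylo(tt)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
  set.seed(401)
  hits <- 0L
  for (i in 1:50) {
    rt <- ape::rtree(6)
    rt$edge.length <- runif(nrow(rt$edge), 0.1, 2)
    nj <- nj_tree(ape::cophenetic.phylo(rt))
    hits <- hits + (ape::dist.topo(ape::unroot(rt), ape::unroot(nj)) == 0)
  }
  expect_equal(hits, 50L)
})

test_that("taxa at distance zero come out as siblings", {
  set.seed(402)
  d <- matrix(runif(25, 1, 3), 5)
  d <- (d + t(d)) / 2; diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  dimnames(d) <- list(letters[1:5], letters[1:5])
  tr <- nj_tree(d)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_true(all(tr$edge.length >= 0))
})

make_split_alignment <- function() {
  set.seed(403)
  colsA <- random_aa_string(100, c("A", "C", "D", "E"))
  colsB <- random_aa_string(100, c("K", "L", "M", "F"))
  mixed <- paste0(substr(colsA, 1, 50), substr(colsB, 51, 100))
  rows <- c(g1a = colsA, g1b = colsA, g1c = colsA, g1d = colsA,
            g2a = mixed, g2b = mixed, g2c = mixed, g2d = mixed)
  aln <- structure(list(rows = rows, ncol = 100L),
                   class = "multiple_alignment")
  structure(list(alignment = aln, retained = 1:100, params = list()),
            class = "cleaned_alignment")
}

test_that("a clean 4+4 split gets bootstrap support 1 and supports live in
           [0,1] with the trivial split unreported", {
  cl <- make_split_alignment()
  bs <- bootstrap_support(cl, n_reps = 50, seed = 9)
  supp <- attr(bs, "support")
  expect_true(all(supp >= 0 & supp <= 1))
  expect_identical(bs$node.label[1], "")    # root / all-leaves split
  central <- which(vapply(2:bs$Nnode, function(n) {
    tips <- ape::extract.clade(bs, length(bs$tip.label) + n)$tip.label
    setequal(tips, paste0("g1", letters[1:4])) ||
      setequal(tips, paste0("g2", letters[1:4]))
  }, logical(1))) + 1
  expect_true(all(supp[central] == 1))
})

test_that("single-replicate supports are 0 or 1 and fixed seeds reproduce
           byte-identical supports", {
  cl <- make_split_alignment()
  b1 <- bootstrap_support(cl, n_reps = 1, seed = 4)
  expect_true(all(attr(b1, "support") %in% c(0, 1)))
  b2 <- bootstrap_support(cl, n_reps = 25, seed = 7)
  b3 <- bootstrap_support(cl, n_reps = 25, seed = 7)
  expect_identical(ape::write.tree(b2), ape::write.tree(b3))
})

test_that("a homogeneous family refines in a single round with no splits", {
  set.seed(404)
  base <- random_aa_string(80, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  seqs <- setNames(vapply(1:10, function(i) {
    ch <- strsplit(base, "")[[1]]
    mut <- runif(80) < 0.05
    ch[mut] <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                      sum(mut), replace = TRUE)
    paste(ch, collapse = "")
  }, ""), paste0("s", 1:10))
  rounds <- iterative_refine(seqs, pipeline_config(boot_reps = 40))
  expect_length(rounds, 1)
  expect_length(rounds[[1]]$split_clusters, 0)
})

test_that("a planted divergent subfamily is split off and its own round
           retains more positions than the joint round", {
  fam <- simulate_divergent_family(seed = 5)
  rounds <- iterative_refine(fam$seqs,
                             pipeline_config(boot_reps = 60, rng_seed = 5))
  expect_gte(length(rounds), 2)
  splits <- rounds[[1]]$split_clusters
  expect_true(any(vapply(splits, setequal, logical(1), fam$divergent)))
  div_round <- Filter(function(r) setequal(r$members, fam$divergent),
                      rounds)
  expect_length(div_round, 1)
  expect_gt(div_round[[1]]$retained_positions,
            rounds[[1]]$retained_positions)
})

test_that("an infinite stem threshold disables splitting", {
  fam <- simulate_divergent_family(seed = 6)
  rounds <- iterative_refine(
    fam$seqs, pipeline_config(boot_reps = 30, refine_min_stem = Inf))
  expect_length(rounds, 1)
})

test_that("round count never exceeds the number of sequences", {
  fam <- simulate_divergent_family(seed = 12, n_core = 10, n_div = 8)
  rounds <- iterative_refine(fam$seqs,
                             pipeline_config(boot_reps = 30))
  expect_lte(length(rounds), length(fam$seqs))
  rs <- refinement_summary(rounds)
  expect_equal(rs$round, seq_len(nrow(rs)) - 1L)
})
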