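# Tandem arrays, WGD paralog pairing, chromosome distribution.

toy_genes <- function(starts, chrom = "chr1", og = "2a", len = 1000L) {
  genes <- lapply(seq_along(starts), function(i)
    gene_model(paste0("g", i), chrom, "+",
               cbind(starts[i], starts[i] + len)))
  names(genes) <- paste0("g", seq_along(starts))
  assign <- data.frame(gene_id = names(genes), og_label = og,
                       stringsAsFactors = FALSE)
  list(genes = genes, assign = assign)
}

test_that("tandem chaining follows the 100 kb start-to-start rule", {
  t1 <- toy_genes(c(0, 60000))
  expect_equal(detect_tandem_arrays(t1$genes, t1$assign)$n, 2L)
  t2 <- toy_genes(c(0, 150000))
  expect_equal(nrow(detect_tandem_arrays(t2$genes, t2$assign)), 0L)
  # transitive chaining: 0 / 90k / 180k is one array of 3
  t3 <- toy_genes(c(0, 90000, 180000))
  arr <- detect_tandem_arrays(t3$genes, t3$assign)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$n, 3L)
  expect_equal(arr$members, "g1,g2,g3")
})

test_that("arrays partition their genes and singletons account for the
           rest", {
  t4 <- toy_genes(c(0, 50000, 300000, 340000, 600000))
  arr <- detect_tandem_arrays(t4$genes, t4$assign)
  members <- unlist(strsplit(arr$members, ","))
  expect_false(anyDuplicated(members) > 0)
  expect_equal(sum(arr$n) + (length(t4$genes) - length(members)),
               length(t4$genes))
})

test_that("genes of different OGs never chain", {
  t5 <- toy_genes(c(0, 50000))
  t5$assign$og_label <- c("2a", "2b")
  expect_equal(nrow(detect_tandem_arrays(t5$genes, t5$assign)), 0L)
})

test_that("planted tandem arrays on the synthetic genome are recovered
           exactly", {
  sim <- default_sim()
  arr <- detect_tandem_arrays(sim$annotation, sim$truth$og)
  tr <- sim$truth$tandem_arrays
  expect_equal(nrow(arr), nrow(tr))
  expect_setequal(arr$members, tr$members)
  expect_equal(sort(arr$og_label), sort(tr$og_label))
})

wgd_setup <- function(og2 = "2a") {
  genes <- list(
    a = gene_model("a", "chr1", "+", cbind(100000L, 101000L)),
    b = gene_model("b", "chr5", "+", cbind(200000L, 201000L)))
  assign <- data.frame(gene_id = c("a", "b"), og_label = c("2a", og2),
                       stringsAsFactors = FALSE)
  blocks <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 1e6,
                       chrom2 = "chr5", start2 = 0, end2 = 1e6,
                       block_id = "b1", score = 0,
                       stringsAsFactors = FALSE)
  list(genes = genes, assign = assign, blocks = blocks)
}

test_that("one same-OG gene on each block side yields one pair", {
  s <- wgd_setup()
  p <- pair_wgd_paralogs(s$genes, s$assign, s$blocks)
  expect_equal(nrow(p), 1L)
  expect_setequal(c(p$gene_a, p$gene_b), c("a", "b"))
})

test_that("different OGs on the two sides yield no pair", {
  s <- wgd_setup(og2 = "3c")
  expect_equal(nrow(pair_wgd_paralogs(s$genes, s$assign, s$blocks)), 0L)
})

test_that("two candidates on one side resolve to the best-scoring partner", {
  set.seed(601)
  alpha <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  target <- random_aa_string(50, alpha)
  near <- paste0(substr(target, 1, 45), "AAAAA")
  far <- random_aa_string(50, alpha)
  genes <- list(
    a1 = gene_model("a1", "chr1", "+", cbind(100000L, 101000L)),
    a2 = gene_model("a2", "chr1", "+", cbind(300000L, 301000L)),
    b1 = gene_model("b1", "chr5", "+", cbind(200000L, 201000L)))
  genes$a1$protein <- near; genes$a2$protein <- far
  genes$b1$protein <- target
  assign <- data.frame(gene_id = c("a1", "a2", "b1"), og_label = "2a",
                       stringsAsFactors = FALSE)
  blocks <- wgd_setup()$blocks
  p <- pair_wgd_paralogs(genes, assign, blocks)
  expect_equal(nrow(p), 1L)
  # brute force: partner = candidate with the higher alignment score
  scores <- c(a1 = sw_align(near, target)$score,
              a2 = sw_align(far, target)$score)
  expect_equal(p$gene_a, names(which.max(scores)))
  expect_equal(p$gene_b, "b1")
})

test_that("planted WGD pairs on the synthetic genome are recovered
           exactly", {
  sim <- default_sim()
  p <- pair_wgd_paralogs(sim$annotation, sim$truth$og, sim$blocks)
  tr <- sim$truth$wgd_pairs
  key <- function(df) sort(paste(pmin(df$gene_a, df$gene_b),
                                 pmax(df$gene_a, df$gene_b)))
  expect_equal(key(p), key(tr))
})

test_that("chromosome distribution reports counts, percentages and
           argmax/argmin", {
  genes <- c(lapply(1:10, function(i)
    gene_model(paste0("x", i), "chr1", "+", cbind(i * 1000L, i * 1000L + 10L))),
    lapply(1:5, function(i)
      gene_model(paste0("y", i), "chr2", "+", cbind(i * 1000L, i * 1000L + 10L))))
  cd <- chromosome_distribution(genes)
  expect_equal(cd$counts$n, c(10L, 5L))
  expect_equal(cd$counts$percent, c(200 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(cd$max_chromosomes, "chr1")
  expect_equal(cd$min_chromosomes, "chr2")
  empty <- chromosome_distribution(list())
  expect_equal(nrow(empty$counts), 0L)
})

test_that("block-pair files round-trip", {
  sim <- default_sim()
  f <- tempfile()
  write_block_pairs(sim$blocks, f)
  b2 <- read_block_pairs(f)
  expect_equal(b2$block_id, sim$blocks$block_id)
  expect_equal(b2$start1, sim$blocks$start1)
})
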