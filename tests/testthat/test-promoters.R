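# Promoter extraction, PWM scanning, per-OG TFBS aggregation.

sharp_pwm <- function(consensus, fam = "AP2") {
  w <- nchar(consensus)
  mat <- matrix(0.01, w, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  for (r in seq_len(w)) mat[r, idx[r]] <- 0.97
  nuc_pwm(fam, mat)
}

test_that("promoters come from immediately upstream of the CDS start on
           the coding strand", {
  set.seed(701)
  chrom <- paste(sample(c("A", "C", "G", "T"), 9000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  gplus <- gene_model("gp", "chr1", "+", cbind(5000L, 5300L))
  expect_identical(extract_promoter(gplus, genome),
                   substr(chrom, 3001, 5000))
  gminus <- gene_model("gm", "chr1", "-", cbind(4700L, 5000L))
  expect_identical(extract_promoter(gminus, genome),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(chrom, 5001, 7000)))))
})

test_that("promoters truncate at the chromosome edge with a warning", {
  set.seed(702)
  chrom <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  g <- gene_model("g", "chr1", "+", cbind(800L, 1100L))
  expect_warning(p <- extract_promoter(g, genome), "truncated")
  expect_equal(nchar(p), 800)
  g2 <- gene_model("g2", "chr1", "+", cbind(800L, 1100L))
  g2$cds <- matrix(numeric(0), 0, 2)
  expect_error(extract_promoter(g2, genome), "no CDS")
})

test_that("a planted consensus site is found once, on either strand", {
  pwm <- sharp_pwm("ACGTACGTACGT")
  set.seed(703)
  prom <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  substr(prom, 101, 112) <- "ACGTACGTACGT"
  expect_equal(as.integer(scan_promoter(prom, pwm)), 1L)
  prom2 <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  substr(prom2, 101, 112) <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGTACGTACGT")))
  expect_equal(as.integer(scan_promoter(prom2, pwm)), 1L)
  # scanning a sequence and its reverse complement is equivalent
  expect_equal(as.integer(scan_promoter(prom, pwm)),
               as.integer(scan_promoter(as.character(
                 Biostrings::reverseComplement(Biostrings::DNAString(prom))),
                 pwm)))
})

test_that("sequences shorter than the PWM and N-rich windows behave", {
  pwm <- sharp_pwm("ACGTACGTACGT")
  expect_equal(as.integer(scan_promoter("ACGT", pwm)), 0L)
  expect_equal(as.integer(scan_promoter(strrep("N", 100), pwm)), 0L)
})

test_that("hit counts match the brute-force window oracle", {
  pwm <- sharp_pwm("ACGTTGCAAGT")
  set.seed(704)
  for (rep in 1:5) {
    prom <- paste(sample(c("A", "C", "G", "T", "N"), 300, TRUE,
                         prob = c(.24, .24, .24, .24, .04)), collapse = "")
    k <- sample(0:2, 1)
    for (s in seq_len(k)) {
      off <- 30 + 40 * s
      substr(prom, off, off + 10) <- "ACGTTGCAAGT"
    }
    expect_equal(as.integer(scan_promoter(prom, pwm)),
                 oracle_scan_count(prom, pwm))
  }
})

test_that("raising the threshold never increases hit counts", {
  pwm <- sharp_pwm("ACGTTGCAAGT")
  set.seed(705)
  prom <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  substr(prom, 50, 60) <- "ACGTTGCAAGT"
  counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(th)
    as.integer(scan_promoter(prom, pwm, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted site counts are recovered over the synthetic promoters", {
  sim <- default_sim()
  ht <- promoter_hit_table(sim$annotation, sim$genome, sim$pwms)
  m <- merge(ht, sim$truth$promoter_sites,
             by = c("gene_id", "tf_family"),
             suffixes = c("_obs", "_true"))
  expect_equal(nrow(m), nrow(sim$truth$promoter_sites))
  expect_equal(m$count_obs, m$count_true)
})

test_that("OG matrix cells are arithmetic means of per-gene counts", {
  counts <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    tf_family = "AP2", count = c(2L, 4L, 7L), stringsAsFactors = FALSE)
  assign <- data.frame(gene_id = c("g1", "g2", "g3"),
                       og_label = c("1a", "1a", "2a"),
                       stringsAsFactors = FALSE)
  m <- og_tfbs_matrix(counts, assign)
  expect_equal(m["1a", "AP2"], 3)     # mean of 2 and 4
  expect_equal(m["2a", "AP2"], 7)     # single-gene OG
  expect_error(og_tfbs_matrix(
    data.frame(gene_id = "nope", tf_family = "AP2", count = 1), assign),
    "without an OG")
})

test_that("matrix cells equal brute-force recomputation on the synthetic
           family", {
  sim <- default_sim()
  ht <- promoter_hit_table(sim$annotation, sim$genome, sim$pwms)
  m <- og_tfbs_matrix(ht, sim$truth$og)
  lab <- setNames(sim$truth$og$og_label, sim$truth$og$gene_id)
  for (og in rownames(m)) for (fam in colnames(m)) {
    genes <- names(lab)[lab == og]
    vals <- ht$count[ht$gene_id %in% genes & ht$tf_family == fam]
    expect_equal(m[og, fam], mean(vals))
  }
})

test_that("a planted enrichment dominates its row and column", {
  sim_e <- simulate_family(default_scenario(
    enrich = list(og = "7e", tf_family = "AP2", extra = 5L)), seed = 23)
  ht <- promoter_hit_table(sim_e$annotation, sim_e$genome, sim_e$pwms)
  m <- og_tfbs_matrix(ht, sim_e$truth$og)
  expect_equal(m["7e", "AP2"], max(m))
  expect_true(all(m["7e", "AP2"] >= m[, "AP2"]))
  expect_true(all(m["7e", "AP2"] >= m["7e", ]))
})

test_that("PWMs and the TFBS matrix round-trip as text", {
  sim <- default_sim()
  f <- tempfile()
  write_pwms(sim$pwms, f)
  back <- read_pwms(f)
  expect_equal(length(back), length(sim$pwms))
  expect_equal(back[[1]]$tf_family, sim$pwms[[1]]$tf_family)
  expect_equal(back[[1]]$matrix, sim$pwms[[1]]$matrix, tolerance = 1e-6,
               ignore_attr = TRUE)
  ht <- promoter_hit_table(sim$annotation, sim$genome, sim$pwms)
  m <- og_tfbs_matrix(ht, sim$truth$og)
  fm <- tempfile()
  write_tfbs_matrix(m, fm)
  back_m <- read.delim(fm, check.names = FALSE)
  expect_equal(back_m$og_label, rownames(m))
  expect_equal(as.matrix(back_m[, -1]), m, ignore_attr = TRUE)
})
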