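# Translated-search locus mining and exon-architecture typing.

plant_genome <- function(inserts, chrom_len = 30000, seed = 501) {
  # inserts: list of list(seq, at); returns DNAStringSet with one chromosome
  set.seed(seed)
  bg <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
              collapse = "")
  for (ins in inserts)
    substr(bg, ins$at + 1L, ins$at + nchar(ins$seq)) <- ins$seq
  Biostrings::DNAStringSet(c(chr1 = bg))
}

test_that("an exact planted copy of a query is mined as one intact locus", {
  set.seed(502)
  prot <- random_aa_string(120, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  cds <- nacfam:::back_translate(prot)
  genome <- plant_genome(list(list(seq = cds, at = 5000)))
  loci <- mine_loci(genome, c(q = prot))
  expect_equal(nrow(loci), 1)
  expect_true(loci$intact[1])
  expect_lte(loci$start[1], 5000)
  expect_gte(loci$end[1], 5000 + nchar(cds) - 3)
})

test_that("a mid-sequence stop codon flags the locus internal_stop", {
  set.seed(503)
  prot <- random_aa_string(120, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  cds <- nacfam:::back_translate(prot)
  substr(cds, 3 * 60 + 1, 3 * 60 + 3) <- "TAA"
  genome <- plant_genome(list(list(seq = cds, at = 5000)))
  loci <- mine_loci(genome, c(q = prot))
  expect_equal(nrow(loci), 1)
  expect_true(loci$internal_stop[1])
  expect_false(loci$frameshift[1])
})

test_that("a single-base deletion flags the locus frameshift", {
  set.seed(504)
  prot <- random_aa_string(120, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  cds <- nacfam:::back_translate(prot)
  cds <- paste0(substr(cds, 1, 180), substr(cds, 182, nchar(cds)))
  genome <- plant_genome(list(list(seq = cds, at = 5000)))
  loci <- mine_loci(genome, c(q = prot))
  expect_equal(nrow(loci), 1)
  expect_true(loci$frameshift[1])
})

test_that("two distant planted copies come out as two loci", {
  set.seed(505)
  prot <- random_aa_string(100, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  cds <- nacfam:::back_translate(prot)
  genome <- plant_genome(list(list(seq = cds, at = 4000),
                              list(seq = cds, at = 24000)))
  loci <- mine_loci(genome, c(q = prot))
  expect_equal(nrow(loci), 2)
  expect_true(all(loci$intact))
})

test_that("short chromosomes are skipped with a warning", {
  genome <- Biostrings::DNAStringSet(c(tiny = "AT"))
  expect_warning(loci <- mine_loci(genome, c(q = "MKKLLW")), "skipped")
  expect_equal(nrow(loci), 0)
})

test_that("the mined loci of the synthetic genome equal planted genes plus
           pseudogenes, with exact lesion flags", {
  sim <- default_sim()
  loci <- mined_loci_cached()
  n_genes <- length(sim$annotation$genes)
  n_pseudo <- nrow(sim$truth$pseudogenes)
  expect_equal(nrow(loci), n_genes + n_pseudo)
  # every annotated gene is linked to exactly one intact locus
  linked <- loci[!is.na(loci$gene_id), ]
  expect_setequal(linked$gene_id, names(sim$annotation$genes))
  expect_true(all(linked$intact))
  # pseudogene remnants carry exactly the planted lesion
  ps <- loci[is.na(loci$gene_id), ]
  ps <- ps[order(ps$chromosome, ps$start), ]
  tr <- sim$truth$pseudogenes[order(sim$truth$pseudogenes$chromosome,
                                    sim$truth$pseudogenes$start), ]
  expect_equal(nrow(ps), nrow(tr))
  expect_equal(ps$internal_stop, tr$lesion == "internal_stop")
  expect_equal(ps$frameshift, tr$lesion == "frameshift")
})

basic_gene <- function(strand = "+") {
  # 3 exons, phases [1, 0]: exon1 = 10 codons + 1 nt, exon2 ends on a codon
  # boundary, exon3 carries the rest; protein length 29
  lens <- c(31L, 29L, 30L)  # 90 nt CDS = 29 aa + stop
  # mirror construction: exon 1 (31 nt) sits at the highest genomic
  # coordinates on the minus strand
  starts <- if (strand == "+") c(100L, 200L, 300L) else c(300L, 200L, 100L)
  ex <- cbind(starts, starts + lens)
  gene_model("g", "chr1", strand, ex[order(ex[, 1]), ])
}

test_that("canonical subdomain placement labels the basic structure", {
  g <- basic_gene()
  sd <- list(A = c(1, 4), B = c(6, 9), C = c(12, 15), D = c(16, 19),
             E = c(20, 24))
  call <- classify_structure(g, sd)
  expect_equal(call$label, "basic")
  expect_equal(call$intron_phases, c(1L, 0L))
  expect_equal(unname(call$subdomain_exon_map[c("A", "B", "C", "D", "E")]),
               c(1L, 1L, 2L, 2L, 3L))
})

test_that("intron phases are strand-independent", {
  sd <- list(A = c(1, 4), B = c(6, 9), C = c(12, 15), D = c(16, 19),
             E = c(20, 24))
  plus <- classify_structure(basic_gene("+"), sd)
  minus <- classify_structure(basic_gene("-"), sd)
  expect_equal(minus$intron_phases, plus$intron_phases)
  expect_equal(minus$label, plus$label)
})

test_that("two exons with subdomains A-D together label merged_1_2", {
  ex <- cbind(c(100L, 200L), c(100L + 60L, 200L + 30L))
  g <- gene_model("g", "chr1", "+", ex)
  sd <- list(A = c(0, 3), B = c(4, 7), C = c(8, 11), D = c(12, 15),
             E = c(20, 24))
  expect_equal(classify_structure(g, sd)$label, "merged_1_2")
})

test_that("extra exons wholly 3' of E label basic_plus_cterm", {
  lens <- c(31L, 29L, 24L, 9L, 9L)   # 102 nt CDS = 33 aa + stop
  starts <- c(100L, 200L, 300L, 400L, 500L)
  g <- gene_model("g", "chr1", "+", cbind(starts, starts + lens))
  sd <- list(A = c(1, 4), B = c(6, 9), C = c(12, 15), D = c(16, 19),
             E = c(20, 24))
  expect_equal(classify_structure(g, sd)$label, "basic_plus_cterm")
})

test_that("leading subdomain-free exons label extra_nterm", {
  lens <- c(9L, 31L, 29L, 30L)       # 99 nt CDS = 32 aa + stop
  starts <- c(50L, 100L, 200L, 300L)
  g <- gene_model("g", "chr1", "+", cbind(starts, starts + lens))
  sd <- list(A = c(4, 7), B = c(9, 12), C = c(15, 18), D = c(19, 22),
             E = c(23, 27))
  expect_equal(classify_structure(g, sd)$label, "extra_nterm")
})

test_that("missing subdomains or odd layouts are noncanonical, and spans
           past the stop are an error", {
  g <- basic_gene()
  expect_equal(classify_structure(g, list(A = c(1, 4), D = c(16, 19),
                                          E = c(20, 24)))$label,
               "noncanonical")
  expect_error(classify_structure(g, list(A = c(1, 4), B = c(6, 9),
                                          C = c(12, 15), D = c(16, 19),
                                          E = c(25, 40))),
               "stop")
})

test_that("structure calls on the synthetic family match planted labels", {
  sim <- default_sim()
  lab <- setNames(sim$truth$og$og_label, sim$truth$og$gene_id)
  calls <- vapply(sim$annotation$genes, function(g)
    classify_structure(g, sim$subdomain_spans[[lab[[g$gene_id]]]])$label,
    "")
  truth <- setNames(sim$truth$structure$label, sim$truth$structure$gene_id)
  expect_equal(unname(calls[names(truth)]), unname(truth))
})
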