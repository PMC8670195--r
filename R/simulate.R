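# Seeded synthetic-data generator: a toy multi-chromosome genome carrying a
# NAC-like gene family with known OG labels, canonical and variant exon
# structures, planted tandem arrays and WGD duplicate blocks, promoters
# with planted PWM sites, proteins with planted motif blocks, pseudogene
# remnants, a labelled reference database and a DE table -- all with
# exhaustive planted truth so every pipeline stage is testable offline.

# Most frequent plant codon per amino acid (back-translation).
plant_codons <- function() c(
  A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGA", H = "CAT", I = "ATT", L = "CTT", K = "AAG",
  M = "ATG", F = "TTT", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT")

back_translate <- function(protein, stop_codon = "TAA") {
  paste0(paste(plant_codons()[strsplit(protein, "")[[1]]], collapse = ""),
         stop_codon)
}

random_protein <- function(n) paste(sample(aa20(), n, replace = TRUE),
                                    collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Point-mutate a protein; motif positions (mask TRUE) mutate at motif_rate.
mutate_protein <- function(p, rate, mask = NULL, motif_rate = rate) {
  ch <- strsplit(p, "")[[1]]
  r <- rep(rate, length(ch))
  if (!is.null(mask)) r[mask] <- motif_rate
  hit <- runif(length(ch)) < r
  for (i in which(hit))
    ch[i] <- sample(setdiff(aa20(), ch[i]), 1L)
  paste(ch, collapse = "")
}

# Fixed consensus blocks for the family's ten motifs. Motifs 5/6/7 carry
# the anchored subdomain C/D consensi; motif 1 carries the DEEL
# calcium-motif-like signature of subdomain A.
family_motif_consensi <- function() c(
  "1" = "MGVDEELDPW", "2" = "SNGSRPNRAT", "3" = "EVIPHNCDLK",
  "4" = "WWHDFARPKV", "5" = "GYWKATGADQI", "6" = "GSKKTLVFYN",
  "7" = "TPWVMHEYRL", "8" = "NWVLCRIYKK", "9" = "QHFDTRSPAE",
  "10" = "KPMVDSWTEL")

# Which motifs each architecture carries.
structure_motifs <- function(structure) switch(
  structure,
  A = 1:8,
  B = c(1, 2, 3, 5, 6, 7, 8),
  C = c(1, 6, 7, 8, 9),
  D = c(6, 7, 8, 10),
  stop("unknown structure ", structure))

#' Default synthetic-family scenario
#'
#' Eight OGs of five genes on three chromosomes with one planted 2-gene
#' tandem array (60 kb), one 3-gene array (90 kb spacings), a same-OG pair
#' at 150 kb (beyond the tandem rule), two WGD block pairs, two pseudogene
#' remnants (one internal stop, one 1-bp deletion), planted promoter TFBS
#' sites for six TF families, and twelve differentially expressed genes
#' (including one genotype-contrasting gene). Within-OG protein identity
#' targets 0.8, between-OG 0.4.
#'
#' @param enrich optional list(og, tf_family, extra): plant `extra` extra
#'   promoter sites of one family in every gene of one OG.
#' @return scenario list consumed by [simulate_family()].
#' @export
default_scenario <- function(enrich = NULL) {
  og_plan <- data.frame(
    og = c("1a", "2a", "3c", "4b", "5a", "7a", "7e", "7f"),
    structure = c("A", "A", "A", "A", "A", "C", "B", "D"),
    n = 5L, stringsAsFactors = FALSE)
  layout <- list(
    chr1 = data.frame(
      gene = c("1a_1", "1a_2", "4b_1", "7a_1", "7f_1", "2a_4", "3c_5",
               "1a_3", "7a_2", "7e_4", "4b_2", "7f_2", "7a_3"),
      gap = c(30000, 60000, rep(27000, 11))),
    chr2 = data.frame(
      gene = c("2a_1", "2a_2", "2a_3", "5a_4", "7e_1", "1a_4", "3c_4",
               "4b_5", "7f_3", "2a_5", "5a_5", "7a_5", "7e_5"),
      gap = c(30000, 90000, 90000, rep(27000, 10))),
    chr3 = data.frame(
      gene = c("3c_1", "3c_2", "4b_3", "5a_1", "7f_4", "7e_2", "7a_4",
               "3c_3", "5a_2", "4b_4", "1a_5", "7f_5", "7e_3", "5a_3"),
      gap = c(30000, 150000, rep(27000, 12))))
  tf_families <- c("AP2", "Dof", "MYB", "NAC", "WRKY", "bZIP")
  de_plan <- rbind(
    data.frame(gene = c("1a_1", "1a_2", "2a_2", "7e_1"),
               comparison = "R453_PA_vs_A", status = "up"),
    data.frame(gene = "5a_1", comparison = "R453_PA_vs_A", status = "down"),
    data.frame(gene = "3c_1", comparison = "B481_PA_vs_A", status = "up"),
    data.frame(gene = "2a_1", comparison = "B481_PA_vs_A", status = "down"),
    data.frame(gene = "3c_2", comparison = "R453_PA_vs_A", status = "up"),
    data.frame(gene = "3c_2", comparison = "B481_PA_vs_A", status = "down"),
    data.frame(gene = "4b_1", comparison = "R453_vs_B481_A", status = "up"),
    data.frame(gene = "7f_1", comparison = "R453_vs_B481_A", status = "down"),
    data.frame(gene = "7a_1", comparison = "R453_vs_B481_PA", status = "up"),
    data.frame(gene = "1a_3", comparison = "R453_vs_B481_PA",
               status = "down"))
  list(og_plan = og_plan, layout = layout,
       within_identity = 0.8, between_identity = 0.4,
       tandem_pairs = list(c("1a_1", "1a_2"), c("2a_1", "2a_2", "2a_3")),
       wgd = list(
         list(side1 = "4b_1", side2 = "4b_3", width1 = 40000,
              width2 = 40000, id = "blk1"),
         list(side1 = "5a_4", side2 = "5a_3", width1 = 6000,
              width2 = 6000, id = "blk2")),
       pseudogenes = list(
         list(id = "ps1", source_og = "3c", lesion = "internal_stop",
              chromosome = "chr1", after = "3c_5", strand = "+"),
         list(id = "ps2", source_og = "3c", lesion = "frameshift",
              chromosome = "chr3", after = "4b_4", strand = "-")),
       merged_gene = "1a_5",            # the single merged-exon-1/2 gene
       cterm_extra_og = "7e",           # OG with extra C-terminal exons
       tf_families = tf_families, pwm_width = 12L,
       site_lambda = 0.8, enrich = enrich,
       promoter_len = 2000L, intron_range = c(80L, 160L),
       trr_range = c(40L, 60L), de_plan = de_plan)
}

# Build one OG founder: linkers + motif blocks + TRR; returns protein,
# per-motif residue spans (0-based half-open) and motif mask.
build_founder <- function(structure, trr_range) {
  motifs <- structure_motifs(structure)
  cons <- family_motif_consensi()
  parts <- character(0)
  spans <- vector("list", 10)
  pos <- 0L
  add <- function(s) { parts <<- c(parts, s); pos <<- pos + nchar(s) }
  add(random_protein(sample(4:6, 1)))
  for (m in motifs) {
    # inter-motif spacing varies across OGs, as in the real family
    add(random_protein(sample(4:20, 1)))
    spans[[m]] <- c(pos, pos + nchar(cons[[as.character(m)]]))
    add(cons[[as.character(m)]])
  }
  add(random_protein(sample(trr_range[1]:trr_range[2], 1)))
  protein <- paste(parts, collapse = "")
  mask <- rep(FALSE, nchar(protein))
  for (m in motifs) mask[(spans[[m]][1] + 1):spans[[m]][2]] <- TRUE
  list(protein = protein, spans = spans, mask = mask, motifs = motifs)
}

# Exon split points (nt offsets into the CDS, exclusive ends of exons 1..k-1)
# for a gene, from its subdomain spans and planned structure label.
plan_splits <- function(spans, label) {
  b_end <- if (!is.null(spans[[2]])) spans[[2]][2] else NA
  e_start <- if (!is.null(spans[[8]])) spans[[8]][1] else NA
  e_end <- if (!is.null(spans[[8]])) spans[[8]][2] else NA
  switch(label,
    basic = c(3L * b_end + 1L, 3L * e_start),
    merged_1_2 = 3L * e_start,
    basic_plus_cterm = c(3L * b_end + 1L, 3L * e_start,
                         3L * (e_end + 5L), 3L * (e_end + 15L)),
    noncanonical = c(3L * 40L, 3L * 80L))
}

# Assemble a gene's genomic forward-strand sequence from CDS + splits;
# returns sequence and exon intervals (gene-local, transcription order).
gene_sequence <- function(cds, splits, intron_range) {
  bounds <- c(0L, splits, nchar(cds))
  seqs <- character(0); exons <- NULL; pos <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    ex <- substr(cds, bounds[i] + 1L, bounds[i + 1L])
    seqs <- c(seqs, ex)
    exons <- rbind(exons, c(pos, pos + nchar(ex)))
    pos <- pos + nchar(ex)
    if (i < length(bounds) - 1L) {
      intr <- random_dna(sample(intron_range[1]:intron_range[2], 1))
      seqs <- c(seqs, intr)
      pos <- pos + nchar(intr)
    }
  }
  list(seq = paste(seqs, collapse = ""), exons = exons)
}

#' Simulate a synthetic gene family with full planted truth
#'
#' Generates, from a seeded RNG, the complete input set of the pipeline:
#' genome FASTA, gene models, labelled reference protein database, PWM
#' collection, DE table and an exhaustive truth record (OG labels, tandem
#' arrays, WGD pairs, pseudogene lesions, exon-structure labels, motif
#' content, planted promoter site counts, DE statuses). Regenerating with
#' the same seed reproduces every output byte-identically.
#'
#' @param scenario a scenario list from [default_scenario()].
#' @param seed integer seed.
#' @param dir optional output directory; when given, all artefacts are
#'   written there as plain-text files (FASTA/GFF3/TSV).
#' @return list of class `family_simulation`: `genome` (DNAStringSet),
#'   `annotation` (`genome_annotation`), `ref_db`, `pwms`, `de_table`,
#'   `blocks`, `truth`, `subdomain_spans`, `founders`, `seed`.
#' @export
simulate_family <- function(scenario = default_scenario(), seed = 17L,
                            dir = NULL) {
  if (scenario$within_identity < scenario$between_identity)
    stop("within-OG identity target below between-OG target")
  set.seed(seed)
  ogp <- scenario$og_plan
  # Mutation rates chosen so expected pairwise member identity matches the
  # within-OG target: members are independent mutants of the founder.
  r_nonmotif <- 0.15; r_motif <- 0.03
  founders <- list(); members <- list(); spans <- list()
  for (i in seq_len(nrow(ogp))) {
    og <- ogp$og[i]
    f <- build_founder(ogp$structure[i], scenario$trr_range)
    founders[[og]] <- f
    spans[[og]] <- f$spans
    members[[og]] <- vapply(seq_len(ogp$n[i]), function(k)
      mutate_protein(f$protein, r_nonmotif, f$mask, r_motif), "")
  }
  # reference DB: founder + 3 relatives per OG, cycled over 4 species
  species <- c("Atha", "Vvin", "Macu", "Osat")
  ref <- list()
  for (og in ogp$og) {
    f <- founders[[og]]
    seqs <- c(f$protein, vapply(1:3, function(k)
      mutate_protein(f$protein, 0.1, f$mask, 0.03), ""))
    ref[[og]] <- data.frame(
      protein_id = paste0(og, "_ref", 0:3),
      species = species[c(2, 1, 3, 4)],
      og_label = og, sequence = seqs, stringsAsFactors = FALSE)
  }
  ref_db <- reference_db(do.call(rbind, ref))

  # PWMs: one sharp matrix per TF family
  pw <- scenario$pwm_width
  pwms <- list(); consensi <- character(0)
  for (fam in scenario$tf_families) {
    repeat {
      cons <- random_dna(pw)
      if (!cons %in% consensi && !revcomp_chr(cons) %in% consensi) break
    }
    consensi <- c(consensi, cons)
    mat <- matrix(0.01, pw, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
    for (r in seq_len(pw)) mat[r, idx[r]] <- 0.97
    pwms[[fam]] <- nuc_pwm(fam, mat)
  }

  # per-gene structure labels
  gene_ids <- unlist(lapply(seq_len(nrow(ogp)), function(i)
    paste0(ogp$og[i], "_", seq_len(ogp$n[i]))))
  gene_og <- setNames(rep(ogp$og, ogp$n), gene_ids)
  base_label <- setNames(rep("basic", length(gene_ids)), gene_ids)
  for (og in ogp$og[ogp$structure %in% c("C", "D")])
    base_label[gene_og == og] <- "noncanonical"
  base_label[gene_og == scenario$cterm_extra_og] <- "basic_plus_cterm"
  base_label[scenario$merged_gene] <- "merged_1_2"

  # pseudogene remnant sequences (intronless copies of a founder CDS)
  pseudo <- list()
  for (ps in scenario$pseudogenes) {
    cds <- back_translate(founders[[ps$source_og]]$protein)
    if (ps$lesion == "internal_stop") {
      at <- 3L * 65L
      substr(cds, at + 1L, at + 3L) <- "TAA"
    } else {
      at <- 3L * 70L
      cds <- paste0(substr(cds, 1L, at), substr(cds, at + 2L, nchar(cds)))
    }
    pseudo[[ps$id]] <- c(ps, list(seq = cds))
  }

  # chromosome assembly
  plen <- scenario$promoter_len
  genes <- list(); chrom_seqs <- character(0)
  site_counts <- list()
  for (chrom in names(scenario$layout)) {
    lay <- scenario$layout[[chrom]]
    # insert pseudogene slots
    rows <- lapply(seq_len(nrow(lay)), function(i)
      list(id = lay$gene[i], gap = lay$gap[i], pseudo = FALSE))
    for (ps in scenario$pseudogenes) {
      if (ps$chromosome != chrom) next
      at <- which(vapply(rows, function(r) identical(r$id, ps$after),
                         logical(1)))
      rows <- append(rows, list(list(id = ps$id, gap = 27000,
                                     pseudo = TRUE)), after = at)
    }
    starts <- cumsum(vapply(rows, `[[`, 0, "gap"))
    pieces <- character(0); cursor <- 0L
    slot_strand <- ifelse(seq_along(rows) %% 2L == 1L, "+", "-")
    for (si in seq_along(rows)) {
      row <- rows[[si]]
      strand <- if (row$pseudo) pseudo[[row$id]]$strand else slot_strand[si]
      if (row$pseudo) {
        fwd <- pseudo[[row$id]]$seq
        exons <- NULL
      } else {
        og <- gene_og[[row$id]]
        k <- as.integer(sub(".*_", "", row$id))
        prot <- members[[og]][k]
        cds <- back_translate(prot)
        gs <- gene_sequence(cds, plan_splits(spans[[og]],
                                             base_label[[row$id]]),
                            scenario$intron_range)
        fwd <- gs$seq
        exons <- gs$exons
      }
      glen <- nchar(fwd)
      gstart <- starts[si]
      # promoter with planted sites (coding-strand orientation)
      prom <- random_dna(plen)
      if (!row$pseudo) {
        counts <- setNames(rpois(length(pwms), scenario$site_lambda),
                           names(pwms))
        if (!is.null(scenario$enrich) &&
            gene_og[[row$id]] == scenario$enrich$og)
          counts[scenario$enrich$tf_family] <-
            counts[scenario$enrich$tf_family] + scenario$enrich$extra
        taken <- NULL
        for (fam in names(pwms)) {
          for (s in seq_len(counts[[fam]])) {
            repeat {
              off <- sample.int(plen - pw + 1L, 1L)
              if (is.null(taken) ||
                  all(off + pw <= taken[, 1] | off > taken[, 2])) break
            }
            taken <- rbind(taken, c(off, off + pw - 1L))
            substr(prom, off, off + pw - 1L) <- consensi[[
              match(fam, scenario$tf_families)]]
          }
        }
        site_counts[[row$id]] <- counts
      }
      # fill background up to the promoter/gene region
      if (strand == "+") {
        pieces <- c(pieces, random_dna(gstart - plen - cursor), prom,
                    fwd)
        cursor <- gstart + glen
      } else {
        pieces <- c(pieces, random_dna(gstart - cursor), revcomp_chr(fwd),
                    revcomp_chr(prom))
        cursor <- gstart + glen + plen
      }
      if (!row$pseudo) {
        if (strand == "+") {
          gex <- cbind(gstart + exons[, 1], gstart + exons[, 2])
        } else {
          gex <- cbind(gstart + glen - exons[, 2],
                       gstart + glen - exons[, 1])
        }
        g <- gene_model(row$id, chrom, strand, gex)
        g$protein <- members[[gene_og[[row$id]]]][
          as.integer(sub(".*_", "", row$id))]
        genes[[row$id]] <- g
      } else {
        pseudo[[row$id]]$start <- gstart
        pseudo[[row$id]]$end <- gstart + glen
        pseudo[[row$id]]$genome_strand <- strand
      }
    }
    pieces <- c(pieces, random_dna(30000))
    chrom_seqs[[chrom]] <- paste(pieces, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  names(genome) <- names(chrom_seqs)
  annotation <- structure(
    list(chromosomes = setNames(Biostrings::width(genome), names(genome)),
         genes = genes[gene_ids]),
    class = "genome_annotation")

  # WGD blocks (coordinates known only after layout)
  gene_start <- vapply(annotation$genes, function(g) min(g$exons[, 1]), 0)
  gene_end <- vapply(annotation$genes, function(g) max(g$exons[, 2]), 0)
  gene_chrom <- vapply(annotation$genes, `[[`, "", "chromosome")
  # block sides always contain their anchor gene whole; wider blocks also
  # sweep in a different-OG bystander gene
  blocks <- do.call(rbind, lapply(scenario$wgd, function(b) data.frame(
    chrom1 = gene_chrom[[b$side1]],
    start1 = max(0, gene_start[[b$side1]] - 5000),
    end1 = max(gene_end[[b$side1]] + 3000,
               gene_start[[b$side1]] - 5000 + b$width1),
    chrom2 = gene_chrom[[b$side2]],
    start2 = max(0, gene_start[[b$side2]] - 5000),
    end2 = max(gene_end[[b$side2]] + 3000,
               gene_start[[b$side2]] - 5000 + b$width2),
    block_id = b$id, score = 0, stringsAsFactors = FALSE)))

  # DE table: planned statuses + ns noise for everything else
  de_rows <- list()
  plan_key <- paste(scenario$de_plan$gene, scenario$de_plan$comparison)
  for (gid in gene_ids) for (cmp in de_comparisons()) {
    hit <- match(paste(gid, cmp), plan_key)
    if (!is.na(hit)) {
      st <- scenario$de_plan$status[hit]
      lfc <- runif(1, 1.6, 4) * if (st == "up") 1 else -1
      p <- runif(1, 1e-5, 0.01)
    } else {
      if (runif(1) < 0.15) {          # large ratio but insignificant
        lfc <- runif(1, 1.6, 3) * sample(c(-1, 1), 1)
        p <- runif(1, 0.2, 0.9)
      } else {
        lfc <- runif(1, -1.2, 1.2)
        p <- runif(1, 0, 1)
      }
    }
    de_rows[[length(de_rows) + 1]] <- data.frame(
      gene_id = gid, comparison = cmp, log2_ratio = lfc, p_value = p,
      stringsAsFactors = FALSE)
  }
  de_table <- do.call(rbind, de_rows)

  de_truth <- de_table[, c("gene_id", "comparison")]
  de_truth$status <- "ns"
  hit <- match(paste(de_truth$gene_id, de_truth$comparison), plan_key)
  de_truth$status[!is.na(hit)] <- scenario$de_plan$status[hit[!is.na(hit)]]

  subdomain_map <- lapply(spans, function(sp) {
    pick <- function(i) if (is.null(sp[[i]])) NULL else sp[[i]]
    list(
      A = pick(1), B = pick(2),
      C = if (!is.null(sp[[3]]) && !is.null(sp[[5]]))
        c(sp[[3]][1], sp[[5]][2]) else NULL,
      D = if (!is.null(sp[[6]]) && !is.null(sp[[7]]))
        c(sp[[6]][1], sp[[7]][2]) else NULL,
      E = pick(8))
  })

  truth <- list(
    og = data.frame(gene_id = gene_ids, og_label = unname(gene_og),
                    stringsAsFactors = FALSE),
    tandem_arrays = do.call(rbind, lapply(scenario$tandem_pairs,
      function(m) data.frame(
        chromosome = gene_chrom[[m[1]]], og_label = gene_og[[m[1]]],
        members = paste(m, collapse = ","), n = length(m),
        stringsAsFactors = FALSE))),
    wgd_pairs = do.call(rbind, lapply(scenario$wgd, function(b)
      data.frame(gene_a = b$side1, gene_b = b$side2,
                 og_label = gene_og[[b$side1]], block_id = b$id,
                 stringsAsFactors = FALSE))),
    pseudogenes = do.call(rbind, lapply(pseudo, function(ps) data.frame(
      id = ps$id, chromosome = ps$chromosome, start = ps$start,
      end = ps$end, strand = ps$genome_strand, lesion = ps$lesion,
      stringsAsFactors = FALSE))),
    structure = data.frame(gene_id = gene_ids,
                           label = unname(base_label[gene_ids]),
                           stringsAsFactors = FALSE),
    motif_content = data.frame(
      gene_id = gene_ids,
      motifs = vapply(gene_ids, function(g) paste(
        founders[[gene_og[[g]]]]$motifs, collapse = ","), ""),
      stringsAsFactors = FALSE),
    promoter_sites = do.call(rbind, lapply(gene_ids, function(g)
      data.frame(gene_id = g, tf_family = names(site_counts[[g]]),
                 count = as.integer(site_counts[[g]]),
                 stringsAsFactors = FALSE))),
    de_status = de_truth)
  rownames(truth$promoter_sites) <- NULL

  out <- structure(list(genome = genome, annotation = annotation,
                        ref_db = ref_db, pwms = pwms, de_table = de_table,
                        blocks = blocks, truth = truth,
                        subdomain_spans = subdomain_map,
                        founders = lapply(founders, `[[`, "protein"),
                        seed = seed, scenario = scenario),
                   class = "family_simulation")
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

#' Write all simulation artefacts to a directory as plain text
#' @param sim a `family_simulation`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_gff3(sim$annotation, p("genes.gff3"))
  write_reference_db(sim$ref_db, p("reference_db.fa"))
  write_pwms(sim$pwms, p("pwms.txt"))
  write.table(sim$de_table, p("de_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_block_pairs(sim$blocks, p("wgd_blocks.tsv"))
  for (nm in names(sim$truth))
    write.table(sim$truth[[nm]], p(paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a protein family with one sharply divergent subfamily
#'
#' A homogeneous core (members mutated from one founder) plus a divergent
#' subfamily built from an unrelated founder carrying an extra shared
#' segment, for exercising the iterative refinement loop: the joint
#' alignment is heterogeneous and cleans poorly, the split subfamily
#' cleans well.
#'
#' @param seed integer seed.
#' @param n_core,n_div core and divergent subfamily sizes.
#' @param core_len,div_len founder lengths (aa).
#' @param rate per-residue mutation rate within each group.
#' @return list: `seqs` (named vector), `divergent` (ids of the planted
#'   subfamily).
#' @export
simulate_divergent_family <- function(seed = 1L, n_core = 12L, n_div = 8L,
                                      core_len = 120L, div_len = 160L,
                                      rate = 0.08) {
  set.seed(seed)
  core_f <- random_protein(core_len)
  div_f <- random_protein(div_len)
  seqs <- c(
    setNames(vapply(seq_len(n_core), function(i)
      mutate_protein(core_f, rate), ""), sprintf("core%02d", seq_len(n_core))),
    setNames(vapply(seq_len(n_div), function(i)
      mutate_protein(div_f, rate), ""), sprintf("div%02d", seq_len(n_div))))
  list(seqs = seqs, divergent = sprintf("div%02d", seq_len(n_div)))
}

#' Simulate sequences with one planted motif
#'
#' Random-background sequences with a fixed motif word planted at a random
#' offset in every sequence, for motif-discovery recovery tests.
#'
#' @param n_seq number of sequences.
#' @param len sequence length (aa).
#' @param motif motif word.
#' @param seed integer seed.
#' @return list: `seqs` (named vector), `offsets` (0-based planted
#'   offsets).
#' @export
simulate_motif_set <- function(n_seq = 20L, len = 60L,
                               motif = "GYWKATGKD", seed = 1L) {
  set.seed(seed)
  w <- nchar(motif)
  offs <- integer(n_seq)
  seqs <- character(n_seq)
  for (i in seq_len(n_seq)) {
    s <- random_protein(len)
    off <- sample.int(len - w + 1L, 1L)
    substr(s, off, off + w - 1L) <- motif
    seqs[i] <- s
    offs[i] <- off - 1L
  }
  names(seqs) <- sprintf("s%02d", seq_len(n_seq))
  list(seqs = seqs, offsets = offs)
}

#' Simulate a stand-alone differential-expression table
#'
#' @param n_genes total genes.
#' @param n_de number of genes planted as differential (in one random
#'   comparison each, random direction).
#' @param seed integer seed.
#' @return list: `de` (long table), `de_genes` (planted DE gene ids).
#' @export
simulate_de_table <- function(n_genes = 60L, n_de = 12L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("gene%03d", seq_len(n_genes))
  de_genes <- sort(sample(ids, n_de))
  rows <- list()
  for (gid in ids) {
    cmp_de <- if (gid %in% de_genes) sample(de_comparisons(), 1) else NA
    for (cmp in de_comparisons()) {
      if (!is.na(cmp_de) && cmp == cmp_de) {
        lfc <- runif(1, 1.6, 4) * sample(c(-1, 1), 1)
        p <- runif(1, 1e-5, 0.01)
      } else if (runif(1) < 0.15) {
        lfc <- runif(1, 1.6, 3) * sample(c(-1, 1), 1)
        p <- runif(1, 0.2, 0.9)
      } else {
        lfc <- runif(1, -1.2, 1.2)
        p <- runif(1, 0, 1)
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, comparison = cmp, log2_ratio = lfc, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  list(de = do.call(rbind, rows), de_genes = de_genes)
}
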