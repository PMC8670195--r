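# Readers/writers and the internal coordinate convention.
#
# All coordinates inside the package are 0-based half-open [start, end) on
# the chromosome forward strand; GFF3's 1-based closed convention is
# converted at the boundary in read_gff3()/write_gff3().

#' The 40 orthogroup labels of the reference classification
#'
#' Closed label set used for OG assignment: 1a-1h, 2a-2f, 3a-3e, 4a-4g,
#' 5a-5c, 6a-6c, 7a-7f, 8a, 8b.
#' @return character vector of 40 labels.
#' @export
og_label_set <- function() {
  c(paste0("1", letters[1:8]), paste0("2", letters[1:6]),
    paste0("3", letters[1:5]), paste0("4", letters[1:7]),
    paste0("5", letters[1:3]), paste0("6", letters[1:3]),
    paste0("7", letters[1:6]), paste0("8", letters[1:2]))
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chromosome chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns start, end: 0-based half-open
#'   exon intervals in genomic order (sorted, non-overlapping).
#' @param cds like `exons`, the coding part (defaults to `exons`).
#' @param protein translated protein (stop removed), or `NA`.
#' @param status `"functional"`, `"pseudogene"` or `"pseudogene-candidate"`.
#' @return list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds = exons,
                       protein = NA_character_, status = "functional") {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", gene_id)
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, cds = cds, protein = protein, status = status),
            class = "gene_model")
}

# Length in bp/aa of a plain string or an XString.
xlen <- function(x) if (is.character(x)) nchar(x) else length(x)

# Spliced CDS (coding-strand orientation) of a gene, given chromosome seq.
spliced_cds <- function(gene, chrom_seq) {
  parts <- apply(gene$cds, 1, function(iv)
    as.character(Biostrings::subseq(chrom_seq, iv[1] + 1L, iv[2])))
  cds <- paste(parts, collapse = "")
  if (gene$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

translate_cds <- function(cds) {
  if (nchar(cds) < 3L) return(NA_character_)
  n <- nchar(cds) - nchar(cds) %% 3L
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)), if.fuzzy.codon = "solve")))
  sub("\\*$", "", aa)
}

#' Read gene models from GFF3 + genome FASTA
#'
#' Parses gene/mRNA/exon/CDS features, converts coordinates to the internal
#' 0-based half-open convention, keeps one model per gene (the mRNA with
#' the longest CDS) and translates the spliced, strand-corrected CDS.
#' Genes whose CDS falls outside the chromosome are dropped with a warning;
#' a CDS whose length is not a multiple of 3, or whose translation has an
#' internal stop, marks the gene `pseudogene-candidate` instead of failing.
#'
#' @param path GFF3 file.
#' @param genome DNAStringSet or FASTA path with the chromosome sequences.
#' @return list of class `genome_annotation` with `chromosomes` (named
#'   lengths) and `genes` (named list of [gene_model()]).
#' @export
read_gff3 <- function(path, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  genes <- list()
  gene_rows <- which(typ == "gene")
  for (gi in gene_rows) {
    gid <- ids[gi]
    chrom <- as.character(GenomicRanges::seqnames(gr))[gi]
    strand <- as.character(GenomicRanges::strand(gr))[gi]
    if (!chrom %in% names(genome)) {
      warning("gene ", gid, " on unknown chromosome ", chrom, "; dropped")
      next
    }
    mrnas <- ids[typ == "mRNA" & parents == gid]
    pick <- function(feat, parent) {
      sel <- typ == feat & parents == parent
      cbind(GenomicRanges::start(gr)[sel] - 1L, GenomicRanges::end(gr)[sel])
    }
    if (length(mrnas) == 0L) mrnas <- gid  # exon/CDS parented to the gene
    cds_by_mrna <- lapply(mrnas, pick, feat = "CDS")
    cds_len <- vapply(cds_by_mrna, function(m)
      if (nrow(m)) sum(m[, 2] - m[, 1]) else 0L, numeric(1))
    best <- which.max(cds_len)
    cds <- cds_by_mrna[[best]]
    exons <- pick("exon", mrnas[best])
    if (nrow(exons) == 0L) exons <- cds
    if (nrow(cds) == 0L) {
      warning("gene ", gid, " has no CDS; dropped")
      next
    }
    clen <- xlen(genome[[chrom]])
    if (min(cds[, 1]) < 0L || max(cds[, 2]) > clen) {
      warning("gene ", gid, " CDS outside chromosome ", chrom, "; dropped")
      next
    }
    g <- gene_model(gid, chrom, strand, exons, cds)
    cds_seq <- spliced_cds(g, genome[[chrom]])
    g$protein <- translate_cds(cds_seq)
    if (nchar(cds_seq) %% 3L != 0L || grepl("\\*", g$protein))
      g$status <- "pseudogene-candidate"
    genes[[gid]] <- g
  }
  structure(list(chromosomes = setNames(Biostrings::width(genome),
                                        names(genome)),
                 genes = genes),
            class = "genome_annotation")
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()]: emits gene/mRNA/exon/CDS records (1-based
#' closed coordinates) and round-trips gene and exon coordinates exactly.
#'
#' @param ann a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in ann$genes) {
    span <- c(min(g$exons[, 1], g$cds[, 1]), max(g$exons[, 2], g$cds[, 2]))
    line <- function(type, s, e, id, parent = NULL, phase = ".") {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      paste(g$chromosome, "nacfam", type, s + 1L, e, ".", g$strand, phase,
            attrs, sep = "\t")
    }
    writeLines(line("gene", span[1], span[2], g$gene_id), con)
    mid <- paste0(g$gene_id, ".m1")
    writeLines(line("mRNA", span[1], span[2], mid, g$gene_id), con)
    for (i in seq_len(nrow(g$exons)))
      writeLines(line("exon", g$exons[i, 1], g$exons[i, 2],
                      paste0(mid, ".exon", i), mid), con)
    phases <- cds_phases(g)
    ord <- seq_len(nrow(g$cds))
    for (i in ord)
      writeLines(line("CDS", g$cds[i, 1], g$cds[i, 2],
                      paste0(mid, ".cds", i), mid,
                      phase = phases[i]), con)
  }
  invisible(path)
}

# GFF3 phase column per CDS segment (genomic order): number of bases to skip
# to reach the next codon start, accounting for strand.
cds_phases <- function(gene) {
  lens <- gene$cds[, 2] - gene$cds[, 1]
  if (gene$strand == "-") lens <- rev(lens)
  ph <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
  if (gene$strand == "-") ph <- rev(ph)
  ph
}

#' Read a labelled reference protein database from FASTA
#'
#' Headers must be `id|species|og_label`; every label must belong to the
#' closed OG label set.
#'
#' @param path FASTA file.
#' @param og_labels closed label set (default [og_label_set()]).
#' @return list of class `reference_db` with `entries` (data.frame
#'   protein_id, species, og_label, sequence) and `og_labels`.
#' @export
read_reference_db <- function(path, og_labels = og_label_set()) {
  ss <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed reference header: ", names(ss)[bad][1])
  entries <- data.frame(
    protein_id = vapply(parts, `[`, "", 1L),
    species = vapply(parts, `[`, "", 2L),
    og_label = vapply(parts, `[`, "", 3L),
    sequence = as.character(ss), stringsAsFactors = FALSE)
  reference_db(entries, og_labels)
}

#' @rdname read_reference_db
#' @param entries data.frame with columns protein_id, species, og_label,
#'   sequence.
#' @export
reference_db <- function(entries, og_labels = og_label_set()) {
  stopifnot(all(c("protein_id", "species", "og_label", "sequence") %in%
                  names(entries)),
            !anyDuplicated(entries$protein_id))
  bad <- setdiff(entries$og_label, og_labels)
  if (length(bad)) stop("og_label(s) outside the label set: ",
                        paste(bad, collapse = ", "))
  rownames(entries) <- NULL
  structure(list(entries = entries, og_labels = og_labels),
            class = "reference_db")
}

#' Write a reference database as FASTA
#' @param db a `reference_db`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path) {
  ss <- Biostrings::AAStringSet(db$entries$sequence)
  names(ss) <- paste(db$entries$protein_id, db$entries$species,
                     db$entries$og_label, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write / read phylogenetic trees in newick format
#'
#' Thin wrappers around ape's newick IO that refuse duplicate leaf names
#' before writing. Branch support values are carried as internal-node
#' labels and round-trip through [read_newick()].
#'
#' @param tree an ape `phylo` object with at least 2 leaves.
#' @param path file path.
#' @return `write_newick` returns `path` invisibly; `read_newick` returns a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2L)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
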