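# Family locus mining by translated search (tBLASTn-like: six-frame
# translation + local protein alignment, windowed for chromosome scale) and
# exon/intron architecture typing against the family's canonical 3-exon
# structure (exon 1: subdomains A+B, phase-1 intron; exon 2: C+D, phase-0
# intron; exon 3: E + the C-terminal regulatory region).

# Translate one frame of a chromosome; returns the aa string plus the
# genomic interval of aa position p (1-based): helper closure data.
frame_translation <- function(chrom_seq, strand, offset) {
  L <- xlen(chrom_seq)
  s <- if (strand == "+") chrom_seq else
    Biostrings::reverseComplement(Biostrings::DNAString(as.character(chrom_seq)))
  n_codons <- (L - offset) %/% 3L
  if (n_codons < 1L) return(NULL)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::subseq(Biostrings::DNAString(as.character(s)),
                       offset + 1L, offset + 3L * n_codons),
    if.fuzzy.codon = "solve")))
  list(aa = aa, strand = strand, offset = offset, chrom_len = L)
}

# Genomic [start, end) of aa positions p1..p2 (1-based) in a frame.
frame_to_genomic <- function(fr, p1, p2) {
  a <- fr$offset + 3L * (p1 - 1L)          # 0-based on oriented strand
  b <- fr$offset + 3L * p2
  if (fr$strand == "+") c(a, b) else c(fr$chrom_len - b, fr$chrom_len - a)
}

#' Mine family loci from a genome by translated search
#'
#' Translates all six frames of each chromosome, scans them against each
#' reference query protein with windowed local alignment, and merges hits
#' on the same chromosome and strand whose genomic gap is at most
#' `merge_gap` into loci. Each locus is then re-examined in detail to set
#' pseudogene-evidence flags: an in-frame stop inside the aligned region
#' sets `internal_stop`; two query-adjacent alignment segments in different
#' frames separated by less than `frameshift_max_gap` bp (too short to be
#' an intron) set `frameshift`. Loci overlapping an annotated gene are
#' linked to it.
#'
#' @param genome DNAStringSet (or FASTA path) of chromosomes.
#' @param queries named character vector of reference query proteins.
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum local-alignment score for a seed hit.
#' @param merge_gap maximum genomic gap (bp) merged into one locus.
#' @param annotation optional `genome_annotation` for locus-gene linking.
#' @param window,step window size and step (aa) for the chromosome scan.
#' @param frameshift_max_gap maximum genomic gap (bp) between
#'   different-frame segments still called a frameshift rather than an
#'   intron.
#' @return data.frame of loci: chromosome, strand, start, end (0-based
#'   half-open), best_query, score, n_hits, internal_stop, frameshift,
#'   intact, gene_id.
#' @export
mine_loci <- function(genome, queries, scheme = scoring_scheme(),
                      min_score = 50, merge_gap = 10000,
                      annotation = NULL, window = 400L, step = 250L,
                      frameshift_max_gap = 30L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  stopifnot(length(genome) > 0L, length(queries) > 0L,
            !is.null(names(queries)))
  hits <- list()
  for (chrom in names(genome)) {
    cseq <- genome[[chrom]]
    if (xlen(cseq) < 3L) {
      warning("chromosome ", chrom, " shorter than 3 bp; skipped")
      next
    }
    for (strand in c("+", "-")) for (off in 0:2) {
      fr <- frame_translation(cseq, strand, off)
      if (is.null(fr)) next
      m <- nchar(fr$aa)
      starts <- unique(pmin(seq(1L, max(1L, m), by = step),
                            max(1L, m - window + 1L)))
      wins <- Biostrings::AAStringSet(substring(
        fr$aa, starts, pmin(starts + window - 1L, m)))
      for (qid in names(queries)) {
        q <- Biostrings::AAString(sanitize_aa(queries[[qid]], scheme))
        sc <- Biostrings::pairwiseAlignment(
          wins, q, type = "local",
          substitutionMatrix = scheme$substitution,
          gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
          scoreOnly = TRUE)
        for (wi in which(sc >= min_score)) {
          aln <- Biostrings::pairwiseAlignment(
            wins[[wi]], q, type = "local",
            substitutionMatrix = scheme$substitution,
            gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
          p <- Biostrings::pattern(aln)
          p1 <- starts[wi] + Biostrings::start(p) - 1L
          p2 <- starts[wi] + Biostrings::end(p) - 1L
          gspan <- frame_to_genomic(fr, p1, p2)
          hits[[length(hits) + 1]] <- data.frame(
            chromosome = chrom, strand = strand, frame = off,
            start = gspan[1], end = gspan[2],
            aa_start = p1, aa_end = p2,
            query_id = qid, score = Biostrings::score(aln),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(chromosome = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0),
                      best_query = character(0), score = numeric(0),
                      n_hits = integer(0), internal_stop = logical(0),
                      frameshift = logical(0), intact = logical(0),
                      gene_id = character(0)))
  hits <- do.call(rbind, hits)
  loci <- list()
  for (key in unique(paste(hits$chromosome, hits$strand))) {
    sub <- hits[paste(hits$chromosome, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, sub$start[-1] > cummax(sub$end)[-nrow(sub)] +
                      merge_gap))
    for (g in unique(grp)) {
      loc <- sub[grp == g, , drop = FALSE]
      loci[[length(loci) + 1]] <- loc
    }
  }
  out <- lapply(loci, function(loc) {
    best <- loc[which.max(loc$score), ]
    flags <- locus_flags(genome[[best$chromosome]], best$strand,
                         c(min(loc$start), max(loc$end)),
                         queries[[best$query_id]], scheme, min_score,
                         frameshift_max_gap)
    data.frame(chromosome = best$chromosome, strand = best$strand,
               start = min(loc$start), end = max(loc$end),
               best_query = best$query_id, score = max(loc$score),
               n_hits = nrow(loc),
               internal_stop = flags$internal_stop,
               frameshift = flags$frameshift,
               intact = !flags$internal_stop && !flags$frameshift,
               gene_id = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(annotation)) {
    for (g in annotation$genes) {
      span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
      ov <- out$chromosome == g$chromosome & out$start < span[2] &
        out$end > span[1]
      out$gene_id[ov & is.na(out$gene_id)] <- g$gene_id
    }
  }
  out
}

# Detailed per-locus re-examination: iterative local alignment of the best
# query against the three frames of the locus (oriented to its strand),
# then stop/frameshift evidence from the collected segments.
locus_flags <- function(chrom_seq, strand, span, query, scheme, min_score,
                        frameshift_max_gap) {
  margin <- 60L
  L <- xlen(chrom_seq)
  s0 <- max(0L, span[1] - margin); e0 <- min(L, span[2] + margin)
  seq <- as.character(Biostrings::subseq(chrom_seq, s0 + 1L, e0))
  if (strand == "-")
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  # Alignments are confined to stop-free chunks (ORF pieces) of each frame
  # translation, so introns are never bridged; lesions are inferred from
  # how adjacent segments relate.
  segs <- list()
  thr <- max(30, min_score)   # chance hits in intron frames sit well below
  for (off in 0:2) {
    n_codons <- (nchar(seq) - off) %/% 3L
    if (n_codons < 1L) next
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, off + 1L, off + 3L * n_codons)),
      if.fuzzy.codon = "solve")))
    stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
    bounds <- c(0L, if (stops[1] > 0) stops, nchar(aa) + 1L)
    for (ci in seq_len(length(bounds) - 1L)) {
      c1 <- bounds[ci] + 1L; c2 <- bounds[ci + 1L] - 1L
      if (c2 - c1 + 1L < 10L) next
      masked <- substr(aa, c1, c2)
      repeat {
        h <- sw_align(query, masked, scheme)
        if (h$score < thr) break
        a1 <- c1 - 1L + h$subject_span[1]    # 0-based aa offsets in frame
        a2 <- c1 - 1L + h$subject_span[2]
        segs[[length(segs) + 1]] <- list(
          frame = off, chunk = paste0(off, ".", ci),
          aa_span = c(a1, a2), q_span = h$query_span,
          score = h$score, nt_span = c(off + 3L * a1, off + 3L * a2))
        substr(masked, h$subject_span[1] + 1L, h$subject_span[2]) <-
          strrep("X", h$subject_span[2] - h$subject_span[1])
      }
    }
  }
  internal_stop <- FALSE; frameshift <- FALSE
  if (length(segs) >= 2L) {
    for (i in seq_len(length(segs) - 1L)) for (j in (i + 1L):length(segs)) {
      a <- segs[[i]]; b <- segs[[j]]
      if (a$nt_span[1] > b$nt_span[1]) { tmp <- a; a <- b; b <- tmp }
      gap_nt <- b$nt_span[1] - a$nt_span[2]
      if (abs(gap_nt) > frameshift_max_gap) next
      q_overlap <- min(a$q_span[2], b$q_span[2]) -
        max(a$q_span[1], b$q_span[1])
      if (q_overlap >= 10L) next             # not query-adjacent
      if (a$frame != b$frame) frameshift <- TRUE
      else if (a$chunk != b$chunk) internal_stop <- TRUE  # stop(s) between
    }
  }
  list(internal_stop = internal_stop, frameshift = frameshift)
}

#' Classify the exon/intron architecture of a gene
#'
#' Maps protein-coordinate subdomain spans (A-E) onto exons via the CDS
#' coordinate map, computes intron phases from cumulative CDS length mod 3,
#' and assigns a structure label. The family's basic structure is 3 exons
#' with intron phases [1, 0]: exon 1 carries subdomains A and B, exon 2
#' carries C and D, exon 3 starts with E and holds the C-terminal
#' regulatory region. Variants: `merged_1_2` (2 exons, A-D together),
#' `extra_nterm` (additional leading exon(s) before the subdomains),
#' `basic_plus_cterm` (basic core plus extra exons wholly 3' of E),
#' `extra_cterm` (other extra C-terminal exons), else `noncanonical`.
#'
#' @param gene a [gene_model()].
#' @param subdomain_spans named list A..E of protein intervals
#'   `c(start, end)`, 0-based half-open; missing subdomains may be omitted
#'   or NULL.
#' @return list of class `structure_call`: gene_id, n_exons,
#'   intron_phases, subdomain_exon_map, label.
#' @export
classify_structure <- function(gene, subdomain_spans) {
  lens <- gene$cds[, 2] - gene$cds[, 1]
  if (gene$strand == "-") lens <- rev(lens)     # transcription order
  n <- length(lens)
  cum <- cumsum(lens)
  phases <- if (n > 1) as.integer(cum[-n] %% 3L) else integer(0)
  prot_len <- sum(lens) %/% 3L - 1L
  subdomain_spans <- Filter(Negate(is.null), subdomain_spans)
  map <- integer(0)
  for (sd in names(subdomain_spans)) {
    sp <- subdomain_spans[[sd]]
    if (sp[2] > prot_len)
      stop("subdomain ", sd, " span crosses the stop codon")
    nt0 <- 3L * sp[1]                            # first nt of first codon
    map[sd] <- findInterval(nt0, c(0, cum), rightmost.closed = FALSE)
  }
  label <- "noncanonical"
  if (all(c("A", "B", "C", "D", "E") %in% names(map))) {
    k <- map[["A"]]
    shifted_core <- map[["B"]] == k && map[["C"]] == k + 1L &&
      map[["D"]] == k + 1L && map[["E"]] == k + 2L
    if (n == 3L && identical(phases, c(1L, 0L)) && k == 1L && shifted_core) {
      label <- "basic"
    } else if (n == 2L && k == 1L &&
               all(map[c("A", "B", "C", "D")] == 1L) && map[["E"]] == 2L) {
      label <- "merged_1_2"
    } else if (k > 1L && shifted_core) {
      label <- "extra_nterm"
    } else if (k == 1L && shifted_core && n > 3L &&
               identical(phases[1:2], c(1L, 0L))) {
      label <- "basic_plus_cterm"
    } else if (k == 1L && shifted_core && map[["E"]] < n) {
      label <- "extra_cterm"
    }
  }
  structure(list(gene_id = gene$gene_id, n_exons = n,
                 intron_phases = phases,
                 subdomain_exon_map = map, label = label),
            class = "structure_call")
}
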