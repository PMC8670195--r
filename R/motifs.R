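# Ungapped protein motif discovery by ZOOPS EM (zero or one occurrence per
# sequence), sequential with masking, MEME-style; plus classification of
# per-protein motif content into the family's A/B/C/D architectures and
# mapping of discovered motifs onto the NAC subdomains A-E.

aa20 <- function() c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                     "F","P","S","T","W","Y","V")

seq_to_int <- function(x) {
  idx <- match(strsplit(toupper(x), "")[[1]], aa20())
  idx        # unknown/X -> NA (scores as background, excluded from counts)
}

logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }

# Initial PWM from one seed word: 0.5 on the seed letter, rest uniform.
seed_theta <- function(word, w) {
  theta <- matrix(0.5 / 19, w, 20)
  for (c in seq_len(w)) if (!is.na(word[c])) theta[c, word[c]] <- 0.5
  theta / rowSums(theta)
}

# One EM run for a fixed width from an initial PWM.
# seqs_int: list of integer vectors; returns model with objective trace.
zoops_em <- function(seqs_int, w, bg, theta0, pseudo = 0.1,
                     tol = 1e-5, maxiter = 200L) {
  nseq <- length(seqs_int)
  lens <- lengths(seqs_int)
  ms <- pmax(0L, lens - w + 1L)
  # flat matrix of every window of every sequence (rows) x motif column
  Wm <- matrix(NA_integer_, sum(ms), w)
  seq_id <- rep(seq_len(nseq), ms)
  row0 <- 0L
  for (i in seq_len(nseq)) {
    m <- ms[i]
    if (m < 1L) next
    x <- seqs_int[[i]]
    for (c in seq_len(w)) Wm[row0 + seq_len(m), c] <- x[c:(c + m - 1L)]
    row0 <- row0 + m
  }
  win_of_seq <- split(seq_len(nrow(Wm)), factor(seq_id, seq_len(nseq)))
  theta <- theta0
  gamma <- 0.5
  llr_trace <- numeric(0)
  z <- numeric(nrow(Wm)); llr <- -Inf
  prev <- -Inf
  bgrow <- matrix(bg, w, 20, byrow = TRUE)
  lbgrow <- log(bgrow)
  for (iter in seq_len(maxiter)) {
    lw <- log(theta) - lbgrow
    sc <- numeric(nrow(Wm))
    for (c in seq_len(w)) {
      v <- lw[c, Wm[, c]]
      v[is.na(v)] <- 0
      sc <- sc + v
    }
    lg <- log(gamma / ms[seq_id]) + sc
    llr <- 0
    for (i in seq_len(nseq)) {
      idx <- win_of_seq[[i]]
      if (!length(idx)) { llr <- llr + log(1 - gamma); next }
      li <- logsumexp(c(log(1 - gamma), lg[idx]))
      z[idx] <- exp(lg[idx] - li)
      llr <- llr + li
    }
    # EM objective: likelihood ratio plus the Dirichlet (pseudocount)
    # prior on the PWM rows; this is the quantity EM never decreases.
    obj <- llr + sum(pseudo * bgrow * log(theta))
    llr_trace <- c(llr_trace, obj)
    if (is.finite(prev) && obj < prev - 1e-8)
      stop("ZOOPS EM objective decreased")   # invariant guard
    converged <- is.finite(prev) && (obj - prev) < tol
    # M-step
    counts <- matrix(0, w, 20)
    for (c in seq_len(w)) {
      letters <- Wm[, c]
      ok <- !is.na(letters)
      if (!any(ok)) next
      t <- rowsum(z[ok], letters[ok])
      counts[c, as.integer(rownames(t))] <- t[, 1]
    }
    gamma <- min(1 - 1e-4, max(1e-4, sum(z) / nseq))
    theta <- counts + pseudo * bgrow
    theta <- theta / rowSums(theta)
    if (converged) break
    prev <- obj
  }
  z_list <- lapply(win_of_seq, function(idx) z[idx])
  sc_list <- lapply(win_of_seq, function(idx) sc[idx])
  list(width = w, pwm = theta, gamma = gamma, llr = llr,
       obj = llr_trace[length(llr_trace)], llr_trace = llr_trace,
       z = z_list, sc = sc_list)
}

# MEME-style column-shift refinement: re-seed the model from the current
# occurrence positions shifted by a few columns and keep the best EM
# optimum; escapes off-by-one local maxima.
shift_refine <- function(fit, seqs_int, w, bg, pseudo) {
  best <- fit
  repeat {
    improved <- FALSE
    occ_pos <- vapply(best$z, function(z)
      if (length(z) && max(z) >= 0.3) which.max(z) else NA_integer_,
      integer(1))
    for (sh in c(-2L, -1L, 1L, 2L)) {
      counts <- matrix(0, w, 20)
      n_used <- 0
      for (i in seq_along(seqs_int)) {
        p <- occ_pos[i] + sh
        if (is.na(p) || p < 1L || p + w - 1L > length(seqs_int[[i]])) next
        word <- seqs_int[[i]][p:(p + w - 1L)]
        for (c in seq_len(w))
          if (!is.na(word[c])) counts[c, word[c]] <- counts[c, word[c]] + 1
        n_used <- n_used + 1
      }
      if (n_used < 2L) next
      theta0 <- counts + 1 + matrix(bg, w, 20, byrow = TRUE)
      theta0 <- theta0 / rowSums(theta0)
      cand <- zoops_em(seqs_int, w, bg, theta0, pseudo = pseudo)
      if (cand$obj > best$obj + 1e-6) { best <- cand; improved <- TRUE }
    }
    if (!improved) break
  }
  best
}

#' Discover ungapped protein motifs by ZOOPS EM
#'
#' Sequentially fits `n` motif models: for each, ZOOPS EM (each sequence
#' carries 0 or 1 occurrence) is run over a width grid with several seeded
#' restarts; the model maximising a width-penalised log-likelihood ratio
#' (BIC-style penalty `0.5 * 19 * w * log(n_seqs)`) is kept, its
#' occurrences (posterior >= 0.5) are masked, and discovery repeats on the
#' masked sequences. Deterministic for a fixed seed; the EM objective (the
#' log-likelihood ratio plus the pseudocount prior) is asserted
#' non-decreasing at every iteration.
#'
#' @param proteins named character vector (>= 5 sequences).
#' @param n number of motifs.
#' @param wmin,wmax width bounds; the grid {6, 9, 12, 15, 20, 29, 50} is
#'   intersected with `[wmin, wmax]` and capped at the shortest sequence.
#' @param seed integer seed.
#' @param restarts EM restarts per width.
#' @param pseudo pseudocount weight added as `pseudo * background`.
#' @return list of `motif_model`: index, width, pwm (width x 20 probability
#'   matrix), background, llr, occurrences (data.frame protein_id, offset
#'   0-based, posterior), consensus.
#' @export
discover_motifs <- function(proteins, n = 10L, wmin = 6L, wmax = 20L,
                            seed = 1L, restarts = 8L, pseudo = 0.1) {
  stopifnot(length(proteins) >= 5L, !is.null(names(proteins)), n >= 0L)
  if (n == 0L) return(list())
  grid <- c(6L, 9L, 12L, 15L, 20L, 29L, 50L)
  grid <- grid[grid >= wmin & grid <= wmax]
  grid <- grid[grid <= min(nchar(proteins))]
  if (!length(grid)) stop("no admissible motif width for these sequences")
  set.seed(seed)
  all_int <- lapply(proteins, seq_to_int)
  flat <- unlist(all_int)
  bg <- (tabulate(flat[!is.na(flat)], 20) + 1) /
    (sum(!is.na(flat)) + 20)
  masked <- all_int
  models <- list()
  for (mi in seq_len(n)) {
    best <- NULL; best_sel <- -Inf
    for (w in grid) {
      eligible <- which(lengths(masked) >= w)
      if (!length(eligible)) next
      best_w <- NULL
      for (r in seq_len(restarts)) {
        si <- eligible[sample.int(length(eligible), 1L)]
        off <- sample.int(lengths(masked)[si] - w + 1L, 1L)
        word <- masked[[si]][off:(off + w - 1L)]
        fit <- zoops_em(masked, w, bg, seed_theta(word, w),
                        pseudo = pseudo)
        if (is.null(best_w) || fit$obj > best_w$obj) best_w <- fit
      }
      best_w <- shift_refine(best_w, masked, w, bg, pseudo)
      sel <- best_w$obj - 0.5 * 19 * w * log(length(masked))
      if (sel > best_sel) { best_sel <- sel; best <- best_w }
    }
    if (is.null(best)) break
    # presence needs both a confident posterior and a window that actually
    # scores like a site: at least half the model's maximum attainable
    # log-odds (same relative-threshold convention as the promoter scanner)
    occ <- list()
    lw_best <- log(best$pwm) -
      matrix(log(bg), best$width, 20, byrow = TRUE)
    sc_floor <- 0.5 * sum(apply(lw_best, 1, max))
    for (i in seq_along(masked)) {
      z <- best$z[[i]]
      if (!length(z)) next
      j <- which.max(z)
      if (z[j] >= 0.5 && best$sc[[i]][j] >= sc_floor)
        occ[[length(occ) + 1]] <- data.frame(
          protein_id = names(proteins)[i], offset = j - 1L,
          posterior = z[j], stringsAsFactors = FALSE)
    }
    occ <- if (length(occ)) do.call(rbind, occ) else
      data.frame(protein_id = character(0), offset = integer(0),
                 posterior = numeric(0))
    pwm <- best$pwm
    colnames(pwm) <- aa20()
    models[[mi]] <- structure(
      list(index = mi, width = best$width, pwm = pwm, background = bg,
           llr = best$llr, occurrences = occ,
           consensus = paste(aa20()[apply(pwm, 1, which.max)],
                             collapse = "")),
      class = "motif_model")
    # mask occurrences for the next motif
    for (k in seq_len(nrow(occ))) {
      i <- match(occ$protein_id[k], names(proteins))
      span <- occ$offset[k] + seq_len(best$width)
      masked[[i]][span] <- NA
    }
  }
  models
}

#' Mean information content of a motif (bits per column)
#' @param model a `motif_model`.
#' @return numeric scalar.
#' @export
motif_ic <- function(model) {
  bg <- matrix(model$background, model$width, 20, byrow = TRUE)
  mean(rowSums(model$pwm * (log2(model$pwm) - log2(bg))))
}

#' Classify a protein's motif content into architecture A/B/C/D
#'
#' Precedence (a declared rule): D if motif 10 is present; else C if motif
#' 9 is present; else B if motifs {1,2,3,5,6,7,8} are present and 4 is
#' absent; else A if motifs 1-8 are all present; else `other`. The
#' classifier is a pure function of the presence set.
#'
#' @param present integer vector of motif indices (1..10) present in the
#'   protein.
#' @param protein_id optional id carried through.
#' @return list of class `motif_architecture`: protein_id, present_motifs
#'   (sorted), structure.
#' @export
classify_architecture <- function(present, protein_id = NA_character_) {
  present <- sort(unique(as.integer(present)))
  stopifnot(all(present %in% 1:10))
  structure_label <-
    if (10L %in% present) "D"
    else if (9L %in% present) "C"
    else if (all(c(1L, 2L, 3L, 5L, 6L, 7L, 8L) %in% present) &&
             !(4L %in% present)) "B"
    else if (all(1:8 %in% present)) "A"
    else "other"
  structure(list(protein_id = protein_id, present_motifs = present,
                 structure = structure_label),
            class = "motif_architecture")
}

# Anchor consensus patterns for motifs 5/6/7 (subdomains C and D). Z and B
# in published logos mean Q/E and N/D; expanded here to character classes.
anchor_patterns <- function() c(
  "5" = "GYWK[AT]TG.D.{1,2}[IV]",
  "6" = "G.KK.LVFY",
  "7" = "T.W.MHEY")

expand_zb <- function(p) gsub("B", "[ND]", gsub("Z", "[QE]", p))

#' Map discovered motifs to family motif numbers and subdomains
#'
#' Models whose consensus matches one of the anchored consensus patterns
#' (G-Y-W-K-A/T-T-G-x-D-x1-2-I/V; G-x-K-K-x-L-V-F-Y; T-x-W-x-M-H-E-Y) are
#' pinned to motifs 5, 6 and 7 (subdomains C, D, D). The remaining models
#' are ordered by mean occurrence offset and numbered 1, 2, 3, 4, 8, 9, 10
#' in that order (subdomains A, B, C, C, E, C-like, TRR). When two models
#' match the same anchor the one with higher information content wins,
#' with a warning.
#'
#' @param models list of `motif_model` from [discover_motifs()].
#' @return data.frame: model (position in `models`), motif_index,
#'   subdomain, consensus.
#' @export
map_subdomains <- function(models) {
  stopifnot(length(models) >= 1L)
  cons <- vapply(models, `[[`, "", "consensus")
  subdom <- c("1" = "A", "2" = "B", "3" = "C", "4" = "C", "5" = "C",
              "6" = "D", "7" = "D", "8" = "E", "9" = "C-like", "10" = "TRR")
  assigned <- rep(NA_integer_, length(models))
  for (anum in names(anchor_patterns())) {
    pat <- expand_zb(anchor_patterns()[[anum]])
    hit <- which(grepl(pat, cons) & is.na(assigned))
    if (length(hit) > 1L) {
      ics <- vapply(models[hit], motif_ic, numeric(1))
      warning("several models match anchor for motif ", anum,
              "; keeping the most informative")
      hit <- hit[which.max(ics)]
    }
    if (length(hit) == 1L) assigned[hit] <- as.integer(anum)
  }
  rest <- which(is.na(assigned))
  mean_off <- vapply(models[rest], function(m)
    if (nrow(m$occurrences)) mean(m$occurrences$offset) else Inf, numeric(1))
  rest <- rest[order(mean_off)]
  free <- setdiff(c(1L, 2L, 3L, 4L, 8L, 9L, 10L), assigned)
  for (k in seq_along(rest)) {
    if (k > length(free)) break
    assigned[rest[k]] <- free[k]
  }
  data.frame(model = seq_along(models), motif_index = assigned,
             subdomain = unname(subdom[as.character(assigned)]),
             consensus = cons, stringsAsFactors = FALSE)
}

#' Per-protein motif architectures from discovered models
#'
#' Combines model occurrences with the motif-number mapping from
#' [map_subdomains()] and classifies each protein.
#'
#' @param models list of `motif_model`.
#' @param proteins named character vector the models were fitted on.
#' @param mapping optional result of [map_subdomains()].
#' @return data.frame protein_id, motifs (comma-separated indices),
#'   structure.
#' @export
architecture_table <- function(models, proteins, mapping = NULL) {
  if (is.null(mapping)) mapping <- map_subdomains(models)
  idx_of_model <- mapping$motif_index
  present <- lapply(names(proteins), function(pid) {
    got <- integer(0)
    for (k in seq_along(models)) {
      if (is.na(idx_of_model[k])) next
      if (pid %in% models[[k]]$occurrences$protein_id)
        got <- c(got, idx_of_model[k])
    }
    sort(unique(got))
  })
  data.frame(
    protein_id = names(proteins),
    motifs = vapply(present, paste, "", collapse = ","),
    structure = vapply(present, function(p)
      classify_architecture(p)$structure, ""),
    stringsAsFactors = FALSE)
}

#' Write / read protein motif models in a minimal MEME-like text format
#'
#' One `MOTIF <index> w=<width>` header per motif followed by `width` rows
#' of 20 tab-separated probabilities (columns in [aa20()] order), plus a
#' shared `BACKGROUND` line.
#'
#' @param models list of `motif_model`.
#' @param path file path.
#' @return `path` invisibly (writer); list of `motif_model` (reader;
#'   occurrences are not stored in the file).
#' @export
write_meme_motifs <- function(models, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("ALPHABET", paste(aa20(), collapse = "")), con)
  if (length(models))
    writeLines(paste("BACKGROUND",
                     paste(formatC(models[[1]]$background, format = "g",
                                   digits = 8), collapse = "\t")), con)
  for (m in models) {
    writeLines(sprintf("MOTIF %d w=%d", m$index, m$width), con)
    for (r in seq_len(m$width))
      writeLines(paste(formatC(m$pwm[r, ], format = "g", digits = 8),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_meme_motifs
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  bg <- rep(1 / 20, 20)
  bgl <- grep("^BACKGROUND", lines, value = TRUE)
  if (length(bgl))
    bg <- as.numeric(strsplit(sub("^BACKGROUND\\s+", "", bgl[1]),
                              "\t")[[1]])
  heads <- grep("^MOTIF ", lines)
  models <- list()
  for (h in heads) {
    parts <- strsplit(lines[h], "\\s+")[[1]]
    idx <- as.integer(parts[2])
    w <- as.integer(sub("w=", "", parts[3]))
    pwm <- do.call(rbind, lapply(lines[(h + 1):(h + w)], function(l)
      as.numeric(strsplit(l, "\t")[[1]])))
    colnames(pwm) <- aa20()
    models[[length(models) + 1]] <- structure(
      list(index = idx, width = w, pwm = pwm, background = bg,
           llr = NA_real_,
           occurrences = data.frame(protein_id = character(0),
                                    offset = integer(0),
                                    posterior = numeric(0)),
           consensus = paste(aa20()[apply(pwm, 1, which.max)],
                             collapse = "")),
      class = "motif_model")
  }
  models
}
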