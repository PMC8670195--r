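# ZOOPS EM motif discovery, architecture typing, subdomain mapping.

test_that("a 9-mer planted in every sequence is recovered exactly", {
  ms <- simulate_motif_set(seed = 11)
  mods <- discover_motifs(ms$seqs, n = 1, wmin = 6, wmax = 20, seed = 11)
  m <- mods[[1]]
  expect_equal(m$width, 9L)
  expect_equal(m$consensus, "GYWKATGKD")
  expect_equal(nrow(m$occurrences), 20L)
  planted <- ms$offsets[match(m$occurrences$protein_id, names(ms$seqs))]
  expect_equal(m$occurrences$offset, planted)
  expect_true(all(abs(rowSums(m$pwm) - 1) < 1e-9))
})

test_that("the EM objective trace is non-decreasing", {
  ms <- simulate_motif_set(seed = 21)
  ints <- lapply(ms$seqs, nacfam:::seq_to_int)
  flat <- unlist(ints)
  bg <- (tabulate(flat, 20) + 1) / (length(flat) + 20)
  set.seed(21)
  word <- ints[[1]][3:11]
  fit <- nacfam:::zoops_em(ints, 9L, bg, nacfam:::seed_theta(word, 9L))
  expect_true(all(diff(fit$llr_trace) >= -1e-8))
  expect_gt(length(fit$llr_trace), 1)
})

test_that("two disjoint planted motifs are both recovered after masking", {
  set.seed(99)
  m1 <- "GYWKATGKD"; m2 <- "LQHMPWFRV"
  seqs <- vapply(1:20, function(i) {
    s <- random_aa_string(70, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
    o1 <- sample(1:20, 1); substr(s, o1, o1 + 8) <- m1
    o2 <- sample(40:60, 1); substr(s, o2, o2 + 8) <- m2
    s
  }, "")
  names(seqs) <- paste0("p", 1:20)
  mods <- discover_motifs(seqs, n = 2, seed = 99)
  expect_setequal(vapply(mods, `[[`, "", "consensus"), c(m1, m2))
  expect_true(all(vapply(mods, function(m) nrow(m$occurrences), 0L) == 20L))
})

test_that("motifs fitted on i.i.d. random sequences are far less
           informative than planted ones", {
  planted_ic <- numeric(3); random_ic <- numeric(3)
  for (k in 1:3) {
    ms <- simulate_motif_set(seed = 30 + k)
    mp <- discover_motifs(ms$seqs, n = 1, seed = 30 + k)
    planted_ic[k] <- motif_ic(mp[[1]])
    set.seed(60 + k)
    rnd <- setNames(vapply(1:20, function(i)
      random_aa_string(60, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]), ""),
      paste0("r", 1:20))
    mr <- discover_motifs(rnd, n = 1, seed = 60 + k)
    random_ic[k] <- motif_ic(mr[[1]])
  }
  expect_true(all(random_ic < planted_ic))
  expect_gt(mean(planted_ic) - mean(random_ic), 1)  # bits/column margin
})

test_that("discovery is deterministic for a fixed seed", {
  ms <- simulate_motif_set(seed = 41)
  a <- discover_motifs(ms$seqs, n = 1, seed = 41)
  b <- discover_motifs(ms$seqs, n = 1, seed = 41)
  expect_identical(a[[1]]$pwm, b[[1]]$pwm)
  expect_identical(a[[1]]$occurrences, b[[1]]$occurrences)
})

test_that("architecture typing follows the D > C > B > A precedence", {
  expect_equal(classify_architecture(1:8)$structure, "A")
  expect_equal(classify_architecture(c(1, 2, 3, 5, 6, 7, 8))$structure, "B")
  expect_equal(classify_architecture(c(1, 6, 7, 8, 9))$structure, "C")
  expect_equal(classify_architecture(c(6, 7, 8, 10))$structure, "D")
  expect_equal(classify_architecture(c(1, 2, 3))$structure, "other")
  # precedence: 9 or 10 beat a complete 1-8 set
  expect_equal(classify_architecture(c(1:8, 9))$structure, "C")
  expect_equal(classify_architecture(c(1:9, 10))$structure, "D")
  # pure function: order and duplicates never matter
  expect_identical(classify_architecture(c(8:1, 1, 2)),
                   classify_architecture(1:8))
})

fake_model <- function(consensus, offsets, ids = paste0("p", seq_along(offsets))) {
  w <- nchar(consensus)
  pwm <- matrix(0.01 / 19, w, 20, dimnames = list(NULL, nacfam:::aa20()))
  idx <- match(strsplit(consensus, "")[[1]], nacfam:::aa20())
  for (r in seq_len(w)) pwm[r, idx[r]] <- 1 - 0.01
  pwm <- pwm / rowSums(pwm)
  structure(list(index = NA, width = w, pwm = pwm,
                 background = rep(0.05, 20), llr = 0,
                 occurrences = data.frame(protein_id = ids,
                                          offset = offsets,
                                          posterior = 1),
                 consensus = consensus), class = "motif_model")
}

test_that("anchored consensi pin motifs 5, 6 and 7; the rest are numbered
           by mean offset", {
  mods <- list(
    fake_model("GYWKATGADQI", c(60, 62)),   # subdomain C anchor -> motif 5
    fake_model("TRWIMHEY", c(100, 99)),     # subdomain D anchor -> motif 7
    fake_model("GQKKALVFY", c(80, 81)),     # subdomain D anchor -> motif 6
    fake_model("MMMMMM", c(5, 6)),          # earliest remaining -> motif 1
    fake_model("PPPPPP", c(30, 31)),        # next -> motif 2
    fake_model("HHHHHH", c(140, 141)))      # later -> motif 3
  mp <- map_subdomains(mods)
  expect_equal(mp$motif_index, c(5L, 7L, 6L, 1L, 2L, 3L))
  expect_equal(mp$subdomain, c("C", "D", "D", "A", "B", "C"))
})

test_that("two models matching one anchor keep the more informative, with
           a warning", {
  sharp <- fake_model("GYWKATGADQI", c(10, 11))
  blurry <- fake_model("GYWKTTGLDAV", c(50, 51))
  blurry$pwm <- matrix(1 / 20, nchar(blurry$consensus), 20,
                       dimnames = list(NULL, nacfam:::aa20()))
  blurry$pwm[cbind(1:11, match(strsplit("GYWKTTGLDAV", "")[[1]],
                               nacfam:::aa20()))] <- 0.3
  blurry$pwm <- blurry$pwm / rowSums(blurry$pwm)
  expect_warning(mp <- map_subdomains(list(sharp, blurry)), "anchor")
  expect_equal(mp$motif_index[1], 5L)
})

test_that("Z/B ambiguity letters expand to Q/E and N/D in patterns", {
  expect_equal(nacfam:::expand_zb("GZKKBLVFY"), "G[QE]KK[ND]LVFY")
  m <- fake_model("GEKKNLVFY", c(1, 2))
  expect_true(grepl(nacfam:::expand_zb("G[QE]KK[ND]LVFY"), m$consensus))
})

test_that("motif models round-trip through the MEME-like text format", {
  ms <- simulate_motif_set(seed = 51)
  mods <- discover_motifs(ms$seqs, n = 1, seed = 51)
  f <- tempfile()
  write_meme_motifs(mods, f)
  back <- read_meme_motifs(f)
  expect_equal(back[[1]]$width, mods[[1]]$width)
  expect_equal(back[[1]]$consensus, mods[[1]]$consensus)
  expect_equal(back[[1]]$pwm, mods[[1]]$pwm, tolerance = 1e-6)
})
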