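# brute-force IUPAC matcher used as the independent oracle
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))
brute_scan <- function(seq, motif) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  L <- length(m)
  hits <- integer(0)
  for (i in seq_len(max(0, length(s) - L + 1))) {
    ok <- TRUE
    for (j in seq_len(L))
      if (!(s[i + j - 1] %in% iupac_sets[[m[j]]])) { ok <- FALSE; break }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

test_that("IUPAC scanning reports all overlapping sense-strand matches", {
  h <- scan_iupac("GGAATAAAC", "AATAAA")
  expect_identical(h$start, 2L)
  expect_identical(h$text, "AATAAA")
  h2 <- scan_iupac("ACCATT", "YCAY")
  expect_identical(h2$start, 1L)
  expect_identical(h2$text, "CCAT")
  expect_identical(nrow(scan_iupac("AAAA", "YCAY")), 0L)
  # RNA spelling scans as DNA
  expect_identical(scan_iupac("GGAATAAAC", "AAUAAA")$start, 2L)
  expect_error(scan_iupac("ACGT", "AZT"), "IUPAC")
  # overlapping matches are all reported
  expect_identical(scan_iupac("ATATATA", "ATA")$start, c(0L, 2L, 4L))
  # antisense hits map back to reference coordinates
  anti <- scan_iupac("GTTTATTCC", "AATAAA", antisense = TRUE)
  expect_identical(anti$start, 1L)
  expect_identical(anti$strand, "antisense")
  expect_identical(substr("GTTTATTCC", 2, 7), "TTTATT")  # revcomp of motif
})

test_that("IUPAC scanning agrees with a brute-force oracle on random sequence", {
  set.seed(14)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  for (motif in c("YCAY", "CTCTCT", "TCTTC", "AATAAA", "RNYK")) {
    expect_identical(scan_iupac(seq, motif)$start, brute_scan(seq, motif),
                     info = motif)
  }
})

test_that("G runs are maximal and at least the minimum length", {
  feature_b <- "GCAAAGGGATCCAGCTCTCCCTGGGGGCCTTCGTGACAC"
  h <- find_g_runs(feature_b)
  expect_identical(nrow(h), 2L)
  expect_identical(h$start, c(5L, 22L))
  expect_identical(h$length, c(3L, 5L))
  h2 <- find_g_runs("GGGGGG")
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$length, 6L)
  expect_identical(nrow(find_g_runs("GGAGG")), 0L)
})

test_that("tandem repeats are maximal perfect runs with enough units", {
  h <- find_tandem_repeats("TCACACAG", "CA", 3)
  expect_identical(h$start, 1L)
  expect_identical(h$n_units, 3L)
  expect_identical(nrow(find_tandem_repeats("CACA", "CA", 3)), 0L)
  pl <- plant_motifs(500, data.frame(text = strrep("CA", 8), start = 200),
                     seed = 15)
  h2 <- find_tandem_repeats(pl$seq, "CA", 3)
  big <- h2[h2$n_units >= 8, ]
  expect_identical(nrow(big), 1L)
  expect_identical(big$start, 200L)
  expect_identical(big$n_units, 8L)
})

cols_from_strings <- function(ref, mouse, rat) {
  data.frame(pos = seq_len(nchar(ref)) - 1L,
             ref = strsplit(ref, "")[[1]],
             mouse = strsplit(mouse, "")[[1]],
             rat = strsplit(rat, "")[[1]],
             stringsAsFactors = FALSE)
}

test_that("conserved hits require a full-length match in every species", {
  cols <- cols_from_strings("ACTCTCTG", "ACTCTCTG", "ACTCTCTG")
  h <- conserved_hits(cols, "CUCUCU")
  expect_identical(h$start, 1L)
  expect_true(h$conserved)
  expect_identical(h$n_species, 3L)
  # a substitution in rat breaks conservation
  h2 <- conserved_hits(cols_from_strings("ACTCTCTG", "ACTCTCTG", "ACTATCTG"),
                       "CUCUCU")
  expect_false(h2$conserved)
  expect_identical(h2$n_species, 2L)
  # a gap inside the window breaks conservation
  h3 <- conserved_hits(cols_from_strings("ACTCTCTG", "ACT-TCTG", "ACTCTCTG"),
                       "CUCUCU")
  expect_false(h3$conserved)
})

test_that("conserved hits are a subset of reference hits", {
  sim <- simulate_codes(600, 2, c(0.7, 0.3),
                        rbind(c(60, 3, 1), c(10, 30, 5)), 0.02, seed = 16)
  cols <- emit_alignment(sim$codes, seed = 16)
  for (motif in c("YCAY", "g_triplet", "ca_repeat")) {
    ch <- conserved_hits(cols, motif)
    refseq <- paste(cols$ref, collapse = "")
    ref_hits <- switch(motif,
                       YCAY = scan_iupac(refseq, "YCAY"),
                       g_triplet = find_g_runs(refseq),
                       ca_repeat = find_tandem_repeats(refseq))
    expect_identical(ch$start, ref_hits$start, info = motif)
    expect_true(all(ch$start[ch$conserved] %in% ref_hits$start))
  }
})

test_that("phosphorylation patterns match the reported peptides", {
  expect_identical(scan_protein_pattern("TSLD", "CKII")$start, 0L)
  ck <- scan_protein_pattern("STKE", "CKII")
  expect_identical(ck$start, 0L)
  pk <- scan_protein_pattern("STKE", "PKC")
  expect_identical(pk$start, 0L)          # 'STK' via [ST]X[RK]
  expect_identical(ck$acceptor_pos, pk$acceptor_pos)  # same acceptor S
  ca <- scan_protein_pattern("KRLT", "cAMP_cGMP")
  expect_identical(ca$start, 0L)
  expect_identical(ca$acceptor_pos, 3L)   # the T is the acceptor
  for (p in names(protein_patterns()))
    expect_identical(nrow(scan_protein_pattern("AAAA", p)), 0L, info = p)
  expect_error(scan_protein_pattern("ABXJ", "CKII"), "residue")
  # overlapping protein matches are all reported
  expect_identical(scan_protein_pattern("SSKRSSKR", "PKC")$start,
                   c(0L, 1L, 4L, 5L))
})

test_that("flank annotation classifies the N-terminal residue and +5", {
  seq <- "AESKQE"
  hit <- scan_protein_pattern(seq, "CKII")   # SKQE at 2
  expect_identical(hit$start, 2L)
  fl <- annotate_flanks(seq, hit[1, ])
  expect_identical(fl$n_terminal, "E")
  expect_identical(fl$n_terminal_class, "acidic")
  seq2 <- "AKSVSEQAW"
  fl2 <- annotate_flanks(seq2, scan_protein_pattern(seq2, "CKII")[1, ])
  expect_identical(fl2$n_terminal, "K")
  expect_identical(fl2$n_terminal_class, "basic")
  expect_identical(fl2$plus5, "A")         # +5 from the acceptor S
  # +5 beyond the sequence end is absent
  fl2b <- annotate_flanks("AKSVSEQ",
                          scan_protein_pattern("AKSVSEQ", "CKII")[1, ])
  expect_true(is.na(fl2b$plus5))
  seq3 <- "TSLDAAAA"
  fl3 <- annotate_flanks(seq3, scan_protein_pattern(seq3, "CKII")[1, ])
  expect_identical(fl3$n_terminal_class, "absent")
})

test_that("planted motifs are recovered and chance hits match theory", {
  pl <- plant_motifs(1000, data.frame(text = "AATAAA", start = 100), seed = 17)
  h <- scan_iupac(pl$seq, "AATAAA")
  expect_true(100L %in% h$start)
  # with nothing planted, hit counts match the analytic per-window rate
  total <- 0L
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    bg <- plant_motifs(1000, data.frame(text = character(0),
                                        start = integer(0)), seed = 1000 + r)
    total <- total + nrow(scan_iupac(bg$seq, "AATAAA"))
  }
  expected <- n_rep * (1000 - 6 + 1) * (1 / 4)^6
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("hit density counts window starts", {
  hits <- data.frame(start = c(0L, 10L, 60L))
  d <- hit_density(hits, seq_length = 120, window = 50)
  expect_identical(d$count[1], 2L)          # starts 0 and 10
  expect_identical(d$count[d$start == 60], 1L)
})
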