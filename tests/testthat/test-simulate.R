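test_that("the generator is deterministic under seed", {
  a <- simulate_codes(500, 2, c(0.5, 0.5),
                      rbind(c(10, 5, 1), c(1, 5, 10)), 0.01, seed = 19)
  b <- simulate_codes(500, 2, c(0.5, 0.5),
                      rbind(c(10, 5, 1), c(1, 5, 10)), 0.01, seed = 19)
  expect_identical(as.integer(a$codes), as.integer(b$codes))
  expect_identical(a$changepoints, b$changepoints)
  expect_identical(a$labels, b$labels)
  c2 <- emit_alignment(a$codes, seed = 19)
  d2 <- emit_alignment(a$codes, seed = 19)
  expect_identical(c2, d2)
})

test_that("degenerate parameters behave as stated", {
  s <- simulate_codes(300, 4, c(1, 0, 0, 0),
                      matrix(10, 4, 3), 0.02, seed = 20)
  expect_true(all(s$labels == 1L))
  s2 <- simulate_codes(2000, 1, 1, rbind(c(1e6, 1, 1)), 0.01, seed = 20)
  expect_gt(mean(as.integer(s2$codes) == 0L), 0.99)
  expect_error(simulate_codes(100, 2, c(0.6, 0.6),
                              rbind(c(1, 1, 1), c(1, 1, 1)), 0.01),
               "simplex")
  expect_error(simulate_codes(100, 1, 1, rbind(c(-1, 1, 1)), 0.01),
               "positive")
  expect_error(simulate_codes(100, 1, 1, rbind(c(1, 1, 1)), 1.5), "rho")
})

test_that("changepoint counts follow the Bernoulli boundary rate", {
  s <- simulate_codes(20000, 1, 1, rbind(c(5, 3, 2)), 0.005, seed = 21)
  n <- length(s$changepoints)
  expect_lt(abs(n - 19999 * 0.005), 3 * sqrt(19999 * 0.005 * 0.995))
  # segments tile the sequence
  expect_identical(s$position_labels, rep(s$labels,
    diff(c(0L, s$changepoints, 20000L))))
})

test_that("emitted code frequencies match the Dirichlet mean", {
  al <- c(60, 30, 10)
  s <- simulate_codes(10000, 1, 1, rbind(al * 100), 0.02, seed = 22)
  freq <- tabulate(as.integer(s$codes) + 1L, 3) / 10000
  p <- al / sum(al)
  for (c in 1:3)
    expect_lt(abs(freq[c] - p[c]), 3 * sqrt(p[c] * (1 - p[c]) / 10000) + 0.01)
})

test_that("emitted alignments re-encode to the input codes", {
  for (sd in c(23, 24)) {
    s <- simulate_codes(400, 2, c(0.5, 0.5),
                        rbind(c(30, 5, 2), c(5, 20, 10)), 0.02, seed = sd)
    cols <- emit_alignment(s$codes, seed = sd)
    expect_identical(as.integer(encode_region(cols)), as.integer(s$codes))
  }
  # constrained pattern mix realizes the requested signature
  s <- simulate_codes(300, 1, 1, rbind(c(1, 50, 1)), 0.02, seed = 25)
  cols <- emit_alignment(s$codes, pattern_mix = list(`1` = c(ABB = 1)),
                         seed = 25)
  i <- which(as.integer(s$codes) == 1L)
  expect_true(all(cols$mouse[i] == cols$rat[i]))
  expect_true(all(cols$mouse[i] != cols$ref[i]))
  expect_error(emit_alignment(s$codes, pattern_mix = list(`1` = c(AAA = 1))),
               "incompatible")
})

test_that("coding annotation equals the maximal runs of the coding class", {
  truth <- list(position_labels = c(1L, 1L, 2L, 2L, 2L, 1L))
  iv <- annotate_coding(truth, 2L)
  expect_identical(iv$start, 2L)
  expect_identical(iv$end, 5L)
  expect_identical(nrow(annotate_coding(list(position_labels = rep(1L, 5)),
                                        2L)), 0L)
  s <- simulate_codes(2000, 3, c(0.3, 0.4, 0.3),
                      matrix(c(50, 5, 1, 5, 50, 1, 1, 5, 50), 3, 3,
                             byrow = TRUE), 0.01, seed = 26)
  iv2 <- annotate_coding(s, 2L)
  mask <- logical(2000)
  for (i in seq_len(nrow(iv2))) mask[(iv2$start[i] + 1):iv2$end[i]] <- TRUE
  expect_identical(mask, s$position_labels == 2L)
})

test_that("motif planting validates positions and records ground truth", {
  expect_error(plant_motifs(100, data.frame(text = "AAAA", start = 98)),
               "outside")
  expect_error(plant_motifs(100, data.frame(text = c("AAAA", "CCCC"),
                                            start = c(10, 12))),
               "overlap")
  pl <- plant_motifs(100, data.frame(text = "TTTT", start = 10), seed = 27)
  expect_identical(substr(pl$seq, 11, 14), "TTTT")
  expect_identical(pl$planted$end, 14)
})

test_that("the bundled scenarios compose into consistent truth objects", {
  sc <- gfap_scenario()
  expect_equal(sum(sc$pi), 1)
  expect_identical(dim(sc$alphas), c(4L, 3L))
  s <- simulate_alignment(scenario = list(length = 1500L, k = 4L,
                                          pi = sc$pi, alphas = sc$alphas,
                                          rho = sc$rho, coding_class = 2L,
                                          pattern_mix = sc$pattern_mix),
                          seed = 28, emit_columns = TRUE)
  expect_identical(as.integer(encode_region(s$columns)),
                   as.integer(s$codes))
  mask <- logical(1500)
  for (i in seq_len(nrow(s$coding)))
    mask[(s$coding$start[i] + 1):s$coding$end[i]] <- TRUE
  expect_identical(mask, s$position_labels == 2L)
})
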