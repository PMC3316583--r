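test_that("conservation codes count distinct symbols, gaps included", {
  expect_identical(encode_column(c("A", "A", "A")), 0L)
  expect_identical(encode_column(c("A", "A", "G")), 1L)
  expect_identical(encode_column(c("A", "C", "G")), 2L)
  expect_identical(encode_column(c("A", "-", "A")), 1L)
  expect_identical(encode_column(c("A", "-", "G")), 2L)
  expect_identical(encode_column(c("A", "-", "-")), 1L)
  expect_identical(encode_column(c("a", "a", "g")), 1L)  # soft-masked
  expect_error(encode_column(c("-", "A", "A")), "gap")
  expect_error(encode_column(c("A", "Q", "A")), "invalid")
})

test_that("column patterns are canonical, gaps literal", {
  expect_identical(classify_pattern(c("A", "A", "G")), "AAB")
  expect_identical(classify_pattern(c("A", "C", "T")), "ABC")
  expect_identical(classify_pattern(c("C", "-", "-")), "A--")
  expect_identical(classify_pattern(c("G", "-", "G")), "A-A")
  expect_identical(classify_pattern(c("T", "T", "T")), "AAA")
  expect_length(pattern_labels(), 10L)
})

test_that("pattern and code agree: code = distinct symbols in label - 1", {
  set.seed(42)
  for (i in 1:200) {
    chars <- c(sample(c("A", "C", "G", "T"), 1),
               sample(c("A", "C", "G", "T", "-"), 2, replace = TRUE))
    lab <- classify_pattern(chars)
    expect_identical(encode_column(chars),
                     length(unique(strsplit(lab, "")[[1]])) - 1L)
  }
})

test_that("permuting non-reference species permutes the label, not the code", {
  set.seed(7)
  for (i in 1:100) {
    chars <- c(sample(c("A", "C", "G", "T"), 1),
               sample(c("A", "C", "G", "T", "-"), 2, replace = TRUE))
    sw <- chars[c(1, 3, 2)]
    expect_identical(encode_column(chars), encode_column(sw))
    map <- c(AAA = "AAA", AAB = "ABA", ABA = "AAB", ABB = "ABB",
             ABC = "ABC", `AA-` = "A-A", `A-A` = "AA-", `AB-` = "A-B",
             `A-B` = "AB-", `A--` = "A--")
    expect_identical(classify_pattern(sw),
                     unname(map[classify_pattern(chars)]))
  }
})

test_that("encode_region vectorizes encode_column and keeps the region", {
  cols <- data.frame(pos = 10:12, ref = c("A", "C", "G"),
                     mouse = c("A", "-", "G"), rat = c("A", "C", "T"),
                     stringsAsFactors = FALSE)
  attr(cols, "chrom") <- "chrTest"
  cs <- encode_region(cols)
  expect_identical(as.integer(cs), c(0L, 1L, 1L))
  expect_identical(attr(cs, "chrom"), "chrTest")
  expect_identical(attr(cs, "start"), 10L)
  # per-column agreement
  for (i in 1:3)
    expect_identical(as.integer(cs)[i],
                     encode_column(unlist(cols[i, -1], use.names = FALSE)))
  # empty and non-contiguous input
  expect_length(as.integer(encode_region(cols[0, ])), 0L)
  gap <- cols; gap$pos <- c(10L, 12L, 13L)
  expect_error(encode_region(gap), "contiguous")
})

test_that("'N' bases are a distinct symbol and are reported", {
  cols <- data.frame(pos = 0:1, ref = c("A", "N"),
                     mouse = c("N", "N"), rat = c("A", "N"),
                     stringsAsFactors = FALSE)
  expect_warning(cs <- encode_region(cols), "'N'")
  expect_identical(as.integer(cs), c(1L, 0L))
})

maf_text <- function(lines) {
  path <- tempfile(fileext = ".maf")
  writeLines(lines, path)
  path
}

test_that("MAF projection drops reference-gap columns and fills absent species", {
  p <- maf_text(c(
    "##maf version=1",
    "a score=1",
    "s hg19.chr17 100 3 + 1000 ACG",
    "s mm9.chr11  5   2 + 900  A-G",
    "s rn4.chr10  7   3 + 800  ACG",
    "",
    "a score=2",                       # human row has a gap; rat absent
    "s hg19.chr17 103 3 + 1000 AC-G",
    "s mm9.chr11  7   4 + 900  ACTG",
    ""))
  cols <- read_maf(p, c("hg19", "mm9", "rn4"))
  expect_identical(nrow(cols), 6L)
  expect_identical(cols$pos, 100:105)
  expect_identical(cols$ref, c("A", "C", "G", "A", "C", "G"))
  expect_identical(cols$mm9, c("A", "-", "G", "A", "C", "G"))
  expect_identical(cols$rn4, c("A", "C", "G", "-", "-", "-"))
  expect_identical(attr(cols, "chrom"), "chr17")
})

test_that("MAF errors name missing reference and unsorted blocks", {
  p1 <- maf_text(c("a", "s mm9.chr11 0 2 + 10 AC", ""))
  expect_error(read_maf(p1, c("hg19", "mm9")), "block 1")
  p2 <- maf_text(c("a", "s hg19.chr1 50 2 + 100 AC", "s mm9.chr1 0 2 + 10 AC",
                   "", "a", "s hg19.chr1 10 2 + 100 GT", ""))
  expect_error(read_maf(p2, c("hg19", "mm9")), "sorted")
})

test_that("synthetic alignments round-trip through MAF and re-encode exactly", {
  sim <- simulate_codes(400, 2, c(0.6, 0.4),
                        rbind(c(50, 4, 1), c(10, 30, 5)), 0.02, seed = 5)
  cols <- emit_alignment(sim$codes, seed = 9)
  expect_identical(as.integer(encode_region(cols)), as.integer(sim$codes))
  p <- tempfile(fileext = ".maf")
  write_maf(cols, p)
  back <- read_maf(p, c("ref", "mouse", "rat"))
  expect_identical(back$ref, cols$ref)
  expect_identical(back$mouse, cols$mouse)
  expect_identical(back$rat, cols$rat)
  expect_identical(as.integer(encode_region(back)), as.integer(sim$codes))
})
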