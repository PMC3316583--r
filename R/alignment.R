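# Reference-anchored alignment columns, conservation codes and column
# patterns.
#
# An alignment-column table is a data.frame with one row per reference
# base: `pos` (0-based reference coordinate), `ref` (reference base,
# never "-") and one character column per non-reference species ("-"
# where that species is gapped or unaligned).  Attribute "chrom" carries
# the reference chromosome.  The reference species is always first.

#' Conservation-code sequence
#'
#' A `code_seq` is an integer vector of per-column conservation codes
#' with genomic-region metadata.  A code is the number of distinct
#' symbols in the alignment column (gaps count as a symbol) minus one,
#' so for a 3-species alignment codes are 0 (all identical), 1 (two
#' distinct symbols) or 2 (three distinct symbols).
#'
#' @param codes integer vector of codes, each in `0:(n_species - 1)`.
#' @param chrom reference chromosome name.
#' @param start 0-based reference coordinate of the first code.
#' @param strand strand of the reference region, `"+"` or `"-"`.
#' @return An integer vector of class `code_seq` with attributes
#'   `chrom`, `start` and `strand`.  Its region is
#'   `[start, start + length)` in 0-based half-open coordinates.
#' @seealso [encode_region()], [conseg()]
#' @export
code_seq <- function(codes, chrom = "synthetic", start = 0L, strand = "+") {
  codes <- as.integer(codes)
  if (any(is.na(codes)) || any(codes < 0L))
    stop("codes must be non-negative integers")
  structure(codes, chrom = chrom, start = as.integer(start),
            strand = strand, class = "code_seq")
}

#' @export
print.code_seq <- function(x, ...) {
  cat(sprintf("<code_seq> %s:%d-%d (%s), %d positions\n",
              attr(x, "chrom"), attr(x, "start"),
              attr(x, "start") + length(x), attr(x, "strand"), length(x)))
  tab <- table(factor(unclass(x), levels = 0:max(2, max(unclass(x)))))
  cat("code counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
`[.code_seq` <- function(x, i, ...) {
  out <- unclass(x)[i]
  attributes(out) <- NULL
  out
}

.norm_base <- function(x) {
  # soft-masked lowercase is treated as its uppercase base
  x <- toupper(x)
  n_amb <- sum(x == "N")
  if (n_amb > 0)
    warning(sprintf("%d 'N' base(s) treated as a distinct symbol", n_amb),
            call. = FALSE)
  x
}

.check_column_chars <- function(chars) {
  bad <- !(chars %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad))
    stop("invalid alignment character(s): ",
         paste(unique(chars[bad]), collapse = " "))
}

#' Encode one alignment column as a conservation code
#'
#' The code is the number of distinct symbols in the column minus one.
#' Gaps (`"-"`) count as an extra character, i.e. a single change, and
#' runs of gaps are scored column by column, never compressed.  `N` is
#' treated as a distinct symbol (with a warning); lowercase
#' (soft-masked) bases are uppercased first.
#'
#' @param chars character vector of aligned characters for one column,
#'   reference first.  The reference character must not be a gap.
#' @return Integer code in `0:(length(chars) - 1)`.
#' @examples
#' encode_column(c("A", "A", "A"))  # 0
#' encode_column(c("A", "A", "G"))  # 1
#' encode_column(c("A", "-", "G"))  # 2: gap is an extra character
#' @export
encode_column <- function(chars) {
  chars <- .norm_base(as.character(chars))
  .check_column_chars(chars)
  if (chars[1] == "-") stop("reference character must not be a gap")
  length(unique(chars)) - 1L
}

#' Classify one alignment column by its match/mismatch/gap pattern
#'
#' Assigns the canonical pattern label: `A` is the reference base,
#' subsequent novel bases become `B`, `C`, ... in species order, and
#' gaps appear literally as `-`.  For three species there are exactly
#' 10 admissible labels: `AAA`, `AAB`, `ABA`, `ABB`, `ABC`, `AA-`,
#' `A-A`, `AB-`, `A-B`, `A--`.
#'
#' @inheritParams encode_column
#' @return A single pattern string.
#' @examples
#' classify_pattern(c("A", "A", "G"))  # "AAB"
#' classify_pattern(c("G", "-", "G"))  # "A-A"
#' @export
classify_pattern <- function(chars) {
  chars <- .norm_base(as.character(chars))
  .check_column_chars(chars)
  if (chars[1] == "-") stop("reference character must not be a gap")
  seen <- character(0)
  lab <- character(length(chars))
  for (i in seq_along(chars)) {
    if (chars[i] == "-") {
      lab[i] <- "-"
    } else {
      j <- match(chars[i], seen)
      if (is.na(j)) {
        seen <- c(seen, chars[i])
        j <- length(seen)
      }
      lab[i] <- LETTERS[j]
    }
  }
  paste(lab, collapse = "")
}

#' The 10 admissible 3-species column patterns
#'
#' @return Character vector of the canonical pattern labels, gapless
#'   patterns first.
#' @export
pattern_labels <- function() {
  c("AAA", "AAB", "ABA", "ABB", "ABC", "AA-", "A-A", "AB-", "A-B", "A--")
}

# vectorized code + pattern computation over a column table
.columns_matrix <- function(columns) {
  sp <- setdiff(names(columns), "pos")
  m <- do.call(cbind, lapply(columns[sp], as.character))
  m <- toupper(m)
  .check_column_chars(as.vector(m))
  if (any(m[, 1] == "-")) stop("reference character must not be a gap")
  m
}

.encode_matrix <- function(m) {
  # distinct-symbol count per row, minus one
  code <- integer(nrow(m))
  for (j in 2:ncol(m)) {
    novel <- rep(TRUE, nrow(m))
    for (i in seq_len(j - 1)) novel <- novel & (m[, j] != m[, i])
    code <- code + as.integer(novel)
  }
  code
}

.classify_matrix <- function(m) {
  if (ncol(m) == 3L) {
    r <- m[, 1]; o1 <- m[, 2]; o2 <- m[, 3]
    l2 <- ifelse(o1 == "-", "-", ifelse(o1 == r, "A", "B"))
    l3 <- ifelse(o2 == "-", "-",
          ifelse(o2 == r, "A",
          ifelse(l2 == "B" & o2 == o1, "B",
          ifelse(l2 == "B", "C", "B"))))
    paste0("A", l2, l3)
  } else {
    apply(m, 1, function(ch) classify_pattern(ch))
  }
}

#' Encode an alignment-column table as a conservation-code sequence
#'
#' Vectorized form of [encode_column()] over a reference-anchored
#' column table such as produced by [read_maf()] or
#' [emit_alignment()].  The table must cover a contiguous reference
#' region.
#'
#' @param columns alignment-column table: data.frame with `pos`
#'   (0-based reference coordinate), `ref`, and one character column
#'   per other species.
#' @return A [code_seq()] spanning the table's reference region.
#' @export
encode_region <- function(columns) {
  chrom <- attr(columns, "chrom")
  if (is.null(chrom)) chrom <- "unknown"
  if (nrow(columns) == 0L)
    return(code_seq(integer(0), chrom = chrom, start = 0L))
  if (is.unsorted(columns$pos, strictly = TRUE))
    stop("column positions must be strictly increasing")
  if (any(diff(columns$pos) != 1L))
    stop("alignment does not cover a contiguous reference region; ",
         "uncovered positions after coordinate(s) ",
         paste(head(columns$pos[which(diff(columns$pos) != 1L)], 3),
               collapse = ", "))
  m <- .columns_matrix(columns)
  n_amb <- sum(m == "N")
  if (n_amb > 0)
    warning(sprintf("%d 'N' base(s) treated as a distinct symbol", n_amb),
            call. = FALSE)
  code_seq(.encode_matrix(m), chrom = chrom, start = columns$pos[1])
}

#' Classify every column of an alignment-column table
#'
#' Vectorized form of [classify_pattern()].
#'
#' @inheritParams encode_region
#' @return Character vector of pattern labels, one per column.
#' @export
classify_patterns <- function(columns) {
  if (nrow(columns) == 0L) return(character(0))
  m <- .columns_matrix(columns)
  .classify_matrix(m)
}
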