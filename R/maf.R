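# MAF (multiz dialect) input and a minimal writer for synthetic
# alignments.  No installed package parses MAF, so the parser is native.

.maf_src_species <- function(src) sub("\\..*$", "", src)

#' Read a MAF alignment and project it onto the reference species
#'
#' Parses a UCSC multiz-style MAF file, restricts each block to the
#' requested species, and projects the alignment onto the reference
#' (first listed) species: columns where the reference has a gap are
#' dropped, so the result has exactly one row per aligned reference
#' base.  A species absent from a block contributes `"-"` at every
#' column of that block.
#'
#' @param path path to a MAF file.
#' @param species ordered character vector of species (assembly) names;
#'   the first is the reference.  Names are matched against the part of
#'   the MAF `src` field before the first `"."`.
#' @return Alignment-column table (see [encode_region()]): data.frame
#'   with `pos` (0-based reference coordinate), `ref`, and one column
#'   per remaining species, plus attribute `chrom`.
#' @export
read_maf <- function(path, species) {
  stopifnot(length(species) >= 2)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^a", lines)
  if (length(starts) == 0L) stop("no alignment blocks in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ref <- species[1]
  others <- species[-1]
  out <- vector("list", length(starts))
  chrom <- NULL
  last_end <- -Inf
  for (bi in seq_along(starts)) {
    block <- lines[(bounds[bi] + 1L):(bounds[bi + 1L] - 1L)]
    srows <- block[grepl("^s ", block)]
    if (length(srows) == 0L) next
    fields <- lapply(strsplit(srows, "[ \t]+"), function(f) f[f != ""])
    ok <- vapply(fields, length, 1L) >= 7L
    fields <- fields[ok]
    sp <- vapply(fields, function(f) .maf_src_species(f[2]), "")
    ri <- match(ref, sp)
    if (is.na(ri))
      stop(sprintf("reference species '%s' missing from block %d", ref, bi))
    rf <- fields[[ri]]
    if (rf[5] != "+")
      stop(sprintf("reference row on '-' strand in block %d", bi))
    rstart <- as.integer(rf[3])
    rtext <- toupper(strsplit(rf[7], "")[[1]])
    if (rstart < last_end)
      stop(sprintf("blocks not sorted by reference coordinate at block %d", bi))
    bchrom <- sub("^[^.]*\\.", "", rf[2])
    if (is.null(chrom)) chrom <- bchrom
    keep <- rtext != "-"
    pos <- rstart + cumsum(keep) - 1L
    cols <- list(pos = pos[keep], ref = rtext[keep])
    for (o in others) {
      oi <- match(o, sp)
      if (is.na(oi)) {
        cols[[o]] <- rep("-", sum(keep))
      } else {
        otext <- toupper(strsplit(fields[[oi]][7], "")[[1]])
        if (length(otext) != length(rtext))
          stop(sprintf("row length mismatch for '%s' in block %d", o, bi))
        cols[[o]] <- otext[keep]
      }
    }
    last_end <- rstart + sum(keep)
    out[[bi]] <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "chrom") <- chrom
  attr(out, "species") <- species
  out
}

#' Write an alignment-column table as a minimal 3-row MAF block
#'
#' Inverse of [read_maf()] for synthetic alignments: emits one `a`
#' block containing one `s` row per species.  The reference row has no
#' gaps (the table is reference-anchored).
#'
#' @param columns alignment-column table (contiguous reference region).
#' @param path output file path.
#' @param chrom reference chromosome (defaults to the table's
#'   attribute).
#' @return `path`, invisibly.
#' @export
write_maf <- function(columns, path, chrom = attr(columns, "chrom")) {
  if (is.null(chrom)) chrom <- "synthetic"
  if (nrow(columns) > 0 && any(diff(columns$pos) != 1L))
    stop("write_maf requires a contiguous reference region")
  sp <- setdiff(names(columns), "pos")
  start0 <- if (nrow(columns)) columns$pos[1] else 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  writeLines("a score=0", con)
  for (i in seq_along(sp)) {
    txt <- paste(columns[[sp[i]]], collapse = "")
    ungapped <- nchar(gsub("-", "", txt))
    src <- if (i == 1L) paste0(sp[i], ".", chrom) else paste0(sp[i], ".chrUn")
    st <- if (i == 1L) start0 else 0L
    writeLines(sprintf("s %s %d %d + %d %s", src, st, ungapped,
                       st + ungapped, txt), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Thin wrapper over `rtracklayer::import` returning 0-based half-open
#' intervals as a data.frame, the coordinate convention used
#' throughout the package.
#'
#' @param path path to a BED file.
#' @return data.frame with `chrom`, `start` (0-based), `end`
#'   (half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write 0-based half-open intervals to a BED file
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open)
#'   and optionally `chrom`, `name` and `score`.
#' @param path output file path.
#' @param chrom chromosome used when `intervals` lacks a `chrom`
#'   column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, chrom = "synthetic") {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = if ("chrom" %in% names(intervals)) intervals$chrom else chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals))
      as.integer(round(intervals$score)) else 0L)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
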