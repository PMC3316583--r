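# Splicing-regulatory DNA motif scanning, cross-species conservation
# filtering, and PROSITE-style protein phosphorylation patterns.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.check_iupac <- function(motif) {
  ch <- strsplit(toupper(motif), "")[[1]]
  bad <- !(ch %in% names(.IUPAC))
  if (any(bad))
    stop("invalid IUPAC character(s): ", paste(unique(ch[bad]), collapse = " "))
  chartr("U", "T", paste(ch, collapse = ""))
}

#' Registry of splicing-regulatory DNA motifs
#'
#' The sense-strand DNA equivalents of the RNA splicing-regulatory
#' elements scanned by the pipeline: G-triplet runs, CA tandem
#' repeats, the Nova-family YCAY element, the polypyrimidine-tract
#' binding protein (PTB) motifs CUCUCU and UCUUC, and the
#' polyadenylation signal AAUAAA.
#'
#' @return data.frame with `name`, `pattern` and `type`
#'   (`"iupac"`, `"run"`, or `"tandem"`).
#' @export
motif_registry <- function() {
  data.frame(
    name = c("g_triplet", "ca_repeat", "YCAY", "CUCUCU", "UCUUC", "polyA"),
    pattern = c("G", "CA", "YCAY", "CTCTCT", "TCTTC", "AATAAA"),
    type = c("run", "tandem", "iupac", "iupac", "iupac", "iupac"),
    min_rep = c(3L, 3L, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

.hit_df <- function(seq_id, start, length, text, motif, strand = "sense") {
  data.frame(seq_id = seq_id, start = as.integer(start),
             length = as.integer(length), text = text, motif = motif,
             strand = rep(strand, length.out = base::length(start)),
             stringsAsFactors = FALSE)
}

.empty_hits <- function() .hit_df(character(0), integer(0), integer(0),
                                  character(0), character(0), character(0))

#' Scan a DNA sequence for an IUPAC motif
#'
#' Reports every (possibly overlapping) match of a degenerate IUPAC
#' motif on the sense strand; RNA motifs written with `U` are scanned
#' as `T`.  Matching is delegated to
#' `Biostrings::matchPattern(fixed = FALSE)`.
#'
#' @param seq DNA sequence (character string).
#' @param motif IUPAC motif (e.g. `"YCAY"`, `"AAUAAA"`).
#' @param antisense also scan the reverse complement, reporting hits
#'   in reference coordinates with strand `"antisense"`.
#' @param seq_id identifier recorded in the hits.
#' @return data.frame of hits: `seq_id`, `start` (0-based), `length`,
#'   `text` (matched subsequence), `motif`, `strand`.
#' @export
scan_iupac <- function(seq, motif, antisense = FALSE, seq_id = "seq") {
  motif_dna <- .check_iupac(motif)
  seq <- chartr("U", "T", toupper(seq))
  subj <- Biostrings::DNAString(seq)
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif_dna), subj,
                                fixed = FALSE)
  hits <- .hit_df(rep(seq_id, length(m)), Biostrings::start(m) - 1L,
                  Biostrings::width(m), as.character(m), rep(motif, length(m)))
  if (antisense) {
    rc <- Biostrings::reverseComplement(subj)
    m2 <- Biostrings::matchPattern(Biostrings::DNAString(motif_dna), rc,
                                   fixed = FALSE)
    if (length(m2)) {
      st <- nchar(seq) - (Biostrings::start(m2) - 1L) - Biostrings::width(m2)
      hits <- rbind(hits,
                    .hit_df(rep(seq_id, length(m2)), st,
                            Biostrings::width(m2), as.character(m2),
                            rep(motif, length(m2)), "antisense"))
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

#' Maximal runs of G
#'
#' Reports each maximal run of consecutive `G` of length at least
#' `min_run`, once, with its length (so `GGGGGG` is a single run of
#' 6, not overlapping triplets).
#'
#' @param seq DNA sequence.
#' @param min_run minimum run length (default 3: G triplets).
#' @param seq_id identifier recorded in the hits.
#' @return Hits data.frame as in [scan_iupac()].
#' @export
find_g_runs <- function(seq, min_run = 3L, seq_id = "seq") {
  stopifnot(min_run >= 1)
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  if (!length(ch)) return(.empty_hits())
  r <- rle(ch == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(.empty_hits())
  .hit_df(rep(seq_id, sum(keep)), starts[keep], r$lengths[keep],
          strrep("G", r$lengths[keep]), "g_run")
}

#' Maximal perfect tandem repeats of a unit
#'
#' Reports maximal perfect tandem runs of `unit` containing at least
#' `min_units` complete copies.
#'
#' @param seq DNA sequence.
#' @param unit repeat unit (default `"CA"`).
#' @param min_units minimum number of complete copies.
#' @param seq_id identifier recorded in the hits.
#' @return Hits data.frame with an extra `n_units` column.
#' @export
find_tandem_repeats <- function(seq, unit = "CA", min_units = 3L,
                                seq_id = "seq") {
  stopifnot(nchar(unit) >= 1, min_units >= 1)
  seq <- toupper(chartr("U", "T", seq))
  unit <- toupper(unit)
  pat <- sprintf("(?:%s){%d,}", unit, min_units)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    out <- .empty_hits()
    out$n_units <- integer(0)
    return(out)
  }
  len <- attr(m, "match.length")
  # trim to whole units (regex already matches whole units, but guard)
  n_units <- len %/% nchar(unit)
  len <- n_units * nchar(unit)
  out <- .hit_df(rep(seq_id, length(m)), m - 1L, len,
                 substring(seq, m, m + len - 1L),
                 paste0(unit, "_repeat"))
  out$n_units <- n_units
  out
}

.species_matches_hit <- function(sub, hit, type, unit = NULL) {
  # does a species' gapless subsequence over the hit columns still
  # satisfy the motif, full length?
  if (nchar(sub) != hit$length) return(FALSE)
  switch(type,
    iupac = {
      m <- Biostrings::matchPattern(
        Biostrings::DNAString(.check_iupac(hit$motif)),
        Biostrings::DNAString(sub), fixed = FALSE)
      any(Biostrings::start(m) == 1L & Biostrings::width(m) == nchar(sub))
    },
    run = identical(sub, strrep("G", hit$length)),
    tandem = identical(sub, strrep(unit, nchar(sub) %/% nchar(unit))),
    stop("unknown motif type ", type))
}

#' Cross-species conserved motif hits
#'
#' Scans the reference row of a reference-anchored alignment for a
#' motif and keeps, for each hit, a record of whether every other
#' species' gapless subsequence over the hit's columns also matches
#' the motif (same length; any gap in the window breaks conservation).
#'
#' @param columns alignment-column table (see [encode_region()]).
#' @param motif motif name from [motif_registry()], or an IUPAC
#'   string.
#' @param min_run,min_units thresholds for run/tandem motifs.
#' @return Hits data.frame (reference 0-based coordinates relative to
#'   the first column) with `conserved` (logical, all species) and
#'   `n_species` (species matching, including the reference).
#' @export
conserved_hits <- function(columns, motif, min_run = 3L, min_units = 3L) {
  reg <- motif_registry()
  ri <- match(motif, reg$name)
  if (!is.na(ri)) {
    type <- reg$type[ri]
    pattern <- reg$pattern[ri]
  } else {
    type <- "iupac"
    pattern <- motif
  }
  sp <- setdiff(names(columns), c("pos", "ref"))
  refseq <- paste(columns$ref, collapse = "")
  hits <- switch(type,
    iupac = scan_iupac(refseq, pattern, seq_id = "ref"),
    run = find_g_runs(refseq, min_run = min_run, seq_id = "ref"),
    tandem = find_tandem_repeats(refseq, unit = pattern,
                                 min_units = min_units, seq_id = "ref"))
  if (!nrow(hits)) {
    hits$conserved <- logical(0)
    hits$n_species <- integer(0)
    return(hits)
  }
  unit <- if (type == "tandem") pattern else NULL
  nsp <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    rows <- (hits$start[i] + 1L):(hits$start[i] + hits$length[i])
    n <- 1L  # the reference matches by construction
    for (s in sp) {
      chars <- columns[[s]][rows]
      sub <- paste(chars[chars != "-"], collapse = "")
      if (.species_matches_hit(sub, hits[i, ], type, unit)) n <- n + 1L
    }
    nsp[i] <- n
  }
  hits$n_species <- nsp
  hits$conserved <- nsp == length(sp) + 1L
  hits
}

#' Sliding-window motif hit density
#'
#' Number of hit starts per window, reported at each window start —
#' a cluster summary for motifs whose clustering criterion is
#' otherwise unspecified.
#'
#' @param hits hits data.frame.
#' @param seq_length length of the scanned sequence.
#' @param window window width in nt (default 50).
#' @return data.frame with `start` (0-based window start) and `count`.
#' @export
hit_density <- function(hits, seq_length, window = 50L) {
  starts <- 0:max(0L, seq_length - window)
  cnt <- vapply(starts, function(s)
    sum(hits$start >= s & hits$start < s + window), 1L)
  data.frame(start = starts, count = cnt)
}

# ---- protein patterns ----

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' PROSITE-style protein pattern
#'
#' Builds a pattern object from a compact string such as
#' `"[ST]XX[DE]"`, where `[..]` is a residue set and `X` matches any
#' of the 20 standard residues.
#'
#' @param name pattern name.
#' @param pattern compact pattern string.
#' @param acceptor 1-based position of the phospho-acceptor residue
#'   within the match.
#' @return Object of class `protein_pattern`: list with `name`,
#'   `elements` (list of residue character vectors) and `acceptor`.
#' @export
protein_pattern <- function(name, pattern, acceptor = 1L) {
  toks <- regmatches(pattern,
                     gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != pattern)
    stop("cannot parse pattern: ", pattern)
  elements <- lapply(toks, function(t) {
    if (startsWith(t, "[")) strsplit(gsub("\\[|\\]", "", t), "")[[1]]
    else if (t == "X") .AA20
    else t
  })
  structure(list(name = name, elements = elements,
                 acceptor = as.integer(acceptor)),
            class = "protein_pattern")
}

#' Registry of phosphorylation-site acceptor patterns
#'
#' The kinase acceptor-site patterns scanned with zero mismatches:
#' casein kinase II `[ST]XX[DE]`, protein kinase C `[ST]X[RK]`, and
#' cAMP/cGMP-dependent protein kinase `[RK]XX[ST]` (acceptor at
#' position 4).
#'
#' @return Named list of [protein_pattern()] objects.
#' @export
protein_patterns <- function() {
  list(CKII = protein_pattern("CKII", "[ST]XX[DE]", acceptor = 1L),
       PKC = protein_pattern("PKC", "[ST]X[RK]", acceptor = 1L),
       cAMP_cGMP = protein_pattern("cAMP_cGMP", "[RK]XX[ST]", acceptor = 4L))
}

#' Scan a protein sequence for a PROSITE-style pattern
#'
#' Reports every (possibly overlapping) exact match.
#'
#' @param seq protein sequence (1-letter residues).
#' @param pattern a [protein_pattern()], or a name from
#'   [protein_patterns()].
#' @param seq_id identifier recorded in the hits.
#' @return Hits data.frame as in [scan_iupac()], with `acceptor_pos`
#'   (0-based position of the acceptor residue in `seq`).
#' @export
scan_protein_pattern <- function(seq, pattern, seq_id = "protein") {
  if (is.character(pattern)) {
    pattern <- protein_patterns()[[pattern]]
    if (is.null(pattern)) stop("unknown pattern name")
  }
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  bad <- !(ch %in% .AA20)
  if (any(bad))
    stop("invalid residue(s): ", paste(unique(ch[bad]), collapse = " "))
  rx <- paste(vapply(pattern$elements, function(e)
    if (length(e) == 1L) e else paste0("[", paste(e, collapse = ""), "]"),
    ""), collapse = "")
  m <- gregexpr(sprintf("(?=(%s))", rx), seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    out <- .empty_hits()
    out$acceptor_pos <- integer(0)
    return(out)
  }
  L <- length(pattern$elements)
  out <- .hit_df(rep(seq_id, length(m)), m - 1L, L,
                 substring(seq, m, m + L - 1L), pattern$name)
  out$acceptor_pos <- out$start + pattern$acceptor - 1L
  out
}

#' Annotate the flanking residues of a phosphorylation-site hit
#'
#' Classifies the residue immediately N-terminal of the match as
#' acidic (D/E), basic (K/R/H) or other (acidic N-terminal residues
#' increase the CKII phosphorylation rate), and reports the residue
#' at +5 from the acceptor residue when present.
#'
#' @param seq protein sequence.
#' @param hit one row of a [scan_protein_pattern()] result.
#' @return list with `n_terminal` (residue or `NA`), `n_terminal_class`
#'   (`"acidic"`, `"basic"`, `"other"`, or `"absent"`), and `plus5`
#'   (residue at acceptor + 5, or `NA`).
#' @export
annotate_flanks <- function(seq, hit) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (hit$start + hit$length > n) stop("hit extends beyond sequence")
  if (hit$start == 0L) {
    nt <- NA_character_
    cls <- "absent"
  } else {
    nt <- substring(seq, hit$start, hit$start)  # 1-based index = start0
    cls <- if (nt %in% c("D", "E")) "acidic"
           else if (nt %in% c("K", "R", "H")) "basic"
           else "other"
  }
  acc0 <- if (!is.null(hit$acceptor_pos)) hit$acceptor_pos else hit$start
  p5 <- acc0 + 5L
  plus5 <- if (p5 < n) substring(seq, p5 + 1L, p5 + 1L) else NA_character_
  list(n_terminal = nt, n_terminal_class = cls, plus5 = plus5)
}
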