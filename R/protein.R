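# Isoform domain decomposition and windowed hydropathy profiling.

#' Kyte-Doolittle hydropathy scale
#'
#' The standard published per-residue hydropathy values; positive is
#' hydrophobic, negative hydrophilic.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kd_scale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Windowed hydropathy profile
#'
#' Sliding-window arithmetic mean of per-residue hydropathy values,
#' reported at the window's center residue; only full windows are
#' used (no edge padding), so the profile has
#' `nchar(seq) - window + 1` values.  Values above zero indicate
#' hydrophobicity, below zero hydrophilicity.
#'
#' @param seq protein sequence (1-letter residues).
#' @param scale `"kyte_doolittle"` or a named numeric vector over
#'   residues (a pluggable scale such as OMH can be supplied here).
#' @param window odd window width in residues (default 9).
#' @return data.frame with `center` (1-based residue index) and
#'   `value`; empty (with a warning) when the sequence is shorter
#'   than the window.
#' @export
hydropathy_profile <- function(seq, scale = "kyte_doolittle", window = 9L) {
  if (window %% 2L != 1L) stop("window must be odd")
  if (is.character(scale)) {
    if (!identical(scale, "kyte_doolittle")) stop("unknown scale name")
    scale <- kd_scale()
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- !(ch %in% names(scale))
  if (any(bad))
    stop("residue(s) missing from scale: ",
         paste(unique(ch[bad]), collapse = " "))
  n <- length(ch)
  if (n < window) {
    warning("sequence shorter than window; empty profile")
    return(data.frame(center = integer(0), value = numeric(0)))
  }
  v <- unname(scale[ch])
  cs <- cumsum(c(0, v))
  starts <- seq_len(n - window + 1L)
  data.frame(center = starts + (window - 1L) %/% 2L,
             value = (cs[starts + window] - cs[starts]) / window)
}

#' Split a protein into head+rod and tail domains
#'
#' Intermediate-filament proteins decompose into an N-terminal head,
#' a central rod and a C-terminal tail; the 3' splice isoforms differ
#' only in the tail.  Given the combined head+rod length, returns the
#' two parts.
#'
#' @param seq protein sequence.
#' @param head_rod_length residues in the combined head+rod domains.
#' @return list with `head_rod`, `tail` (character strings) and
#'   `tail_length`.
#' @export
split_domains <- function(seq, head_rod_length) {
  n <- nchar(seq)
  head_rod_length <- as.integer(head_rod_length)
  if (head_rod_length > n)
    stop("head_rod_length exceeds sequence length")
  list(head_rod = substring(seq, 1L, head_rod_length),
       tail = if (head_rod_length < n)
         substring(seq, head_rod_length + 1L, n) else "",
       tail_length = n - head_rod_length)
}

#' Published GFAP isoform domain table
#'
#' Total polypeptide and combined head+rod domain lengths (amino
#' acids) for the GFAP alpha, delta/epsilon and kappa isoforms in
#' mouse, human and rat, as curated from UniProt; the head+rod length
#' is species-specific (374 mouse, 377 human, 375 rat) and the tail
#' is the remainder.
#'
#' @return data.frame with `species`, `isoform`, `accession` (NCBI
#'   protein accession; the mouse kappa sequence has none and is
#'   user-supplied), `total_length`, `head_rod_length`,
#'   `tail_length`.
#' @export
gfap_isoform_table <- function() {
  df <- data.frame(
    species = rep(c("mouse", "human", "rat"), each = 3),
    isoform = rep(c("alpha", "delta_epsilon", "kappa"), 3),
    accession = c("P03995.4", "NP_001124492.1", "synthetic_mouse_kappa",
                  "NP_002046.1", "NP_001124491.1", "ABL14186.1",
                  "AAD01873.1", "AAD01874.2", "ABL14185.1"),
    total_length = c(430L, 428L, 435L,
                     432L, 431L, 438L,
                     430L, 421L, 409L),
    head_rod_length = c(374L, 374L, 374L,
                        377L, 377L, 377L,
                        375L, 375L, 375L),
    stringsAsFactors = FALSE)
  df$tail_length <- df$total_length - df$head_rod_length
  df
}

#' Load protein records from FASTA plus a metadata table
#'
#' Reads sequences with `Biostrings::readAAStringSet` and attaches
#' per-record metadata (species, isoform, head+rod length).  FASTA
#' identifiers (up to the first whitespace) must map one-to-one into
#' the metadata `accession` column.
#'
#' @param fasta path to a protein FASTA file.
#' @param metadata data.frame (or TSV path) with columns `accession`,
#'   `species`, `isoform`, `head_rod_length`.
#' @return data.frame with one row per sequence: `accession`,
#'   `species`, `isoform`, `sequence`, `length`, `head_rod_length`,
#'   `tail_length`.
#' @export
load_proteins <- function(fasta, metadata) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read.table(metadata, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("accession", "species", "isoform", "head_rod_length")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(metadata$head_rod_length)))
    stop("metadata head_rod_length contains missing values")
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  mi <- match(ids, metadata$accession)
  if (any(is.na(mi)))
    stop("FASTA id(s) not in metadata: ",
         paste(ids[is.na(mi)], collapse = ", "))
  seqs <- as.character(aa)
  out <- data.frame(accession = ids,
                    species = metadata$species[mi],
                    isoform = metadata$isoform[mi],
                    sequence = unname(seqs),
                    length = nchar(seqs),
                    head_rod_length = as.integer(metadata$head_rod_length[mi]),
                    stringsAsFactors = FALSE)
  if (any(out$head_rod_length > out$length))
    stop("head_rod_length exceeds sequence length for: ",
         paste(out$accession[out$head_rod_length > out$length],
               collapse = ", "))
  out$tail_length <- out$length - out$head_rod_length
  rownames(out) <- NULL
  out
}
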