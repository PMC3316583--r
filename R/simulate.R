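# Synthetic data with known ground truth, mirroring the generative form
# of the segmentation model: Bernoulli(rho) boundaries, labels ~ pi,
# per-segment code proportions ~ Dirichlet(alpha_class), codes i.i.d.
# within segments.  Deliberately *not* a molecular-evolution simulator:
# the generator reproduces exactly the statistical structure the model
# assumes, so recovery tests are calibrated.

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g[g <= 0] <- 1e-300
  g / sum(g)
}

.check_sim_params <- function(pi, alphas, rho) {
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0))
    stop("pi must be a probability simplex")
  if (any(alphas <= 0)) stop("alphas must be positive")
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
}

#' Default 'gfap-like' simulation scenario
#'
#' Desk-scale stand-in for a ~110 kb three-species alignment window:
#' 20,000 positions, four latent conservation classes with mean
#' conservation-code proportions echoing the qualitative class
#' signatures of a real gene analysis (a human-insertion class, a
#' highly conserved exon-like class, a moderately conserved class and
#' a rodent-deletion class), mean segment length 200 (`rho = 0.005`).
#' Class 2 is the exon-like ("coding") class.
#'
#' @return List of generator parameters: `length`, `k`, `pi`, `alphas`
#'   (k x 3 matrix), `rho`, `coding_class`, `pattern_mix`.
#' @export
gfap_scenario <- function() {
  alphas <- rbind(
    c(0.35, 0.55, 0.10) * 100,   # class 1: human-specific insertions
    c(0.95, 0.045, 0.005) * 200, # class 2: highly conserved / exon-like
    c(0.60, 0.35, 0.05) * 100,   # class 3: moderately conserved
    c(0.45, 0.50, 0.05) * 100)   # class 4: rodent deletions
  list(length = 20000L, k = 4L, pi = c(0.1, 0.3, 0.4, 0.2),
       alphas = alphas, rho = 0.005, coding_class = 2L,
       pattern_mix = list(
         # per class, per code: pattern probabilities (names = patterns)
         `1` = list(`1` = c("A--" = 0.7, "AA-" = 0.1, "A-A" = 0.1,
                            "AAB" = 0.05, "ABA" = 0.025, "ABB" = 0.025),
                    `2` = c("A-B" = 0.6, "AB-" = 0.2, "ABC" = 0.2)),
         `2` = list(`1` = c("AAB" = 0.4, "ABA" = 0.4, "ABB" = 0.1,
                            "AA-" = 0.05, "A-A" = 0.05),
                    `2` = c("ABC" = 0.8, "AB-" = 0.1, "A-B" = 0.1)),
         `3` = list(`1` = c("AAB" = 0.25, "ABA" = 0.25, "ABB" = 0.3,
                            "AA-" = 0.1, "A-A" = 0.1),
                    `2` = c("ABC" = 0.6, "AB-" = 0.2, "A-B" = 0.2)),
         `4` = list(`1` = c("AA-" = 0.45, "A-A" = 0.45, "AAB" = 0.04,
                            "ABA" = 0.04, "ABB" = 0.02),
                    `2` = c("AB-" = 0.45, "A-B" = 0.45, "ABC" = 0.1))))
}

#' Well-separated four-class recovery scenario
#'
#' Benchmark scenario for parameter-recovery checks: 20,000 positions,
#' four classes with clearly distinct mean code-0 proportions
#' (0.95, 0.75, 0.50, 0.25), equal mixture weights, concentration 100
#' and mean segment length 200.  Class 2 is the most conserved
#' (exon-like) class, mirroring the role of the coding-tracking class
#' in a real conservation analysis; class labels are otherwise
#' exchangeable.  Used to verify that the sampler recovers class
#' assignments, changepoint counts and the true class count; the
#' overlapping-class [gfap_scenario()] is deliberately harder.
#'
#' @return List of generator parameters as in [gfap_scenario()].
#' @export
recovery_scenario <- function() {
  alphas <- rbind(
    c(0.75, 0.20, 0.05),
    c(0.95, 0.04, 0.01),
    c(0.50, 0.40, 0.10),
    c(0.25, 0.55, 0.20)) * 100
  list(length = 20000L, k = 4L, pi = rep(0.25, 4),
       alphas = alphas, rho = 0.005, coding_class = 2L,
       pattern_mix = NULL)
}

#' Simulate a conservation-code sequence with known segmentation
#'
#' Generative mirror of the model fitted by [conseg()]: changepoints
#' are laid down by independent Bernoulli(`rho`) draws at each of the
#' `length - 1` boundaries, each segment gets an i.i.d. class label
#' from `pi`, per-segment code proportions are drawn from
#' Dirichlet(`alphas[label, ]`), and codes are emitted i.i.d. within
#' the segment.
#'
#' @param length number of positions.
#' @param k number of classes.
#' @param pi mixture weights over classes (simplex of length `k`).
#' @param alphas `k x n_codes` matrix of positive Dirichlet parameters.
#' @param rho per-boundary changepoint probability in (0, 1).
#' @param seed integer seed; every draw is reproducible from it.
#' @return A list of class `conseg_sim` with elements `codes`
#'   ([code_seq()]), `changepoints` (boundary positions in
#'   `1:(length-1)`; a boundary at `j` separates positions `j` and
#'   `j + 1`), `labels` (class per segment), `position_labels` (class
#'   per position), `theta` (per-segment code proportions) and
#'   `params`.
#' @export
simulate_codes <- function(length, k, pi, alphas, rho, seed = 1L) {
  stopifnot(length >= 1, k >= 1, nrow(alphas) == k, length(pi) == k)
  .check_sim_params(pi, alphas, rho)
  set.seed(seed)
  m <- ncol(alphas)
  b <- if (length > 1) which(runif(length - 1) < rho) else integer(0)
  seg_start <- c(1L, b + 1L)
  seg_end <- c(b, length)
  S <- base::length(seg_start)
  labels <- sample.int(k, S, replace = TRUE, prob = pi)
  theta <- matrix(0, S, m)
  codes <- integer(length)
  for (s in seq_len(S)) {
    theta[s, ] <- .rdirichlet1(alphas[labels[s], ])
    n <- seg_end[s] - seg_start[s] + 1L
    codes[seg_start[s]:seg_end[s]] <-
      sample.int(m, n, replace = TRUE, prob = theta[s, ]) - 1L
  }
  structure(list(
    codes = code_seq(codes, chrom = "synthetic", start = 0L),
    changepoints = b,
    labels = labels,
    position_labels = rep(labels, seg_end - seg_start + 1L),
    theta = theta,
    params = list(length = length, k = k, pi = pi, alphas = alphas,
                  rho = rho, seed = seed)),
    class = "conseg_sim")
}

#' @export
print.conseg_sim <- function(x, ...) {
  cat(sprintf("<conseg_sim> %d positions, %d classes, %d changepoints, seed %d\n",
              length(x$codes), x$params$k, length(x$changepoints),
              x$params$seed))
  invisible(x)
}

# patterns admissible for each code value (3-species case)
.patterns_for_code <- function(code) {
  switch(as.character(code),
         "0" = "AAA",
         "1" = c("AAB", "ABA", "ABB", "AA-", "A-A", "A--"),
         "2" = c("ABC", "AB-", "A-B"),
         stop("no 3-species pattern for code ", code))
}

.pattern_to_column <- function(pattern) {
  # draw concrete bases for one pattern; returns 3 characters
  lets <- strsplit(pattern, "")[[1]]
  pool <- sample(c("A", "C", "G", "T"))
  vapply(lets, function(l) if (l == "-") "-" else pool[match(l, LETTERS)], "")
}

#' Emit a 3-species alignment realizing a code sequence
#'
#' Inverse of [encode_region()]: for each position, draws a column
#' pattern compatible with the code (code 0 is always `AAA`; code 1
#' one of `AAB`, `ABA`, `ABB`, `AA-`, `A-A`, `A--`; code 2 one of
#' `ABC`, `AB-`, `A-B`) and fills in concrete bases uniformly subject
#' to the pattern.  Re-encoding the emitted columns reproduces the
#' input codes exactly.
#'
#' @param codes [code_seq()] or integer vector of codes in 0:2.
#' @param pattern_mix optional named list giving, for codes `"1"` and
#'   `"2"`, a named probability vector over admissible patterns
#'   (default uniform).
#' @param seed integer seed.
#' @param species names for the three rows.
#' @return Alignment-column table (see [encode_region()]).
#' @export
emit_alignment <- function(codes, pattern_mix = NULL, seed = 1L,
                           species = c("ref", "mouse", "rat")) {
  set.seed(seed)
  cd <- as.integer(codes)
  if (any(cd < 0 | cd > 2)) stop("codes must be in 0:2 for a 3-row alignment")
  n <- length(cd)
  pat <- character(n)
  pat[cd == 0L] <- "AAA"
  for (code in c(1L, 2L)) {
    idx <- which(cd == code)
    if (!length(idx)) next
    adm <- .patterns_for_code(code)
    mix <- pattern_mix[[as.character(code)]]
    if (is.null(mix)) {
      mix <- setNames(rep(1 / length(adm), length(adm)), adm)
    } else {
      if (!all(names(mix) %in% adm))
        stop("pattern(s) incompatible with code ", code, ": ",
             paste(setdiff(names(mix), adm), collapse = " "))
      mix <- mix / sum(mix)
    }
    pat[idx] <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
  }
  cols <- t(vapply(pat, .pattern_to_column, character(3)))
  start <- if (inherits(codes, "code_seq")) attr(codes, "start") else 0L
  out <- data.frame(pos = start + seq_len(n) - 1L,
                    ref = cols[, 1], stringsAsFactors = FALSE)
  out[[species[2]]] <- cols[, 2]
  out[[species[3]]] <- cols[, 3]
  names(out)[2] <- "ref"
  attr(out, "chrom") <-
    if (inherits(codes, "code_seq")) attr(codes, "chrom") else "synthetic"
  attr(out, "species") <- species
  out
}

#' Ground-truth coding annotation from a simulated segmentation
#'
#' Returns the maximal runs of positions whose true class equals
#' `coding_class`, as 0-based half-open intervals — the synthetic
#' analogue of a protein-coding annotation.
#'
#' @param truth a `conseg_sim` object from [simulate_codes()].
#' @param coding_class class index treated as protein-coding.
#' @return data.frame with `start`, `end` (0-based half-open).
#' @export
annotate_coding <- function(truth, coding_class = 2L) {
  lab <- truth$position_labels
  r <- rle(lab == coding_class)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Plant motif instances in a random background sequence
#'
#' Generates an i.i.d. uniform A/C/G/T background and writes the given
#' motif instances at the given positions, recording ground truth for
#' scanner tests.
#'
#' @param length background length.
#' @param instances data.frame with `text` (concrete DNA to plant) and
#'   `start` (0-based position).
#' @param seed integer seed.
#' @return list with `seq` (character string) and `planted`
#'   (data.frame `text`, `start`, `end`).
#' @export
plant_motifs <- function(length, instances, seed = 1L) {
  set.seed(seed)
  bg <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  if (nrow(instances)) {
    instances <- instances[order(instances$start), , drop = FALSE]
    ends <- instances$start + nchar(instances$text)
    if (any(instances$start < 0) || any(ends > length))
      stop("planted instance outside sequence")
    if (nrow(instances) > 1 &&
        any(instances$start[-1] < ends[-nrow(instances)]))
      stop("planted instances overlap")
    for (i in seq_len(nrow(instances))) {
      ch <- strsplit(instances$text[i], "")[[1]]
      bg[(instances$start[i] + 1):(instances$start[i] + length(ch))] <- ch
    }
  }
  list(seq = paste(bg, collapse = ""),
       planted = if (nrow(instances))
         data.frame(text = instances$text, start = instances$start,
                    end = instances$start + nchar(instances$text))
       else data.frame(text = character(0), start = integer(0),
                       end = integer(0)))
}

#' Simulate a full synthetic alignment bundle
#'
#' Composes [simulate_codes()], [emit_alignment()] and
#' [annotate_coding()] under one seed: a code sequence with known
#' segmentation, a 3-species alignment realizing it (with
#' class-specific column-pattern signatures), and the ground-truth
#' coding annotation.
#'
#' @param scenario parameter list as from [gfap_scenario()].
#' @param seed integer seed.
#' @param emit_columns also emit the 3-species columns (slower for
#'   long sequences).
#' @return `conseg_sim` object with extra elements `columns` (if
#'   requested) and `coding` (annotation intervals).
#' @export
simulate_alignment <- function(scenario = gfap_scenario(), seed = 1L,
                               emit_columns = FALSE) {
  truth <- simulate_codes(scenario$length, scenario$k, scenario$pi,
                          scenario$alphas, scenario$rho, seed = seed)
  truth$coding <- annotate_coding(truth, scenario$coding_class)
  if (emit_columns) {
    # class-specific pattern signatures: sample per position according
    # to its true class
    cd <- as.integer(truth$codes)
    lab <- truth$position_labels
    set.seed(seed + 1L)
    pat <- character(length(cd))
    pat[cd == 0L] <- "AAA"
    for (g in seq_len(scenario$k)) {
      for (code in c(1L, 2L)) {
        idx <- which(cd == code & lab == g)
        if (!length(idx)) next
        mix <- scenario$pattern_mix[[as.character(g)]][[as.character(code)]]
        if (is.null(mix)) {
          adm <- .patterns_for_code(code)
          mix <- setNames(rep(1 / length(adm), length(adm)), adm)
        }
        pat[idx] <- sample(names(mix), length(idx), replace = TRUE,
                           prob = mix / sum(mix))
      }
    }
    cols <- t(vapply(pat, .pattern_to_column, character(3)))
    out <- data.frame(pos = seq_along(cd) - 1L, ref = cols[, 1],
                      mouse = cols[, 2], rat = cols[, 3],
                      stringsAsFactors = FALSE)
    attr(out, "chrom") <- "synthetic"
    attr(out, "species") <- c("ref", "mouse", "rat")
    truth$columns <- out
  }
  truth
}
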