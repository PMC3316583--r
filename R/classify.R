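# Profile-threshold class assignment, per-class column-pattern
# composition, the coding-sequence classifier, and conserved-feature
# interval extraction.

#' Unambiguous profile-threshold class assignment
#'
#' A position is assigned to class g when its class-g profile value is
#' strictly greater than `threshold`; with `threshold >= 0.5` at most
#' one class can qualify, so the assignment is unambiguous.  All other
#' positions are unassigned (`NA`).
#'
#' @param profiles `N x k` profile matrix ([compute_profiles()]).
#' @param threshold assignment threshold in `[0.5, 1)`.
#' @return Integer vector of class indices with `NA` for unassigned
#'   positions.
#' @export
assign_unambiguous <- function(profiles, threshold = 0.5) {
  if (threshold < 0.5)
    stop("threshold below 0.5 would allow ambiguous assignment")
  if (threshold >= 1) stop("threshold must be < 1")
  pm <- unclass(profiles)
  top <- max.col(pm, ties.method = "first")
  val <- pm[cbind(seq_len(nrow(pm)), top)]
  ifelse(val > threshold, top, NA_integer_)
}

#' Per-class alignment-column pattern composition
#'
#' Counts, among the positions unambiguously assigned to each class,
#' how often each of the 10 column patterns occurs, and the
#' corresponding per-class proportions (0 where a class has no
#' assigned positions).
#'
#' @param assignments integer class-or-`NA` vector from
#'   [assign_unambiguous()].
#' @param labels per-position pattern labels
#'   ([classify_patterns()]).
#' @param k number of classes (default: max observed).
#' @return list of class `pattern_composition` with `counts` and
#'   `proportions` (10-row matrices, one column per class) and
#'   `n_assigned`.
#' @export
pattern_composition <- function(assignments, labels,
                                k = max(assignments, na.rm = TRUE)) {
  if (length(assignments) != length(labels))
    stop("assignments and labels must have the same length")
  pats <- pattern_labels()
  cnt <- matrix(0L, length(pats), k,
                dimnames = list(pats, paste0("class", seq_len(k))))
  keep <- !is.na(assignments)
  if (any(keep)) {
    tb <- table(factor(labels[keep], levels = pats),
                factor(assignments[keep], levels = seq_len(k)))
    cnt[] <- as.integer(tb)
  }
  tot <- as.integer(colSums(cnt))
  names(tot) <- colnames(cnt)
  prop <- sweep(cnt, 2, pmax(tot, 1L), "/")
  structure(list(counts = cnt, proportions = prop, n_assigned = tot),
            class = "pattern_composition")
}

#' @export
print.pattern_composition <- function(x, ...) {
  cat("Pattern composition of unambiguously assigned columns\n")
  cat("counts:\n"); print(x$counts)
  cat("proportions:\n"); print(round(x$proportions, 4))
  invisible(x)
}

.coding_mask <- function(coding, n, region_start = 0L) {
  if (is.logical(coding)) {
    if (length(coding) != n) stop("logical coding mask has wrong length")
    return(coding)
  }
  if (inherits(coding, "GRanges")) {
    coding <- data.frame(start = GenomicRanges::start(coding) - 1L,
                         end = GenomicRanges::end(coding))
  }
  st <- as.integer(coding$start) - region_start
  en <- as.integer(coding$end) - region_start
  if (any(st < 0) || any(en > n) || any(st >= en))
    stop("coding annotation extends outside the profiled region")
  mask <- logical(n)
  for (i in seq_along(st)) mask[(st[i] + 1L):en[i]] <- TRUE
  mask
}

#' Confusion counts for the profile-threshold coding classifier
#'
#' Positions whose designated-class ("coding") profile exceeds
#' `threshold` (strictly) are called coding.  Against the annotation:
#' annotated-coding called positions are TP, annotated-coding uncalled
#' are FN, non-coding called are FP, non-coding uncalled are TN.  UTRs
#' count as non-coding.
#'
#' @param group_profile per-position probability for the designated
#'   coding class (one profile column).
#' @param coding the coding annotation: logical mask, data.frame with
#'   0-based half-open `start`/`end`, or a `GRanges`.
#' @param threshold calling threshold (strict `>`).
#' @param region_start 0-based coordinate of the first profiled
#'   position (used to shift interval annotations).
#' @return list of class `confusion` with `TP`, `FN`, `TN`, `FP`.
#' @export
classifier_confusion <- function(group_profile, coding, threshold = 0.5,
                                 region_start = 0L) {
  n <- length(group_profile)
  mask <- .coding_mask(coding, n, region_start)
  called <- group_profile > threshold
  out <- list(TP = sum(called & mask), FN = sum(!called & mask),
              TN = sum(!called & !mask), FP = sum(called & !mask))
  class(out) <- "confusion"
  out
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d TN=%d FP=%d\n", x$TP, x$FN, x$TN, x$FP))
  if (x$TP + x$FN > 0 && x$TN + x$FP > 0) {
    ss <- sensitivity_specificity(x)
    cat(sprintf("sensitivity=%.4f specificity=%.4f\n", ss[1], ss[2]))
  }
  invisible(x)
}

#' Sensitivity and specificity of a confusion table
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#'
#' @param conf a `confusion` list from [classifier_confusion()] (or
#'   any list with `TP`, `FN`, `TN`, `FP`).
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(conf) {
  if (conf$TP + conf$FN == 0)
    stop("no annotated coding positions (TP + FN = 0)")
  if (conf$TN + conf$FP == 0)
    stop("no annotated non-coding positions (TN + FP = 0)")
  c(sensitivity = conf$TP / (conf$TP + conf$FN),
    specificity = conf$TN / (conf$TN + conf$FP))
}

#' Extract conserved-feature intervals from a profile
#'
#' Maximal runs of positions with profile strictly above `threshold`;
#' runs separated by at most `merge_gap` sub-threshold positions are
#' merged, and merged runs shorter than `min_length` are dropped.
#'
#' @param group_profile per-position profile values for one class.
#' @param threshold run threshold in (0, 1).
#' @param min_length minimum feature length kept.
#' @param merge_gap maximum gap bridged between adjacent runs.
#' @param region_start 0-based coordinate of the first position.
#' @return data.frame with `start`, `end` (0-based half-open),
#'   `length`, `mean` and `max` profile value, and a `label` column
#'   (`A`, `B`, ... in coordinate order).
#' @export
extract_features <- function(group_profile, threshold = 0.5,
                             min_length = 10L, merge_gap = 5L,
                             region_start = 0L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  above <- group_profile > threshold
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), mean = numeric(0),
                      max = numeric(0), label = character(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths      # 0-based
  st <- starts[r$values]
  en <- ends[r$values]
  # merge runs separated by <= merge_gap
  if (length(st) > 1) {
    out_st <- c(); out_en <- c()
    cur_st <- st[1]; cur_en <- en[1]
    for (i in seq.int(2, length(st))) {
      if (st[i] - cur_en <= merge_gap) {
        cur_en <- en[i]
      } else {
        out_st <- c(out_st, cur_st); out_en <- c(out_en, cur_en)
        cur_st <- st[i]; cur_en <- en[i]
      }
    }
    out_st <- c(out_st, cur_st); out_en <- c(out_en, cur_en)
    st <- out_st; en <- out_en
  }
  len <- en - st
  keep <- len >= min_length
  st <- st[keep]; en <- en[keep]; len <- len[keep]
  if (!length(st)) return(empty)
  mn <- mapply(function(a, b) mean(group_profile[(a + 1):b]), st, en)
  mx <- mapply(function(a, b) max(group_profile[(a + 1):b]), st, en)
  data.frame(start = st + region_start, end = en + region_start,
             length = len, mean = mn, max = mx,
             label = make.unique(LETTERS[pmin(seq_along(st), 26L)]))
}

#' Write conserved features as a BED track
#'
#' Score is the mean profile value scaled by 1000.
#'
#' @param features data.frame from [extract_features()].
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path, chrom = "synthetic") {
  df <- features
  df$chrom <- chrom
  df$name <- df$label
  df$score <- round(df$mean * 1000)
  write_bed(df, path, chrom = chrom)
}
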