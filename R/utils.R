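# Small shared utilities.

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Best label permutation between two class assignments
#'
#' Mixture-class labels are exchangeable, so estimated and true labels
#' are compared after relabelling: this finds the permutation of
#' `1:k` applied to `est` that maximizes agreement with `truth`, by
#' exhaustive search over the `k!` permutations.
#'
#' @param est estimated integer class labels (NA allowed; never
#'   counted as agreement).
#' @param truth true integer class labels, same length.
#' @param k number of classes.
#' @return list with `permutation` (`perm[g]` is the true class that
#'   estimated class g maps to), `relabelled` (the permuted `est`)
#'   and `accuracy` (agreement fraction over all positions).
#' @export
best_label_permutation <- function(est, truth, k) {
  stopifnot(length(est) == length(truth), k >= 1, k <= 8)
  perms <- .permutations(k)
  best <- -1
  bi <- 1L
  for (i in seq_len(nrow(perms))) {
    acc <- sum(perms[i, ][est] == truth, na.rm = TRUE)
    if (acc > best) { best <- acc; bi <- i }
  }
  perm <- perms[bi, ]
  list(permutation = perm,
       relabelled = perm[est],
       accuracy = best / length(truth))
}
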