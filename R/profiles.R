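# Posterior class profiles, information-criterion model selection,
# convergence diagnostics and wiggle export.

#' Per-position posterior class profiles
#'
#' For each reference position and class, the fraction of post-burn-in
#' samples in which the position lies in a segment carrying that class
#' label.  Rows sum to one.
#'
#' @param fit a [conseg()] fit.
#' @param burn_in iterations to discard (default: the fit's).
#' @return `N x k` matrix of class `profile_matrix` with region
#'   attributes (`chrom`, `start`).
#' @export
compute_profiles <- function(fit, burn_in = fit$burn_in) {
  it <- .retained(fit, burn_in)
  cnt <- .profile_counts_cpp(fit$samples$changepoints[it],
                             fit$samples$labels[it],
                             length(fit$codes), fit$k)
  pr <- cnt / length(it)
  colnames(pr) <- paste0("class", seq_len(fit$k))
  structure(pr, chrom = fit$region$chrom, start = fit$region$start,
            class = c("profile_matrix", class(pr)))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d positions x %d classes (%s:%d-)\n",
              nrow(x), ncol(x), attr(x, "chrom"), attr(x, "start")))
  invisible(x)
}

#' Information criteria across class counts
#'
#' For each fitted class count k, computes approximations to AIC, BIC
#' and DIC from the post-burn-in samples: with per-sample deviance
#' `D = -2 log p(codes | segmentation, labels, alpha)`,
#' `AIC = min(D) + 2p`, `BIC = min(D) + p log N`, and
#' `DIC = mean(D) + var(D) / 2`, where
#' `p = n_codes * k + (k - 1) + 1` counts the free `alpha`, `pi` and
#' `rho` parameters.
#'
#' @param fits list of [conseg()] fits (one per k).
#' @return data.frame of class `ic_table` with columns `k`, `p`,
#'   `loglik_max`, `AIC`, `BIC`, `DIC`.
#' @export
information_criteria <- function(fits) {
  if (inherits(fits, "conseg")) fits <- list(fits)
  if (!length(fits)) stop("need at least one fit")
  rows <- lapply(fits, function(f) {
    it <- .retained(f)
    ll <- f$trace$loglik[it]
    dev <- -2 * ll
    p <- f$n_codes * f$k + (f$k - 1L) + 1L
    n <- length(f$codes)
    data.frame(k = f$k, p = p, loglik_max = max(ll),
               AIC = -2 * max(ll) + 2 * p,
               BIC = -2 * max(ll) + p * log(n),
               DIC = mean(dev) + var(dev) / 2)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  class(out) <- c("ic_table", class(out))
  out
}

#' Select the number of classes from an AIC scan
#'
#' Elbow rule on AIC: the chosen k is the smallest k whose AIC
#' improvement to the next scanned k falls below `tau` times the
#' largest single-step improvement in the scan — the point where AIC
#' has achieved essentially all of its reduction.  The largest step is
#' the anchor (rather than the total range) because the segmentation
#' itself absorbs much of the fit, so total AIC ranges are modest and
#' post-elbow steps are dominated by Monte Carlo noise in the
#' per-k maximum log-likelihood.  AIC is used because in this model
#' family BIC tends to favour a 1-class model and DIC is too variable;
#' both are still reported by [information_criteria()].
#'
#' @param ic an `ic_table` from [information_criteria()].
#' @param tau negligible-improvement fraction of the largest
#'   single-step AIC improvement (default 0.2).
#' @return The selected k (integer), with the full scan attached as
#'   attribute `ic`.
#' @export
select_k <- function(ic, tau = 0.2) {
  stopifnot(nrow(ic) >= 1)
  aic <- ic$AIC
  ks <- ic$k
  if (length(aic) == 1L) return(structure(ks[1], ic = ic))
  gain <- aic[-length(aic)] - aic[-1]   # improvement k -> next k
  if (max(gain) <= 0) return(structure(ks[which.min(aic)], ic = ic))
  small <- which(gain < tau * max(gain))
  kk <- if (length(small)) ks[small[1]] else ks[length(ks)]
  structure(kk, ic = ic)
}

#' MCMC convergence diagnostics
#'
#' Traces of the log-likelihood, changepoint count, `rho`, `pi` and
#' `alpha` are in `fit$trace`; this summarizes them and flags apparent
#' non-convergence when the first-half and second-half means of the
#' post-burn-in log-likelihood differ by more than 3 pooled standard
#' errors.
#'
#' @param fit a [conseg()] fit.
#' @param path optional path; when given, the full trace table is
#'   written there as TSV.
#' @return list with `flag` (TRUE if drift detected), `z` (the
#'   half-difference z score), `trace` (the per-iteration table) and
#'   `alpha_acceptance`.
#' @export
convergence_diagnostics <- function(fit, path = NULL) {
  tr <- fit$trace
  if (!is.null(path))
    write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  it <- .retained(fit)
  ll <- tr$loglik[it]
  h <- length(ll) %/% 2
  a <- ll[seq_len(h)]
  b <- ll[seq.int(h + 1, length(ll))]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  z <- if (is.finite(se) && se > 0) abs(mean(a) - mean(b)) / se else 0
  list(flag = z > 3, z = z, trace = tr,
       alpha_acceptance = fit$alpha_acceptance)
}

#' Write one profile column as a fixedStep wiggle track
#'
#' Emits UCSC fixedStep WIG (step 1, span 1), one value per reference
#' position, with a browser-style 1-based start.
#'
#' @param profiles a `profile_matrix` from [compute_profiles()], or a
#'   numeric matrix.
#' @param class_index which class column to export.
#' @param path output file path (or a connection).
#' @param chrom,start chromosome and 0-based region start (defaults:
#'   the profile's attributes).
#' @param name optional track name line.
#' @param digits decimals written per value.
#' @return The WIG text lines, invisibly.
#' @export
write_wiggle <- function(profiles, class_index, path,
                         chrom = attr(profiles, "chrom") %||% "unknown",
                         start = attr(profiles, "start") %||% 0L,
                         name = NULL, digits = 6) {
  if (class_index < 1 || class_index > ncol(profiles))
    stop("class_index out of range")
  vals <- formatC(profiles[, class_index], digits = digits, format = "f")
  lines <- c(
    if (!is.null(name)) sprintf("track type=wiggle_0 name=\"%s\"", name),
    sprintf("fixedStep chrom=%s start=%d step=1 span=1", chrom,
            as.integer(start) + 1L),
    vals)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a fixedStep wiggle track
#'
#' Parses the single-track fixedStep WIG dialect written by
#' [write_wiggle()].
#'
#' @param path path to a WIG file.
#' @return Numeric vector of values with attributes `chrom` and
#'   `start` (0-based).
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  hdr <- grep("^fixedStep", lines)
  if (length(hdr) != 1L) stop("expected exactly one fixedStep header")
  h <- lines[hdr]
  chrom <- sub(".*chrom=([^ ]+).*", "\\1", h)
  start1 <- as.integer(sub(".*start=([0-9]+).*", "\\1", h))
  step <- as.integer(sub(".*step=([0-9]+).*", "\\1", h))
  if (step != 1L) stop("only step=1 tracks are supported")
  vals <- as.numeric(lines[-seq_len(hdr)])
  structure(vals, chrom = chrom, start = start1 - 1L)
}
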