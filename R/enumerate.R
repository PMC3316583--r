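# Exact posterior by exhaustive enumeration — a reference computation
# feasible only for short sequences, used to validate the MCMC sampler.

#' Exact posterior over segmentations by exhaustive enumeration
#'
#' Enumerates all `2^(N-1)` boundary configurations with class labels
#' summed out analytically, for fixed `pi`, `alphas` and `rho`.
#' Returns exact marginal changepoint probabilities and per-position
#' class-membership probabilities.  Only feasible for small `N`
#' (enumeration is exponential); intended as a ground-truth reference
#' for sampler validation.
#'
#' @inheritParams joint_log_prob
#' @param codes integer code vector (short; `N <= 20` enforced).
#' @return list with `boundary_prob` (length `N-1`; probability that a
#'   changepoint separates positions `j` and `j+1`), `class_prob`
#'   (`N x k` matrix), and `log_evidence`.
#' @export
exact_posterior <- function(codes, pi, alphas, rho) {
  codes <- as.integer(codes)
  n <- length(codes)
  if (n < 1 || n > 20) stop("enumeration supported for 1 <= N <= 20")
  k <- length(pi)
  m <- ncol(alphas)
  # per-segment label-marginalized evidence and label posterior, cached
  # over all n*(n+1)/2 contiguous segments
  seg_ev <- matrix(-Inf, n, n)      # [i, j] = segment positions i..j
  seg_post <- array(0, c(n, n, k))
  for (i in seq_len(n)) {
    cnt <- integer(m)
    for (j in i:n) {
      cnt[codes[j] + 1L] <- cnt[codes[j] + 1L] + 1L
      lg <- vapply(seq_len(k), function(g)
        log(pi[g]) + segment_log_marginal(cnt, alphas[g, ]), 0)
      mx <- max(lg)
      w <- exp(lg - mx)
      seg_ev[i, j] <- mx + log(sum(w))
      seg_post[i, j, ] <- w / sum(w)
    }
  }
  nb <- n - 1L
  nconf <- 2^nb
  b_prob <- numeric(max(nb, 0))
  c_prob <- matrix(0, n, k)
  logw <- numeric(nconf)
  confs <- vector("list", nconf)
  for (ci in seq_len(nconf)) {
    bits <- as.integer(intToBits(ci - 1L))[seq_len(max(nb, 1))]
    if (nb == 0) bits <- integer(0)
    cp <- which(bits == 1L)
    st <- c(1L, cp + 1L)
    en <- c(cp, n)
    lw <- sum(bits) * log(rho) + (nb - sum(bits)) * log1p(-rho)
    for (s in seq_along(st)) lw <- lw + seg_ev[st[s], en[s]]
    logw[ci] <- lw
    confs[[ci]] <- list(cp = cp, st = st, en = en)
  }
  mx <- max(logw)
  w <- exp(logw - mx)
  W <- sum(w)
  for (ci in seq_len(nconf)) {
    wi <- w[ci] / W
    cf <- confs[[ci]]
    if (length(cf$cp)) b_prob[cf$cp] <- b_prob[cf$cp] + wi
    for (s in seq_along(cf$st))
      c_prob[cf$st[s]:cf$en[s], ] <- c_prob[cf$st[s]:cf$en[s], ] +
        rep(wi * seg_post[cf$st[s], cf$en[s], ], each = cf$en[s] - cf$st[s] + 1L)
  }
  list(boundary_prob = b_prob, class_prob = c_prob,
       log_evidence = mx + log(W))
}
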