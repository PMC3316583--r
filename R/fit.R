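# The multiple change-point mixture model: likelihood pieces and the
# MCMC fitting front end.

#' Dirichlet-multinomial log marginal of one segment
#'
#' Log probability of the ordered codes of one segment with the
#' per-segment code proportions integrated out against a
#' Dirichlet(`alpha`) prior:
#' \deqn{\log\frac{\Gamma(\sum_c \alpha_c)}{\Gamma(\sum_c \alpha_c + n)}
#'   + \sum_c \log\frac{\Gamma(\alpha_c + n_c)}{\Gamma(\alpha_c)}.}
#'
#' @param counts non-negative integer code counts of the segment.
#' @param alpha positive Dirichlet parameters, same length as `counts`.
#' @return Log probability (0 for an empty segment).
#' @examples
#' segment_log_marginal(c(2, 0, 0), c(1, 1, 1))  # log(1/6)
#' @export
segment_log_marginal <- function(counts, alpha) {
  if (length(counts) != length(alpha))
    stop("counts and alpha must have the same length")
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) return(0)
  lgamma(sum(alpha)) - lgamma(sum(alpha) + n) +
    sum(lgamma(alpha + counts) - lgamma(alpha))
}

.seg_bounds <- function(changepoints, n) {
  cp <- as.integer(changepoints)
  if (length(cp)) {
    if (is.unsorted(cp, strictly = TRUE) || cp[1] < 1L || cp[length(cp)] > n - 1L)
      stop("changepoints must be strictly increasing positions in 1..N-1")
  }
  list(start = c(1L, cp + 1L), end = c(cp, n))
}

#' Joint log probability of a segmentation under the model
#'
#' Assembles the model's joint density of the data and the latent
#' segmentation: per segment, `log pi[label]` plus the
#' Dirichlet-multinomial marginal ([segment_log_marginal()]); plus
#' Bernoulli(`rho`) terms for each of the `N - 1` boundaries.
#' Hyperprior terms for `pi`, `alpha` and `rho` (uniform simplex,
#' log-uniform on (1e-3, 1e6) per component, Beta(1,1)) are added only
#' when `hyperprior = TRUE`.
#'
#' @param codes integer code vector (values `0:(ncol(alphas) - 1)`).
#' @param changepoints strictly increasing boundary positions in
#'   `1:(N-1)`; boundary `j` separates positions `j` and `j + 1`.
#' @param labels class index in `1:k` per segment
#'   (`length(changepoints) + 1` of them).
#' @param pi mixture weights over classes.
#' @param alphas `k x n_codes` matrix of Dirichlet parameters.
#' @param rho per-boundary changepoint probability.
#' @param hyperprior include hyperprior density terms.
#' @return Joint log probability.
#' @export
joint_log_prob <- function(codes, changepoints, labels, pi, alphas, rho,
                           hyperprior = FALSE) {
  codes <- as.integer(codes)
  n <- length(codes)
  k <- length(pi)
  sb <- .seg_bounds(changepoints, n)
  if (length(labels) != length(sb$start))
    stop("need one more label than changepoints")
  if (any(labels < 1L | labels > k))
    stop("label out of 1..k")
  m <- ncol(alphas)
  lp <- 0
  for (s in seq_along(sb$start)) {
    cnt <- tabulate(codes[sb$start[s]:sb$end[s]] + 1L, nbins = m)
    lp <- lp + log(pi[labels[s]]) +
      segment_log_marginal(cnt, alphas[labels[s], ])
  }
  ncp <- length(changepoints)
  if (n > 1)
    lp <- lp + ncp * log(rho) + (n - 1 - ncp) * log1p(-rho)
  if (hyperprior) {
    lp <- lp + lgamma(k)                              # Dirichlet(1,..,1) on pi
    lp <- lp - sum(log(alphas)) -
      length(alphas) * log(log(1e6) - log(1e-3))      # log-uniform on alpha
    # Beta(1,1) on rho contributes 0
  }
  lp
}

#' Fit the Bayesian multiple change-point mixture model by MCMC
#'
#' Segments a conservation-code sequence into `k` latent classes.  The
#' model: independent Bernoulli(`rho`) changepoint indicators at each
#' between-character boundary with `rho ~ Beta(1,1)`; segment class
#' labels i.i.d. from mixture weights `pi ~ Dirichlet(1,..,1)`; within
#' a segment of class g, codes i.i.d. from proportions drawn from
#' Dirichlet(`alpha_g`) (integrated out analytically); each `alpha`
#' component has a log-uniform prior on (1e-3, 1e6).  The sampler
#' alternates an exact Gibbs sweep over all boundaries (labels
#' marginalized), Gibbs label resampling, conjugate `pi` and `rho`
#' updates, and log-normal random-walk Metropolis on each `alpha`
#' component (step adapted during burn-in only).
#'
#' Chains are bit-reproducible given `seed`.
#'
#' @param codes a [code_seq()] or integer vector of codes.
#' @param k number of classes (`>= 1`).
#' @param n_iter MCMC iterations (default 1000).
#' @param burn_in iterations discarded by downstream summaries
#'   (default 500); stored with the fit.
#' @param seed integer seed.
#' @param n_codes size of the code alphabet (default: 3, or more if
#'   the data contain larger codes).
#' @param params optional list with any of `pi`, `alphas`, `rho`: a
#'   supplied component is held fixed at the given value instead of
#'   being sampled (used for validation against exact enumeration).
#' @param alpha_step initial log-normal random-walk step for the
#'   `alpha` updates.
#' @return An object of class `conseg`: list with `samples`
#'   (per-iteration `changepoints` and `labels`), `trace`
#'   (per-iteration log-likelihood, changepoint count, `rho`, `pi`,
#'   `alpha`), the inputs, and region metadata.  Methods: `print`,
#'   `summary`, `coef`, `logLik`, `plot`, `simulate`,
#'   [compute_profiles()].
#' @examples
#' sim <- simulate_codes(300, 2, c(0.5, 0.5),
#'                       rbind(c(30, 3, 1), c(3, 30, 1)), 0.02, seed = 1)
#' fit <- conseg(sim$codes, k = 2, n_iter = 200, burn_in = 100, seed = 1)
#' fit
#' @export
conseg <- function(codes, k = 4L, n_iter = 1000L, burn_in = 500L,
                   seed = 1L, n_codes = NULL, params = NULL,
                   alpha_step = 0.3) {
  cd <- as.integer(codes)
  if (length(cd) < 1L) stop("empty code sequence")
  if (k < 1L) stop("k must be >= 1")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (is.null(n_codes)) n_codes <- max(3L, max(cd) + 1L)
  if (max(cd) + 1L > n_codes) stop("codes exceed n_codes")
  m <- as.integer(n_codes)
  n <- length(cd)

  fix_pi <- !is.null(params$pi)
  fix_alpha <- !is.null(params$alphas)
  fix_rho <- !is.null(params$rho)

  set.seed(seed)
  init <- .kmeans_init(cd, k, m,
                       random = fix_alpha || fix_pi || fix_rho || k == 1L)
  rho0 <- if (fix_rho) params$rho else init$rho
  pi0 <- if (fix_pi) params$pi else init$pi
  if (length(pi0) != k) stop("params$pi must have length k")
  if (fix_alpha) {
    a0 <- params$alphas
    if (!is.matrix(a0) || nrow(a0) != k || ncol(a0) != m)
      stop("params$alphas must be a k x n_codes matrix")
  } else {
    a0 <- init$alphas
  }
  b0 <- init$b
  if (fix_rho && !any(b0 == 1L) && n > 1)
    b0 <- as.integer(runif(n - 1) < rho0)

  res <- .conseg_mcmc_cpp(cd, m, as.integer(k), as.integer(n_iter),
                          b0, pi0, a0, rho0,
                          fix_pi, fix_alpha, fix_rho,
                          alpha_step, as.integer(burn_in))

  trace <- data.frame(iteration = seq_len(n_iter),
                      loglik = res$loglik,
                      n_changepoints = res$n_changepoints,
                      rho = res$rho)
  pim <- res$pi
  colnames(pim) <- paste0("pi.", seq_len(k))
  am <- res$alpha
  colnames(am) <- paste0("alpha.", rep(seq_len(k), each = m), ".",
                         rep(seq_len(m) - 1L, k))
  trace <- cbind(trace, pim, am)

  structure(list(
    codes = cd, n_codes = m, k = as.integer(k),
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    seed = as.integer(seed),
    region = list(chrom = attr(codes, "chrom") %||% "unknown",
                  start = attr(codes, "start") %||% 0L),
    fixed = list(pi = fix_pi, alphas = fix_alpha, rho = fix_rho),
    samples = list(changepoints = res$changepoints, labels = res$labels),
    trace = trace,
    alpha_acceptance = matrix(res$alpha_acceptance, k, m, byrow = TRUE),
    call = match.call()),
    class = "conseg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moment-based starting state: k-means on windowed code proportions.
# Gives the 1000-iteration default chain a warm start so burn-in is
# spent refining, not finding, the class structure.  Deterministic
# given the RNG state (called after set.seed in conseg).
.kmeans_init <- function(cd, k, m, window = 50L, random = FALSE) {
  n <- length(cd)
  nw <- n %/% window
  if (random || nw < 2L * k) {
    # cold start from a diffuse state
    rho0 <- 0.01
    b0 <- if (n > 1) as.integer(runif(n - 1) < rho0) else integer(0)
    return(list(b = b0, pi = rep(1 / k, k),
                alphas = matrix(exp(runif(k * m, log(0.1), log(100))), k, m),
                rho = rho0))
  }
  idx <- rep(seq_len(nw), each = window)
  props <- t(vapply(seq_len(nw), function(w)
    tabulate(cd[idx == w] + 1L, nbins = m) / window, numeric(m)))
  km <- tryCatch(stats::kmeans(props, centers = k, nstart = 5, iter.max = 30),
                 error = function(e) NULL)
  if (is.null(km)) return(.kmeans_init(cd, k, m, window, random = TRUE))
  cl <- km$cluster
  centers <- km$centers
  # boundaries where consecutive windows change cluster
  b0 <- integer(max(n - 1L, 0L))
  chg <- which(diff(cl) != 0L)
  b0[chg * window] <- 1L
  pi0 <- as.numeric(table(factor(cl, levels = seq_len(k))))
  pi0 <- (pi0 + 0.5) / sum(pi0 + 0.5)
  # per-cluster concentration by Dirichlet-multinomial moments:
  # Var(phat) = p(1-p) (conc + w) / (w (conc + 1))
  # cap at 300: k-means cells truncate within-cluster variance for
  # overlapping classes, which would otherwise inflate the estimate and
  # start the chain in a rigid (huge-concentration) state
  conc <- vapply(seq_len(k), function(g) {
    rows <- which(cl == g)
    if (length(rows) < 3) return(50)
    p <- centers[g, ]
    v <- apply(props[rows, , drop = FALSE], 2, var)
    r <- sum(v) / max(sum(p * (1 - p)), 1e-6)
    if (r * window <= 1.05) return(300)
    max(2, min(300, window * (1 - r) / (r * window - 1)))
  }, 0)
  a0 <- pmax(centers, 0.02) * conc
  rho0 <- max((sum(b0) + 1) / n, 1e-4)
  list(b = b0, pi = pi0, alphas = a0, rho = rho0)
}

.retained <- function(fit, burn_in = fit$burn_in) {
  if (burn_in >= fit$n_iter) stop("burn_in must be smaller than chain length")
  seq.int(burn_in + 1L, fit$n_iter)
}

#' @export
print.conseg <- function(x, ...) {
  cat(sprintf("<conseg> %d positions, k = %d classes, %d iterations (burn-in %d), seed %d\n",
              length(x$codes), x$k, x$n_iter, x$burn_in, x$seed))
  it <- .retained(x)
  cat(sprintf("posterior mean changepoints: %.1f | max log-lik: %.2f\n",
              mean(x$trace$n_changepoints[it]), max(x$trace$loglik[it])))
  invisible(x)
}

#' @method summary conseg
#' @export
summary.conseg <- function(object, ...) {
  it <- .retained(object)
  tr <- object$trace[it, , drop = FALSE]
  k <- object$k; m <- object$n_codes
  pim <- colMeans(tr[paste0("pi.", seq_len(k))])
  am <- matrix(colMeans(tr[grep("^alpha\\.", names(tr))]), k, m, byrow = TRUE)
  rownames(am) <- paste0("class", seq_len(k))
  colnames(am) <- paste0("code", seq_len(m) - 1L)
  out <- list(k = k, n = length(object$codes),
              n_iter = object$n_iter, burn_in = object$burn_in,
              pi = unname(pim), alphas = am,
              code_means = am / rowSums(am),
              rho = mean(tr$rho),
              n_changepoints = mean(tr$n_changepoints),
              loglik_max = max(tr$loglik), loglik_mean = mean(tr$loglik),
              alpha_acceptance = object$alpha_acceptance)
  class(out) <- "summary.conseg"
  out
}

#' @export
print.summary.conseg <- function(x, ...) {
  cat(sprintf("Change-point mixture fit: N = %d, k = %d, %d iterations (burn-in %d)\n",
              x$n, x$k, x$n_iter, x$burn_in))
  cat(sprintf("posterior mean changepoint count: %.1f (rho = %.4g)\n",
              x$n_changepoints, x$rho))
  cat("posterior mean mixture weights (pi):\n")
  print(round(x$pi, 4))
  cat("posterior mean Dirichlet parameters (alpha):\n")
  print(round(x$alphas, 3))
  cat("implied mean code proportions per class:\n")
  print(round(x$code_means, 4))
  cat(sprintf("log-likelihood: max %.2f, mean %.2f\n",
              x$loglik_max, x$loglik_mean))
  invisible(x)
}

#' @method coef conseg
#' @export
coef.conseg <- function(object, ...) {
  s <- summary(object)
  list(pi = s$pi, alphas = s$alphas, rho = s$rho)
}

#' @method logLik conseg
#' @export
logLik.conseg <- function(object, ...) {
  it <- .retained(object)
  ll <- max(object$trace$loglik[it])
  p <- object$n_codes * object$k + (object$k - 1L) + 1L
  structure(ll, df = p, nobs = length(object$codes), class = "logLik")
}

#' @export
simulate.conseg <- function(object, nsim = 1, seed = NULL, ...) {
  co <- coef(object)
  if (is.null(seed)) seed <- object$seed
  lapply(seq_len(nsim), function(i)
    simulate_codes(length(object$codes), object$k, co$pi, co$alphas,
                   co$rho, seed = seed + i - 1L)$codes)
}

#' @method plot conseg
#' @export
plot.conseg <- function(x, burn_in = x$burn_in, ...) {
  pr <- compute_profiles(x, burn_in = burn_in)
  matplot(seq_len(nrow(pr)), pr, type = "l", lty = 1,
          xlab = "position", ylab = "posterior class probability",
          ylim = c(0, 1), ...)
  legend("topright", legend = paste("class", seq_len(ncol(pr))),
         col = seq_len(ncol(pr)), lty = 1, bty = "n", cex = 0.8)
  invisible(pr)
}
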