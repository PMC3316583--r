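test_that("segment marginal matches analytic values and a Monte Carlo oracle", {
  expect_equal(segment_log_marginal(c(2, 0, 0), c(1, 1, 1)), log(1 / 6))
  expect_equal(segment_log_marginal(c(0, 0, 0), c(7, 2, 9)), 0)
  expect_equal(segment_log_marginal(c(1, 1, 1), c(1, 1, 1)), log(1 / 60))
  # independent oracle: integrate the i.i.d. categorical likelihood over
  # Dirichlet draws
  set.seed(1)
  n <- 2e5
  g <- matrix(rgamma(3 * n, 1), n, 3)
  th <- g / rowSums(g)
  vals <- th[, 1] * th[, 2] * th[, 3]   # likelihood of one 0, one 1, one 2
  mc <- mean(vals)
  se <- sd(vals) / sqrt(n)
  expect_lt(abs(mc - exp(segment_log_marginal(c(1, 1, 1), c(1, 1, 1)))), 3 * se)
  expect_error(segment_log_marginal(c(1, 0, 0), c(1, -1, 1)), "positive")
})

test_that("segment marginal depends on counts only and has the categorical limit", {
  a <- c(3.2, 1.5, 0.7)
  expect_equal(segment_log_marginal(c(5, 2, 1), a),
               segment_log_marginal(c(5, 2, 1), a))  # counts are sufficient
  codes <- c(rep(0, 5), rep(1, 2), 2)
  set.seed(2)
  for (i in 1:5) {
    perm <- sample(codes)
    expect_equal(segment_log_marginal(tabulate(perm + 1, 3), a),
                 segment_log_marginal(tabulate(codes + 1, 3), a))
  }
  # alpha -> Inf with fixed proportions: i.i.d. categorical log-likelihood
  p <- c(0.6, 0.3, 0.1)
  cnt <- c(30, 15, 5)
  expect_lt(abs(segment_log_marginal(cnt, 1e6 * p) - sum(cnt * log(p))),
            1e-3 * sum(cnt))
})

test_that("joint log probability composes segment terms and boundary terms", {
  a <- rbind(c(1, 1, 1))
  expect_equal(joint_log_prob(c(0, 0), integer(0), 1L, pi = 1, alphas = a,
                              rho = 0.5),
               log(1 / 6) + log(0.5))
  # permuting codes within segments leaves it unchanged
  codes <- c(0, 1, 0, 2, 2, 1)
  al <- rbind(c(2, 1, 1), c(1, 1, 3))
  v1 <- joint_log_prob(codes, 3L, c(1L, 2L), c(0.4, 0.6), al, 0.1)
  v2 <- joint_log_prob(c(1, 0, 0, 1, 2, 2), 3L, c(1L, 2L), c(0.4, 0.6), al, 0.1)
  expect_equal(v1, v2)
  expect_lt(v1, 0)
  expect_error(joint_log_prob(codes, 3L, c(1L, 5L), c(0.4, 0.6), al, 0.1),
               "label")
  # label-permutation symmetry when pi and alphas are permuted together
  v3 <- joint_log_prob(codes, 3L, c(2L, 1L), c(0.6, 0.4), al[2:1, ], 0.1)
  expect_equal(v1, v3)
})

test_that("chains are bit-reproducible and k = 1 is degenerate", {
  sim <- simulate_codes(150, 2, c(0.5, 0.5),
                        rbind(c(40, 4, 1), c(2, 30, 8)), 0.03, seed = 3)
  f1 <- conseg(sim$codes, k = 2, n_iter = 120, burn_in = 60, seed = 11)
  f2 <- conseg(sim$codes, k = 2, n_iter = 120, burn_in = 60, seed = 11)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$samples, f2$samples)
  f3 <- conseg(sim$codes, k = 1, n_iter = 60, burn_in = 30, seed = 1)
  pr <- compute_profiles(f3)
  expect_true(all(pr[, 1] == 1))
  expect_error(conseg(integer(0), k = 2), "empty")
  expect_error(conseg(sim$codes, k = 2, n_iter = 100, burn_in = 100),
               "burn_in")
})

test_that("profiles average retained samples and rows sum to one", {
  sim <- simulate_codes(200, 2, c(0.5, 0.5),
                        rbind(c(60, 3, 1), c(2, 50, 6)), 0.02, seed = 4)
  f <- conseg(sim$codes, k = 2, n_iter = 200, burn_in = 100, seed = 2)
  pr <- compute_profiles(f)
  expect_equal(unname(rowSums(pr)), rep(1, 200), tolerance = 1e-9)
  expect_true(all(pr >= 0 & pr <= 1))
  # profile values are multiples of 1/(retained samples)
  expect_true(all(abs(pr * 100 - round(pr * 100)) < 1e-9))
  expect_error(compute_profiles(f, burn_in = 200), "burn_in")
})

test_that("hand-built chains give the stated profile fractions", {
  fake <- structure(list(
    codes = rep(0L, 4), n_codes = 3L, k = 2L, n_iter = 2L, burn_in = 0L,
    region = list(chrom = "x", start = 0L),
    samples = list(changepoints = list(2L, 2L),
                   labels = list(c(1L, 1L), c(1L, 2L)))),
    class = "conseg")
  pr <- compute_profiles(fake, burn_in = 0)
  expect_equal(unname(pr[3, ]), c(0.5, 0.5))   # samples disagree on pos 3
  expect_equal(unname(pr[1, ]), c(1, 0))       # and agree on pos 1
})

test_that("fixed-parameter chains match exhaustive enumeration", {
  codes <- c(0, 0, 0, 1, 2, 2, 2, 0, 0, 0)
  alphas <- rbind(c(15, 2, 1), c(1, 2, 15))
  pi <- c(0.6, 0.4); rho <- 0.15
  ex <- exact_posterior(codes, pi, alphas, rho)
  f <- conseg(codes, k = 2, n_iter = 8000, burn_in = 1000, seed = 5,
              params = list(pi = pi, alphas = alphas, rho = rho))
  it <- 1001:8000
  bp <- vapply(seq_len(9), function(j)
    mean(vapply(f$samples$changepoints[it],
                function(cp) j %in% cp, TRUE)), 0)
  # batch-means Monte Carlo SE
  nb <- 50
  bat <- split(it, rep(seq_len(nb), each = length(it) / nb))
  for (j in seq_len(9)) {
    bm <- vapply(bat, function(b)
      mean(vapply(f$samples$changepoints[b],
                  function(cp) j %in% cp, TRUE)), 0)
    se <- sd(bm) / sqrt(nb)
    expect_lt(abs(bp[j] - ex$boundary_prob[j]), 3 * se + 1e-3)
  }
  pr <- compute_profiles(f, burn_in = 1000)
  expect_lt(max(abs(pr[, 1] - ex$class_prob[, 1])), 0.02)
})

test_that("model methods report coherent summaries", {
  sim <- simulate_codes(300, 2, c(0.5, 0.5),
                        rbind(c(50, 4, 1), c(4, 40, 6)), 0.02, seed = 6)
  f <- conseg(sim$codes, k = 2, n_iter = 150, burn_in = 50, seed = 3)
  s <- summary(f)
  expect_equal(sum(s$pi), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(s$code_means)), c(1, 1), tolerance = 1e-9)
  ll <- logLik(f)
  expect_identical(attr(ll, "df"), 3L * 2L + 1L + 1L)
  expect_identical(attr(ll, "nobs"), 300L)
  co <- coef(f)
  expect_named(co, c("pi", "alphas", "rho"))
  sims <- simulate(f, nsim = 2)
  expect_length(sims, 2L)
  expect_length(as.integer(sims[[1]]), 300L)
})
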