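test_that("exact regret matches brute-force enumeration over samples", {
  expect_equal(exact_regret(1, 10), 0)
  expect_equal(exact_regret(2, 1), log(2), tolerance = 1e-12)
  expect_equal(exact_regret(2, 2), log(2.5), tolerance = 1e-12)
  # independent oracle: sum of maximized likelihoods over all S^N samples
  expect_equal(exact_regret(3, 5), brute_regret_samples(3, 5), tolerance = 1e-10)
  expect_equal(exact_regret(4, 4), brute_regret_samples(4, 4), tolerance = 1e-10)
  # the S = 2 closed sum agrees with the convolution route
  b <- exp(nmlcodes:::log_bk(0:12))
  conv <- nmlcodes:::convolve_trunc(b, b, 12)
  expect_equal(exact_regret(2, 12),
               lgamma(13) - 12 * log(12) + 12 + log(conv[13]), tolerance = 1e-10)
  expect_error(exact_regret(7, 10), "saddle")
  expect_error(exact_regret(3, 100), "saddle")
})

test_that("saddle point solves <k>_z = rho and behaves as 1/(2 rho)", {
  sol <- solve_saddle(100)
  expect_lt(abs(sol$z_star - 1 / 200) / (1 / 200), 0.1)
  expect_lt(abs(sol$mean_k - 100), 1e-8)
  expect_gt(sol$var_k, 0)
  # <k>_z decreasing in z => z* decreasing in rho
  expect_gt(solve_saddle(2)$z_star, solve_saddle(10)$z_star)
})

test_that("q(k|z) is a normalized distribution with the saddle mean", {
  qq <- q_k(0.05)
  expect_equal(sum(qq$p), 1, tolerance = 1e-12)
  expect_error(q_k(-0.1), "diverges")
  sol <- solve_saddle(7)
  qq <- q_k(sol$z_star)
  expect_equal(sum(qq$p * qq$k), 7, tolerance = 1e-6)
  # truncated tail below 1e-12
  expect_lt(qq$p[length(qq$p)], 1e-12)
})

test_that("saddle regret tracks the exact regret and its asymptotics", {
  rel <- vapply(2:5, function(S) {
    N <- 10 * S
    abs(saddle_regret(S, N) - exact_regret(S, N)) / exact_regret(S, N)
  }, numeric(1))
  expect_true(all(rel < 0.05))
  # error decreases with N at fixed S
  e1 <- abs(saddle_regret(3, 30) - exact_regret(3, 30)) / exact_regret(3, 30)
  e2 <- abs(saddle_regret(3, 60) - exact_regret(3, 60)) / exact_regret(3, 60)
  expect_lt(e2, e1)
  # rho >> 1 closed form
  expect_lt(abs(saddle_regret(2, 200) - asymptotic_regret(2, 100)) /
              asymptotic_regret(2, 100), 0.1)
  # large N, fixed S: Rissanen form (k/2) log(N/2pi) + log int sqrt(det I);
  # for the two-state model the Jeffreys integral is pi
  ris <- 0.5 * log(1e5 / (2 * pi)) + log(pi)
  expect_lt(abs(saddle_regret(2, 1e5) - ris) / ris, 0.02)
})

test_that("closed-form well-sampled regret is monotone in S and rho", {
  expect_error(asymptotic_regret(3, 0.5), "rho")
  r <- vapply(2:6, asymptotic_regret, numeric(1), rho = 50)
  expect_true(all(diff(r) > 0))
  r2 <- vapply(c(2, 5, 20, 100), function(rho) asymptotic_regret(3, rho),
               numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("profile log-probabilities reproduce enumeration and normalize", {
  # S = 2, N = 2: three profiles with probabilities 0.4, 0.2, 0.4
  r <- exact_regret(2, 2)
  p20 <- exp(nml_log_prob(new_freq_profile(c(a = 2)), r))
  p11 <- exp(nml_log_prob(new_freq_profile(c(a = 1, b = 1)), r))
  expect_equal(p20, 0.4, tolerance = 1e-12)
  expect_equal(p11, 0.2, tolerance = 1e-12)
  expect_equal(nml_log_prob(new_freq_profile(c(a = 3)), 0), 0)
  # normalization over all profiles for S = 2..4
  for (S in 2:4) {
    N <- 12
    r <- exact_regret(S, N)
    profs <- nmlcodes:::compositions_of(N, S)
    tot <- sum(vapply(profs, function(k) {
      exp(nml_log_prob(new_freq_profile(stats::setNames(k, seq_len(S))[k > 0],
                                        n_states = S), r))
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("typical samples conserve N and both samplers agree in law", {
  profs <- sample_typical(20, 100, n_samples = 5, seed = 3)
  expect_true(all(vapply(profs, function(p) p$n_obs, integer(1)) == 100L))
  profs2 <- sample_typical(4, 12, n_samples = 50, seed = 4,
                           method = "profile_mcmc")
  expect_true(all(vapply(profs2, function(p) p$n_obs, integer(1)) == 12L))

  # same profile law from rejection and MCMC (chi-square homogeneity)
  S <- 3; N <- 12
  n_draw <- 20000
  key <- function(p) paste(sort(p$counts, decreasing = TRUE), collapse = ",")
  k1 <- vapply(sample_typical(S, N, n_draw, seed = 5), key, character(1))
  k2 <- vapply(sample_typical(S, N, n_draw, seed = 6, method = "profile_mcmc",
                              burn_in = 2000, thin = 40), key, character(1))
  lev <- union(unique(k1), unique(k2))
  tab <- rbind(table(factor(k1, lev)), table(factor(k2, lev)))
  keep <- colSums(tab) >= 10
  pval <- suppressWarnings(stats::chisq.test(tab[, keep]))$p.value
  expect_gt(pval, 0.01)
})
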