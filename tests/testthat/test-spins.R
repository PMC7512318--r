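test_that("paramagnet regret is the two-state Dirichlet regret", {
  for (N in c(1, 2, 17, 400)) {
    expect_equal(paramagnet_regret(N), exact_regret(2, N), tolerance = 1e-12)
  }
  expect_equal(paramagnet_regret(1), log(2), tolerance = 1e-12)
  expect_equal(paramagnet_regret(2), log(2.5), tolerance = 1e-12)
  # asymptotic (1/2) log(pi N / 2)
  expect_lt(abs(paramagnet_regret(1e5) - paramagnet_regret(1e5, "asymptotic")),
            0.01)
})

test_that("paramagnet samples have arcsine-distributed magnetizations", {
  xs <- paramagnet_sample(400, 2000, n_samples = 5, seed = 31)
  m <- unlist(lapply(xs, colMeans))   # 2000 single-spin draws
  ks <- suppressWarnings(
    stats::ks.test((m + 1) / 2, function(q) stats::pbeta(q, 0.5, 0.5)))
  expect_lt(unname(ks$statistic), 0.05)
  # pattern entropies obey the information inequality
  pp <- pattern_profile(xs[[1]])
  expect_lte(relevance(pp), resolution(pp) + 1e-12)
  expect_lte(resolution(pp), log(2000) + 1e-12)
})

test_that("SK likelihood reduces to known closed forms", {
  set.seed(41)
  x <- spin_sample(matrix(sample(c(-1L, 1L), 60, replace = TRUE), 20, 3))
  p0 <- sk_params(matrix(0, 3, 3), rep(0, 3))
  expect_equal(sk_loglik(x, p0), -20 * 3 * log(2), tolerance = 1e-10)
  # n = 1 at the ML field equals the single-spin maximized likelihood
  x1 <- spin_sample(matrix(c(rep(1L, 14), rep(-1L, 6)), ncol = 1))
  f1 <- sk_fit(x1, tol = 1e-10)
  expect_equal(sk_loglik(x1, f1), 14 * log(14 / 20) + 6 * log(6 / 20),
               tolerance = 1e-6)
  expect_error(sk_loglik(spin_sample(matrix(1L, 2, 21)), p0), "capped")
})

test_that("SK fit matches moments and recovers planted parameters", {
  td <- withr::local_tempdir()
  make_fixture("planted_sk", list(n = 5, N = 8000), seed = 42, dir = td)
  x <- read_spin_sample(file.path(td, "planted_sk.tsv"), "pm1")
  truth <- read_params(file.path(td, "planted_sk_params.json"))
  fit <- sk_fit(x, tol = 1e-6)
  expect_lt(attr(fit, "residual"), 1e-6)
  # recovery within a few sampling standard errors (~ 1/sqrt(N))
  expect_lt(max(abs(fit$h - truth$h)), 6 / sqrt(8000))
  expect_lt(max(abs(fit$J - truth$J)), 6 / sqrt(8000))
  # any other parameter value has lower likelihood
  other <- sk_params(truth$J, truth$h + 0.3)
  expect_lt(sk_loglik(x, other), attr(fit, "loglik"))
  # boundary sample triggers shrinkage, fit still finite
  xb <- spin_sample(matrix(1L, 10, 3))
  expect_warning(fb <- sk_fit(xb), "boundary")
  expect_true(all(is.finite(fb$h)))
})

test_that("RBM marginal likelihood equals the joint-enumeration value", {
  set.seed(43)
  pars <- rbm_params(stats::rnorm(4, sd = 0.3), stats::rnorm(3, sd = 0.3),
                     matrix(stats::rnorm(12, sd = 0.5), 4, 3))
  V <- nmlcodes:::enumerate_01(4)
  H <- nmlcodes:::enumerate_01(3)
  lj <- as.vector(outer(seq_len(16), seq_len(8), Vectorize(function(i, j) {
    sum(pars$a * V[i, ]) + sum(pars$b * H[j, ]) +
      as.numeric(t(V[i, ]) %*% pars$w %*% H[j, ])
  })))
  lZ_joint <- nmlcodes:::logsumexp(lj)
  x <- spin_sample(V[c(1, 5, 9, 16), ], "01")
  ll <- rbm_loglik(x, pars)
  # recompute with the joint Z: same marginal term, Z from both layers
  lu <- as.numeric(x %*% pars$a) + nmlcodes:::rbm_hidden_term(x, pars)
  expect_equal(ll, sum(lu) - 4 * lZ_joint, tolerance = 1e-10)
  expect_lt(ll, 0)
  # w = 0 factorizes into independent Bernoulli units
  p0 <- rbm_params(c(0.3, -0.2, 0.1, 0), rep(0, 3), matrix(0, 4, 3))
  pv <- stats::plogis(p0$a)
  ind <- sum(t(t(unclass(x)) * log(pv) + (1 - t(unclass(x))) * log(1 - pv)))
  expect_equal(rbm_loglik(x, p0), ind, tolerance = 1e-10)
  # plus-minus convention uses log 2cosh: check against direct sum for one v
  pp <- rbm_params(pars$a, pars$b, pars$w, "plus-minus")
  v <- V[7, ]
  direct <- sum(vapply(seq_len(3), function(j) {
    log(sum(exp(c(-1, 1) * (sum(v * pars$w[, j]) + pars$b[j]))))
  }, numeric(1)))
  expect_equal(unname(nmlcodes:::rbm_hidden_term(rbind(v), pp)), direct,
               tolerance = 1e-10)
})

test_that("contrastive divergence improves on the independent model", {
  td <- withr::local_tempdir()
  make_fixture("planted_rbm", list(n_v = 6, n_h = 3, N = 4000), seed = 7,
               dir = td)
  x <- read_spin_sample(file.path(td, "planted_rbm.tsv"), "01")
  fit <- rbm_fit_cd(x, n_h = 3, epochs = 60, learn_rate = 0.1, seed = 3)
  pbar <- pmin(pmax(colMeans(x), 1 / nrow(x)), 1 - 1 / nrow(x))
  ind_ll <- sum(t(t(unclass(x)) * log(pbar) +
                    (1 - t(unclass(x))) * log(1 - pbar)))
  expect_gte(attr(fit, "loglik"), ind_ll)
  # zero learning rate leaves parameters at their initialization
  f0 <- rbm_fit_cd(x, n_h = 2, epochs = 3, learn_rate = 0, seed = 9)
  expect_true(all(f0$w == 0))
  # fixed seed gives a bit-identical trajectory
  f1 <- rbm_fit_cd(x, n_h = 2, epochs = 5, learn_rate = 0.05, seed = 12)
  f2 <- rbm_fit_cd(x, n_h = 2, epochs = 5, learn_rate = 0.05, seed = 12)
  expect_identical(attr(f1, "loglik_trace"), attr(f2, "loglik_trace"))
  expect_identical(f1$w, f2$w)
  expect_error(rbm_fit_cd(spin_sample(matrix(c(-1L, 1L), 2, 2)), 2),
               "binary")
})
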