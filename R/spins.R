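#' Spin samples
#'
#' A spin sample is an `N x n` matrix with one observation (spin
#' configuration) per row. Entries are -1/+1 for paramagnet and
#' Sherrington-Kirkpatrick (SK) data, or 0/1 for RBM visible units; the
#' coding is recorded and respected by all likelihood evaluations.
#'
#' @param x matrix of spin values.
#' @param coding `"pm1"` (entries in \{-1, +1\}) or `"01"`.
#' @return Object of class `spin_sample` (the matrix, with the coding as an
#'   attribute).
#' @export
spin_sample <- function(x, coding = c("pm1", "01")) {
  coding <- match.arg(coding)
  x <- as.matrix(x)
  ok <- if (coding == "pm1") all(x %in% c(-1, 1)) else all(x %in% c(0, 1))
  if (!ok) stop(sprintf("entries must be %s",
                        if (coding == "pm1") "-1/+1" else "0/1"))
  structure(x, coding = coding, class = c("spin_sample", "matrix", "array"))
}

#' @export
print.spin_sample <- function(x, ...) {
  cat(sprintf("<spin_sample> N = %d observations of %d spins (%s coding)\n",
              nrow(x), ncol(x), attr(x, "coding")))
  invisible(x)
}

#' Magnetizations and pairwise correlations of a spin sample
#'
#' \eqn{m_i = \frac1N\sum_l s_i^{(l)}} and
#' \eqn{c_{ij} = \frac1N\sum_l s_i^{(l)} s_j^{(l)}} (so \eqn{c_{ii} = 1}
#' for -1/+1 coding).
#'
#' @param x a `spin_sample`.
#' @return List with `m` (length n) and `c` (n x n matrix).
#' @export
spin_moments <- function(x) {
  list(m = colMeans(x), c = crossprod(x) / nrow(x))
}

#' SK model parameters
#'
#' @param J symmetric coupling matrix with zero diagonal.
#' @param h field vector.
#' @return Object of class `sk_params`.
#' @export
sk_params <- function(J, h) {
  J <- as.matrix(J)
  stopifnot(nrow(J) == ncol(J), length(h) == nrow(J))
  if (any(abs(J - t(J)) > 1e-12)) stop("J must be symmetric")
  if (any(abs(diag(J)) > 1e-12)) stop("J must have zero diagonal")
  structure(list(J = J, h = as.numeric(h)), class = "sk_params")
}

# all 2^n configurations of n +/-1 spins, one per row
enumerate_pm1 <- function(n) {
  if (n > 20) stop("spin enumeration capped at n = 20")
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(g) <- NULL
  g
}

enumerate_01 <- function(n) (enumerate_pm1(n) + 1) / 2

# log-weights exp(h.s + sum_{i<j} J_ij s_i s_j) over all states
sk_state_logw <- function(states, J, h) {
  as.numeric(states %*% h + rowSums((states %*% J) * states) / 2)
}

#' Exact log-likelihood of an SK sample
#'
#' \eqn{N[\sum_i h_i m_i + \sum_{i<j} J_{ij} c_{ij} - \log Z(J,h)]}, with
#' the partition function computed by exact enumeration of all \eqn{2^n}
#' states (capped at n = 20).
#'
#' @param sample a `spin_sample` with -1/+1 coding.
#' @param params an `sk_params`.
#' @return Log-likelihood in nats.
#' @export
sk_loglik <- function(sample, params) {
  n <- ncol(sample)
  if (n > 20) stop("sk_loglik capped at n = 20")
  mom <- spin_moments(sample)
  lZ <- logsumexp(sk_state_logw(enumerate_pm1(n), params$J, params$h))
  nrow(sample) * (sum(params$h * mom$m) + sum(params$J * mom$c) / 2 - lZ)
}

#' Maximum-likelihood fit of the SK model
#'
#' Solves the moment-matching conditions
#' \eqn{\partial\phi/\partial h_i = m_i}, \eqn{\partial\phi/\partial J_{ij}
#' = c_{ij}} by damped Newton iterations with the exact (enumerated)
#' moment map and its Jacobian, the covariance of the sufficient
#' statistics.  The problem is convex, so convergence is quadratic near the
#' solution.  Sample moments on the boundary (\eqn{|m_i| = 1} or
#' \eqn{|c_{ij}| = 1}) make the ML estimate diverge; they are shrunk toward
#' zero by the factor \eqn{1 - 1/N^2} with a warning.
#'
#' @param sample a `spin_sample`, -1/+1 coding, n <= 20.
#' @param tol maximum allowed moment residual.
#' @param max_iter Newton iteration cap.
#' @return An `sk_params` with attributes `residual` (max moment mismatch)
#'   and `loglik` (exact log-likelihood at the fit).
#' @export
sk_fit <- function(sample, tol = 1e-8, max_iter = 200) {
  n <- ncol(sample)
  N <- nrow(sample)
  if (n > 20) stop("sk_fit capped at n = 20")
  mom <- spin_moments(sample)
  up <- upper.tri(mom$c)
  target <- c(mom$m, mom$c[up])
  if (any(abs(target) >= 1)) {
    warning("sample moments on the boundary; shrinking by (1 - 1/N^2)")
    target <- target * (1 - 1 / N^2)
  }
  Tm <- sk_suffstats(n)
  fit <- maxent_fit_core(target, Tm, theta0 = numeric(ncol(Tm)),
                         tol = tol, max_iter = max_iter)
  theta <- fit$theta
  h <- theta[seq_len(n)]
  J <- matrix(0, n, n)
  J[up] <- theta[-seq_len(n)]
  J <- J + t(J)
  out <- sk_params(J, h)
  attr(out, "residual") <- fit$residual
  attr(out, "loglik") <- sk_loglik(sample, out)
  out
}

# sufficient-statistic matrix over all 2^n states: columns (s_i, s_i s_j, i<j)
sk_suffstats <- function(n) {
  states <- enumerate_pm1(n)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  cbind(states, states[, pairs[, 1], drop = FALSE] *
          states[, pairs[, 2], drop = FALSE])
}

# Damped-Newton solver for the convex maximum-entropy problem
#   min_theta  logsumexp(Tm theta) - theta . target
# (exact moment matching for a discrete exponential family).  Returns the
# parameters, the final moment residual and log Z.
maxent_fit_core <- function(target, Tm, theta0, tol = 1e-8, max_iter = 200) {
  d <- ncol(Tm)
  theta <- theta0
  neglog <- function(th) logsumexp(as.numeric(Tm %*% th)) - sum(th * target)
  f_cur <- neglog(theta)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    lw <- as.numeric(Tm %*% theta)
    lZ <- logsumexp(lw)
    p <- exp(lw - lZ)
    mu <- as.numeric(crossprod(Tm, p))
    resid <- mu - target
    if (max(abs(resid)) <= tol) break
    cov <- crossprod(Tm, Tm * p) - tcrossprod(mu)
    step <- tryCatch(as.numeric(solve(cov + diag(1e-10, d), -resid)),
                     error = function(e) -resid)
    lam <- 1
    repeat {
      f_new <- neglog(theta + lam * step)
      if (f_new <= f_cur + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- theta + lam * step
    f_cur <- neglog(theta)
  }
  lw <- as.numeric(Tm %*% theta)
  list(theta = theta, residual = max(abs(resid)),
       log_Z = logsumexp(lw), converged = max(abs(resid)) <= tol)
}

#' RBM parameters
#'
#' @param a visible fields (length n_v).
#' @param b hidden fields (length n_h).
#' @param w n_v x n_h weight matrix.
#' @param hidden_unit_convention `"zero-one"` (hidden units in \{0,1\},
#'   marginalized with a softplus) or `"plus-minus"` (\{-1,+1\},
#'   log-2cosh marginalization).
#' @return Object of class `rbm_params`.
#' @export
rbm_params <- function(a, b, w,
                       hidden_unit_convention = c("zero-one", "plus-minus")) {
  hidden_unit_convention <- match.arg(hidden_unit_convention)
  w <- as.matrix(w)
  stopifnot(length(a) == nrow(w), length(b) == ncol(w),
            all(is.finite(a)), all(is.finite(b)), all(is.finite(w)))
  structure(list(a = as.numeric(a), b = as.numeric(b), w = w,
                 hidden_unit_convention = hidden_unit_convention),
            class = "rbm_params")
}

# sum_j log marginalization factor for hidden units, rows = visible configs
rbm_hidden_term <- function(V, params) {
  act <- sweep(V %*% params$w, 2, params$b, "+")
  if (params$hidden_unit_convention == "zero-one") {
    # softplus, stable for large |x|
    rowSums(pmax(act, 0) + log1p(exp(-abs(act))))
  } else {
    # log(2 cosh x) = |x| + log1p(e^{-2|x|})
    rowSums(abs(act) + log1p(exp(-2 * abs(act))))
  }
}

#' Exact log-likelihood of an RBM sample
#'
#' Hidden units are summed out analytically (softplus accumulation for
#' \{0,1\} hidden units, log-2cosh for \{-1,+1\}); the partition function is
#' computed by enumeration over the \eqn{2^{n_v}} visible states (capped at
#' n_v = 20).
#'
#' @param sample a `spin_sample` with 0/1 coding (visible units).
#' @param params an `rbm_params`.
#' @return Log-likelihood \eqn{\sum_l \log p(v^{(l)}|\theta)} in nats.
#' @export
rbm_loglik <- function(sample, params) {
  n_v <- ncol(sample)
  if (n_v > 20) stop("rbm_loglik capped at n_v = 20")
  V <- enumerate_01(n_v)
  lu_all <- as.numeric(V %*% params$a) + rbm_hidden_term(V, params)
  lZ <- logsumexp(lu_all)
  lu <- as.numeric(sample %*% params$a) + rbm_hidden_term(sample, params)
  sum(lu) - nrow(sample) * lZ
}

#' Fit an RBM by contrastive divergence
#'
#' Standard CD-k training on 0/1 data: alternating Gibbs updates between the
#' layers provide the negative statistics; parameters follow the stochastic
#' likelihood gradient.  At the sizes this package targets the exact
#' log-likelihood is computable, so it is evaluated every epoch and the
#' parameter set with the highest exact log-likelihood is returned.
#'
#' @param sample a `spin_sample` with 0/1 coding.
#' @param n_h number of hidden units.
#' @param cd_steps Gibbs alternations per gradient estimate (k in CD-k).
#' @param learn_rate learning rate.
#' @param epochs number of full-sample passes.
#' @param seed integer seed (optional).
#' @return An `rbm_params` (zero-one convention) with attribute `loglik`
#'   (best exact log-likelihood seen) and `loglik_trace`.
#' @export
rbm_fit_cd <- function(sample, n_h, cd_steps = 1, learn_rate = 0.05,
                       epochs = 100, seed = NULL) {
  if (!all(sample %in% c(0, 1))) stop("visible data must be binary 0/1")
  if (!is.null(seed)) set.seed(seed)
  V0 <- unclass(sample)
  N <- nrow(V0); n_v <- ncol(V0)
  # visible biases start at the data log-odds (the w = 0 model then equals
  # the best independent-unit fit), weights near zero
  pv0 <- pmin(pmax(colMeans(V0), 1 / N), 1 - 1 / N)
  a <- stats::qlogis(pv0)
  b <- numeric(n_h)
  w <- matrix(0, n_v, n_h)   # hidden-unit symmetry is broken by the CD noise
  sigmoid <- function(x) 1 / (1 + exp(-x))
  best <- rbm_params(a, b, w)
  best_ll <- rbm_loglik(sample, best)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ph0 <- sigmoid(sweep(V0 %*% w, 2, b, "+"))
    v <- V0
    ph <- ph0
    for (s in seq_len(cd_steps)) {
      h <- matrix(stats::rbinom(N * n_h, 1, ph), N, n_h)
      pv <- sigmoid(sweep(h %*% t(w), 2, a, "+"))
      v <- matrix(stats::rbinom(N * n_v, 1, pv), N, n_v)
      ph <- sigmoid(sweep(v %*% w, 2, b, "+"))
    }
    w <- w + learn_rate * (crossprod(V0, ph0) - crossprod(v, ph)) / N
    a <- a + learn_rate * (colMeans(V0) - colMeans(v))
    b <- b + learn_rate * (colMeans(ph0) - colMeans(ph))
    cur <- rbm_params(a, b, w)
    trace[ep] <- rbm_loglik(sample, cur)
    if (trace[ep] > best_ll) {
      best_ll <- trace[ep]
      best <- cur
    }
  }
  attr(best, "loglik") <- best_ll
  attr(best, "loglik_trace") <- trace
  best
}

#' Regret of the independent-spin (paramagnet) model
#'
#' For a single spin the NML normalizer is the one-dimensional sum over the
#' number \eqn{\ell} of up-spins,
#' \eqn{e^{\bar R} = \sum_{\ell=0}^N \binom{N}{\ell} (\ell/N)^\ell
#' (1-\ell/N)^{N-\ell}} — identical to the two-state Dirichlet model.  The
#' asymptotic form is \eqn{\bar R \simeq \frac12\log\frac{\pi N}{2}}.
#' For `n` independent spins the regret is `n` times the single-spin value.
#'
#' @param N sample size.
#' @param method `"exact"` or `"asymptotic"`.
#' @return Single-spin regret in nats.
#' @export
paramagnet_regret <- function(N, method = c("exact", "asymptotic")) {
  method <- match.arg(method)
  if (method == "exact") exact_regret(2, N) else 0.5 * log(pi * N / 2)
}

#' Draw typical samples from the paramagnet NML
#'
#' Each spin independently: the up-count \eqn{\ell_i} is drawn from the
#' exact single-spin NML law \eqn{\bar P(\ell) \propto \binom{N}{\ell}
#' (\ell/N)^\ell (1-\ell/N)^{N-\ell}} by inverse CDF, and the \eqn{\ell_i}
#' up-spins are placed uniformly at random among the `N` observations.  The
#' induced magnetization \eqn{m = 2\ell/N - 1} follows the broad arcsine
#' law \eqn{1/(\pi\sqrt{1-m^2})} for large `N` (the Jeffreys prior of the
#' model, induced on the maximum-likelihood parameter).
#'
#' @param n number of spins.
#' @param N sample size.
#' @param n_samples number of samples.
#' @param seed integer seed (optional).
#' @return List of `spin_sample` matrices (`N x n`, -1/+1 coding).
#' @export
paramagnet_sample <- function(n, N, n_samples = 1, seed = NULL) {
  stopifnot(n >= 1, N >= 1)
  if (!is.null(seed)) set.seed(seed)
  l <- 0:N
  lw <- lchoose(N, l) + ifelse(l > 0, l * log(l / N), 0) +
    ifelse(l < N, (N - l) * log((N - l) / N), 0)
  p <- exp(lw - logsumexp(lw))
  lapply(seq_len(n_samples), function(i) {
    ell <- sample(l, n, replace = TRUE, prob = p)
    x <- matrix(-1L, N, n)
    for (j in seq_len(n)) {
      if (ell[j] > 0) x[sample.int(N, ell[j]), j] <- 1L
    }
    spin_sample(x, "pm1")
  })
}

#' Frequency profile of the row patterns of a spin sample
#'
#' Treats each observed configuration (row) as an outcome and tabulates the
#' pattern counts; `n_states` is the full configuration space size
#' \eqn{2^n}.
#'
#' @param x a `spin_sample`.
#' @return A `freq_profile`.
#' @export
pattern_profile <- function(x) {
  n <- ncol(x)
  bin <- if (attr(x, "coding") == "pm1") (x + 1) / 2 else x
  id <- as.numeric(bin %*% 2^(seq_len(n) - 1))
  counts <- rle(sort(id))$lengths
  new_freq_profile(counts, n_states = 2^n)
}
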