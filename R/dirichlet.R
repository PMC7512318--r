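#' Normalized maximum likelihood for the Dirichlet (categorical) model
#'
#' The NML universal code of the model \eqn{f(s|\theta) = \theta_s} over `S`
#' outcomes assigns a whole sample of size `N` the probability proportional
#' to its maximized likelihood \eqn{\prod_s (k_s/N)^{k_s}}. Its log
#' normalizer is the regret (parametric complexity) \eqn{\bar R}. These
#' functions compute \eqn{\bar R} exactly, by saddle point, or by the
#' large-\eqn{\rho} closed form, characterize the frequency law
#' \eqn{q(k|z^*)} of typical samples, and draw typical samples.
#'
#' @name dirichlet_nml
NULL

# -- truncated series N(z) = sum_k k^k e^{-(1+z)k} / k! ----------------------

# Returns log N(z), the truncation index, and the first two moments of
# q(k|z).  The series converges for z > 0 with geometric tail ratio e^{-z};
# k_max is extended until the geometric tail bound is < 1e-12 of the partial
# sum.
partition_series <- function(z, k_start = 256L) {
  if (z <= 0) stop("series diverges: z must be > 0")
  kmax <- max(k_start, ceiling(8 / z))
  repeat {
    k <- 0:kmax
    lt <- log_bk(k) - z * k
    lZ <- logsumexp(lt)
    # tail bound: term_{kmax+1} * 1/(1 - e^{-z}) relative to partial sum
    ltail <- (log_bk(kmax + 1) - z * (kmax + 1)) - log1p(-exp(-z))
    if (ltail - lZ < log(1e-12) || kmax > 5e7) break
    kmax <- kmax * 2L
  }
  p <- exp(lt - lZ)
  m1 <- sum(p * k)
  m2 <- sum(p * k^2)
  list(log_N = lZ, k_max = kmax, mean_k = m1, var_k = m2 - m1^2, k = k, p = p)
}

#' Typical-sample frequency law q(k|z)
#'
#' The distribution \eqn{q(k|z) \propto k^k e^{-(1+z)k}/k!} over
#' \eqn{k = 0, 1, \dots} that governs the per-outcome counts of typical
#' Dirichlet-NML samples when `z` equals the saddle point \eqn{z^*(\rho)}.
#' For large \eqn{k} it behaves like \eqn{e^{-z k}} times a slowly varying
#' factor, so the count distribution is broad with cutoff \eqn{1/z}.
#'
#' @param z positive tilt parameter.
#' @param k_max optional truncation; by default chosen adaptively so the
#'   neglected tail mass is below 1e-12.
#' @return data.frame with columns `k` and `p` (probabilities summing to 1).
#' @export
q_k <- function(z, k_max = NULL) {
  if (z <= 0) stop("series diverges: z must be > 0")
  if (is.null(k_max)) {
    ps <- partition_series(z)
    return(data.frame(k = ps$k, p = ps$p))
  }
  k <- 0:k_max
  lt <- log_bk(k) - z * k
  p <- exp(lt - logsumexp(lt))
  data.frame(k = k, p = p)
}

#' Saddle point of the Dirichlet NML partition function
#'
#' Solves \eqn{\langle k \rangle_z = \rho} for \eqn{z^*(\rho)}, where the
#' average is over \eqn{q(k|z)} and \eqn{\rho = N/S} is the mean number of
#' observations per outcome.  \eqn{\langle k\rangle_z} is strictly
#' decreasing in `z`, so the root is found by bracketing and `uniroot`.
#' For \eqn{\rho \gg 1}, \eqn{z^* \simeq 1/(2\rho)}.
#'
#' @param rho positive real, \eqn{N/S}.
#' @param tol tolerance on the moment residual \eqn{|\langle k\rangle - \rho|}.
#' @return Object of class `saddle_solution`: list with `z_star`, `rho`,
#'   `phi_at_z` (\eqn{\Phi(z^*) = \rho z^* + \log N(z^*)}), `mean_k`,
#'   `var_k`, `k_max_trunc`.
#' @export
solve_saddle <- function(rho, tol = 1e-10) {
  if (rho <= 0) stop("rho must be > 0")
  g <- function(z) partition_series(z)$mean_k - rho
  lo <- 1 / (4 * max(rho, 1))   # mean too large here (z small)
  hi <- max(4, 4 * lo)
  while (g(hi) > 0) hi <- hi * 4
  while (g(lo) < 0) {
    lo <- lo / 4
    if (lo < 1e-14) stop("saddle point underflow: z* < 1e-14")
  }
  r <- stats::uniroot(g, c(lo, hi), tol = min(tol, 1e-12))
  z <- r$root
  ps <- partition_series(z)
  # Newton polish (d<k>/dz = -var_k) until the moment residual meets tol
  for (i in 1:50) {
    if (abs(ps$mean_k - rho) <= tol) break
    z <- z + (ps$mean_k - rho) / ps$var_k
    if (z <= 0) z <- r$root
    ps <- partition_series(z)
  }
  structure(
    list(z_star = z, rho = rho, phi_at_z = rho * z + ps$log_N,
         mean_k = ps$mean_k, var_k = ps$var_k, k_max_trunc = ps$k_max),
    class = "saddle_solution"
  )
}

#' @export
print.saddle_solution <- function(x, ...) {
  cat(sprintf("<saddle_solution> rho = %.6g, z* = %.6g, Phi(z*) = %.6g\n",
              x$rho, x$z_star, x$phi_at_z))
  invisible(x)
}

#' Exact regret (parametric complexity) of the Dirichlet model
#'
#' \eqn{\bar R = \log \sum_{k_1+\dots+k_S=N} \frac{N!}{\prod_s k_s!}
#' \prod_s (k_s/N)^{k_s}} computed exactly.  For `S = 2` the sum is
#' one-dimensional over the up-count and is evaluated in log space for `N`
#' up to 1e6; for general `S` (up to 6, `N` up to 60) the sum over profiles
#' is computed by an S-fold convolution of \eqn{b_k = k^k e^{-k}/k!}.
#'
#' @param S number of outcomes (states).
#' @param N sample size.
#' @return Regret in nats (0 when `S = 1`).
#' @export
exact_regret <- function(S, N) {
  stopifnot(S >= 1, N >= 1)
  if (S == 1) return(0)
  if (S == 2) {
    if (N > 1e6) stop("S = 2 exact sum capped at N = 1e6; use saddle_regret")
    l <- 0:N
    lt <- lchoose(N, l) + ifelse(l > 0, l * log(l / N), 0) +
      ifelse(l < N, (N - l) * log((N - l) / N), 0)
    return(logsumexp(lt))
  }
  if (S > 6 || N > 60)
    stop("exact enumeration capped at S <= 6, N <= 60; use saddle_regret")
  b <- exp(log_bk(0:N))
  conv <- b
  for (i in seq_len(S - 1)) {
    conv <- convolve_trunc(conv, b, N)
  }
  lgamma(N + 1) - N * log(N) + N + log(conv[N + 1])
}

# truncated linear convolution: (x * y)[0..N]
convolve_trunc <- function(x, y, N) {
  out <- numeric(N + 1)
  for (j in 0:N) {
    i <- 0:j
    out[j + 1] <- sum(x[i + 1] * y[j - i + 1])
  }
  out
}

#' Saddle-point regret of the Dirichlet model
#'
#' Gaussian saddle-point evaluation of the partition function:
#' \deqn{e^{\bar R} \simeq \frac{N!\,e^N}{N^N}\,
#'   \frac{e^{S\Phi(z^*)}}{\sqrt{2\pi S\,\mathrm{var}_k}},}
#' with \eqn{\Phi(z) = \rho z + \log N(z)} and the variance taken under
#' \eqn{q(k|z^*)}.  The factorial prefactor is evaluated by `lgamma`, not
#' Stirling, so the approximation error is the saddle expansion alone.
#'
#' By default the next-order (one-loop) cumulant correction
#' \eqn{\log[1 + \frac1S(\frac{\kappa_4}{8\kappa_2^2} -
#' \frac{5\kappa_3^2}{24\kappa_2^3})]} is added, with \eqn{\kappa_j} the
#' cumulants of \eqn{q(k|z^*)}; it reduces the small-`S` error by an order
#' of magnitude and vanishes as \eqn{S \to \infty}.
#'
#' @param S number of outcomes (\eqn{\ge 2}).
#' @param N sample size.
#' @param tol saddle solver tolerance.
#' @param correction include the one-loop cumulant correction.
#' @return Regret in nats.
#' @export
saddle_regret <- function(S, N, tol = 1e-10, correction = TRUE) {
  stopifnot(S >= 2)
  sol <- solve_saddle(N / S, tol = tol)
  r <- lgamma(N + 1) - N * log(N) + N + S * sol$phi_at_z -
    0.5 * log(2 * pi * S * sol$var_k)
  if (correction) {
    ps <- partition_series(sol$z_star)
    k <- ps$k; p <- ps$p
    m1 <- sum(p * k)
    k2 <- sum(p * (k - m1)^2)
    k3 <- sum(p * (k - m1)^3)
    k4 <- sum(p * (k - m1)^4) - 3 * k2^2
    r <- r + log(1 + (k4 / (8 * k2^2) - 5 * k3^2 / (24 * k2^3)) / S)
  }
  r
}

#' Closed-form regret for well-sampled Dirichlet models
#'
#' The \eqn{\rho \gg 1} asymptotic form
#' \eqn{\bar R \simeq (S/2)(1 + \log\rho) - (1/2)\log(2\rho)}.
#'
#' @param S number of outcomes.
#' @param rho observations per outcome, must exceed 1.
#' @return Regret in nats.
#' @export
asymptotic_regret <- function(S, rho) {
  if (rho <= 1) stop("asymptotic form requires rho > 1")
  S / 2 * (1 + log(rho)) - 0.5 * log(2 * rho)
}

#' Log-probability of a frequency profile under the Dirichlet NML
#'
#' \eqn{\log \bar P(k_1,\dots,k_S) = -\bar R + \log\frac{N!}{\prod_s k_s!}
#'  + \sum_s k_s \log(k_s/N)}; the multinomial coefficient counts the
#' samples sharing the profile.
#'
#' @param profile a `freq_profile` (zero counts may be omitted; they do not
#'   contribute).
#' @param regret the model's regret \eqn{\bar R} in nats.
#' @return Log-probability (nats).
#' @export
nml_log_prob <- function(profile, regret) {
  k <- profile$counts
  N <- profile$n_obs
  lgamma(N + 1) - sum(lgamma(k + 1)) + sum(k * log(k / N)) - regret
}

#' Draw typical samples from the Dirichlet NML
#'
#' Generates frequency profiles distributed according to the exact NML
#' profile law.  `iid_reject` exploits the saddle-point factorization:
#' counts \eqn{k_1..k_S} are drawn iid from \eqn{q(k|z^*)} and the draw is
#' kept only when \eqn{\sum_s k_s = N} — conditioning the factorized law on
#' the total reproduces the exact profile law.  `profile_mcmc` runs a
#' Metropolis chain over profiles under the exact weight, moving one unit of
#' count from a uniformly chosen occupied state to a uniformly chosen
#' recipient state.
#'
#' @param S,N model size and sample size (`N >= S` recommended, i.e.
#'   \eqn{\rho \ge 1}).
#' @param n_samples number of profiles to return.
#' @param seed integer seed (optional).
#' @param method `"iid_reject"` or `"profile_mcmc"`.
#' @param burn_in,thin chain controls for `profile_mcmc` (defaults
#'   `10*S*N` and `S*N` elementary moves).
#' @return List of `freq_profile` objects, each with `n_states = S` and
#'   counts summing to `N`.
#' @export
sample_typical <- function(S, N, n_samples = 1, seed = NULL,
                           method = c("iid_reject", "profile_mcmc"),
                           burn_in = NULL, thin = NULL) {
  method <- match.arg(method)
  stopifnot(S >= 2, N >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (method == "iid_reject") {
    sol <- solve_saddle(N / S)
    qq <- q_k(sol$z_star)
    chunk <- max(1L, floor(2e6 / S))
    out <- vector("list", n_samples)
    got <- 0L
    trials <- 0
    while (got < n_samples) {
      draws <- sample(qq$k, chunk * S, replace = TRUE, prob = qq$p)
      m <- matrix(draws, nrow = chunk, ncol = S)
      hit <- which(rowSums(m) == N)
      trials <- trials + chunk
      for (i in hit) {
        if (got >= n_samples) break
        got <- got + 1L
        out[[got]] <- new_freq_profile(m[i, ], n_states = S)
      }
      if (got == 0L && trials > 5e5)
        stop("iid_reject acceptance rate below 1e-4; use method = 'profile_mcmc'")
    }
    out
  } else {
    if (is.null(burn_in)) burn_in <- 10 * S * N
    if (is.null(thin)) thin <- S * N
    ch <- profile_chain(S, N, beta = 0, n_samples = n_samples,
                        burn_in = burn_in, thin = thin)
    lapply(ch$samples, new_freq_profile, n_states = S)
  }
}
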