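#' Model specifications
#'
#' Lightweight descriptors of the statistical models whose universal codes
#' this package can sample: Dirichlet(S), paramagnet(n), SK(n), and
#' RBM(n_v, n_h).
#'
#' @param S,n,n_v,n_h model sizes.
#' @param hidden_unit_convention see [rbm_params()].
#' @return Object of class `model_spec`.
#' @export
dirichlet_model <- function(S) {
  structure(list(kind = "dirichlet", S = S), class = "model_spec")
}

#' @rdname dirichlet_model
#' @export
paramagnet_model <- function(n) {
  structure(list(kind = "paramagnet", n = n), class = "model_spec")
}

#' @rdname dirichlet_model
#' @export
sk_model <- function(n) {
  structure(list(kind = "sk", n = n), class = "model_spec")
}

#' @rdname dirichlet_model
#' @export
rbm_model <- function(n_v, n_h,
                      hidden_unit_convention = c("zero-one", "plus-minus")) {
  structure(list(kind = "rbm", n_v = n_v, n_h = n_h,
                 hidden_unit_convention = match.arg(hidden_unit_convention)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind,
      paste(names(x)[-1], unlist(x[-1]), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Maximized log-likelihood of a spin sample given its pattern counts.
#
# For a saturated SK model (n <= 2: as many parameters as free pattern
# probabilities) the supremum over the closure of the exponential family is
# attained at the empirical pattern distribution, giving the closed form
# sum_s k_s log(k_s/N).  For larger models the ML parameters are refit
# numerically, warm-started from `state$theta`.
max_loglik_counts <- function(model, counts, N, state) {
  if (model$kind == "sk") {
    n <- model$n
    if (n <= 2) {
      k <- counts[counts > 0]
      return(list(w = sum(k * log(k / N)), state = state))
    }
    Tm <- state$Tm
    target <- as.numeric(crossprod(Tm, counts)) / N
    bnd <- 1 - 1 / N^2
    target <- pmin(pmax(target, -bnd), bnd)
    fit <- maxent_fit_core(target, Tm, state$theta, tol = 1e-8, max_iter = 60)
    raw <- as.numeric(crossprod(Tm, counts)) / N
    w <- N * (sum(fit$theta * raw) - fit$log_Z)
    list(w = w, state = modifyList(state, list(theta = fit$theta,
                                               converged = fit$converged)))
  } else {
    # RBM: exact-gradient ascent, warm-started
    fit <- rbm_refit_counts(model, counts, N, state)
    fit
  }
}

# Warm-started exact-gradient ML ascent for the RBM (visible pattern counts).
rbm_refit_counts <- function(model, counts, N, state) {
  V <- state$V
  n_v <- model$n_v; n_h <- model$n_h
  a <- state$a; b <- state$b; w <- state$w
  obs <- counts > 0
  Vo <- V[obs, , drop = FALSE]
  co <- counts[obs] / N
  act_fun <- if (model$hidden_unit_convention == "zero-one") {
    function(x) pmax(x, 0) + log1p(exp(-abs(x)))
  } else {
    function(x) abs(x) + log1p(exp(-2 * abs(x)))
  }
  mean_h <- if (model$hidden_unit_convention == "zero-one") {
    function(x) 1 / (1 + exp(-x))          # E[h|v], h in {0,1}
  } else {
    function(x) tanh(x)                    # E[h|v], h in {-1,+1}
  }
  lr <- 0.5
  ll <- function() {
    act <- sweep(V %*% w, 2, b, "+")
    lu <- as.numeric(V %*% a) + rowSums(act_fun(act))
    lZ <- logsumexp(lu)
    acto <- sweep(Vo %*% w, 2, b, "+")
    luo <- as.numeric(Vo %*% a) + rowSums(act_fun(acto))
    N * (sum(co * luo) - lZ)
  }
  cur <- ll()
  for (it in 1:200) {
    act <- sweep(V %*% w, 2, b, "+")
    lu <- as.numeric(V %*% a) + rowSums(act_fun(act))
    p <- exp(lu - logsumexp(lu))
    eh <- mean_h(act)
    acto <- sweep(Vo %*% w, 2, b, "+")
    eho <- mean_h(acto)
    ga <- as.numeric(crossprod(Vo, co)) - as.numeric(crossprod(V, p))
    gb <- as.numeric(crossprod(eho, co)) - as.numeric(crossprod(eh, p))
    gw <- crossprod(Vo, eho * co) - crossprod(V, eh * p)
    gmax <- max(abs(ga), abs(gb), abs(gw))
    if (gmax < 1e-6) break
    a2 <- a + lr * ga; b2 <- b + lr * gb; w2 <- w + lr * gw
    a_old <- a; b_old <- b; w_old <- w
    a <- a2; b <- b2; w <- w2
    new <- ll()
    if (new < cur) { a <- a_old; b <- b_old; w <- w_old; lr <- lr / 2 }
    else { cur <- new; lr <- min(lr * 1.1, 2) }
    if (lr < 1e-6) break
  }
  list(w = cur, state = modifyList(state, list(a = a, b = b, w = w,
                                               converged = gmax < 1e-3)))
}

#' Sample the universal code of an SK model or RBM by MCMC
#'
#' Metropolis chain over the space of whole samples
#' \eqn{\hat s \in \chi^N}: a proposal flips one spin of one observation and
#' is accepted with probability
#' \eqn{\min\{1, f(\hat s'|\hat\theta(\hat s')) / f(\hat s|\hat\theta(\hat
#' s))\}}, the ratio of maximized likelihoods (the regret cancels).  The
#' maximum-likelihood refit after each proposal is warm-started from the
#' current optimum; for a saturated SK model (n <= 2) the maximized
#' likelihood has the closed form \eqn{\sum_s k_s \log(k_s/N)} over pattern
#' counts and no numerical fit is needed.
#'
#' @param model an `sk_model()` or `rbm_model()` (enumeration caps apply).
#' @param N sample size.
#' @param n_chains number of independent chains.
#' @param sweeps post-burn-in sweeps per chain (one sweep = `N * n`
#'   proposed flips).
#' @param burn_in burn-in sweeps.
#' @param thin sweeps between retained samples.
#' @param seed integer seed (optional).
#' @param record `"samples"` returns thinned `spin_sample`s;
#'   `"visits"` additionally accumulates the chain's visit counts over the
#'   full sample space (only for tiny instances, \eqn{(2^n)^N \le 2^{20}}),
#'   for comparison against exact enumeration.
#' @return List of `spin_sample` objects with attributes `accept_rate`,
#'   `refit_failures`, and (when recorded) `visits`.
#' @export
nml_mcmc_sample <- function(model, N, n_chains = 1, sweeps = 100,
                            burn_in = 50, thin = 10, seed = NULL,
                            record = c("samples", "visits")) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  n <- if (model$kind == "rbm") model$n_v else model$n
  if (is.null(n)) stop("model must be sk or rbm")
  if (n > 16) stop("sample-space MCMC capped at n = 16 (pattern bookkeeping)")
  P <- 2L^n
  zero_one <- model$kind == "rbm"
  states01 <- enumerate_01(n)
  state <- list()
  if (model$kind == "sk" && n > 2) {
    state$Tm <- sk_suffstats(n)
    state$theta <- numeric(ncol(state$Tm))
  }
  if (model$kind == "rbm") {
    state$V <- states01
    state$a <- numeric(model$n_v)
    state$b <- numeric(model$n_h)
    state$w <- matrix(0, model$n_v, model$n_h)
  }
  track_visits <- record == "visits"
  if (track_visits && P^N > 2^20)
    stop("visit recording only for tiny instances ((2^n)^N <= 2^20)")

  out <- list()
  visits_total <- if (track_visits) numeric(P^N) else NULL
  acc <- 0; tot <- 0; refit_fail <- 0L
  saturated <- model$kind == "sk" && n <= 2

  for (ch in seq_len(n_chains)) {
    pid <- sample.int(P, N, replace = TRUE) - 1L    # pattern id per row
    counts <- tabulate(pid + 1L, nbins = P)
    wl <- max_loglik_counts(model, counts, N, state)
    w_cur <- wl$w; state <- wl$state
    cfg <- if (track_visits) sum(pid * P^(seq_len(N) - 1)) else NA
    flips_per_sweep <- N * n
    total_flips <- (burn_in + sweeps) * flips_per_sweep
    snap_every <- thin * flips_per_sweep
    next_snap <- burn_in * flips_per_sweep + snap_every
    block <- 50000L
    done <- 0L
    while (done < total_flips) {
      nb <- min(block, total_flips - done)
      ri <- 1L + floor(stats::runif(nb) * N)
      rj <- 1L + floor(stats::runif(nb) * n)
      ra <- log(stats::runif(nb))
      for (t in seq_len(nb)) {
        i <- ri[t]
        old <- pid[i]
        new <- bitwXor(old, bitwShiftL(1L, rj[t] - 1L))
        ko <- counts[old + 1L]; kn <- counts[new + 1L]
        if (saturated) {
          dw <- xlogx(ko - 1) - xlogx(ko) + xlogx(kn + 1) - xlogx(kn)
          accept <- ra[t] < dw
          if (accept) w_cur <- w_cur + dw  # up to the constant -N log N drift
        } else {
          counts[old + 1L] <- ko - 1L
          counts[new + 1L] <- kn + 1L
          wl <- max_loglik_counts(model, counts, N, state)
          if (!isTRUE(wl$state$converged) && !is.null(wl$state$converged)) {
            refit_fail <- refit_fail + 1L
            accept <- FALSE
          } else {
            accept <- ra[t] < wl$w - w_cur
          }
          if (accept) {
            w_cur <- wl$w; state <- wl$state
          } else {
            counts[old + 1L] <- ko
            counts[new + 1L] <- kn
          }
        }
        tot <- tot + 1
        if (accept) {
          acc <- acc + 1
          if (saturated) {
            counts[old + 1L] <- ko - 1L
            counts[new + 1L] <- kn + 1L
          }
          pid[i] <- new
          if (track_visits) cfg <- cfg + (new - old) * P^(i - 1)
        }
        done <- done + 1L
        if (track_visits && done > burn_in * flips_per_sweep)
          visits_total[cfg + 1] <- visits_total[cfg + 1] + 1
        if (done == next_snap) {
          m01 <- states01[pid + 1L, , drop = FALSE]
          x <- if (zero_one) spin_sample(m01, "01")
               else spin_sample(2L * m01 - 1L, "pm1")
          out[[length(out) + 1L]] <- x
          next_snap <- next_snap + snap_every
        }
      }
    }
  }
  attr(out, "accept_rate") <- acc / tot
  attr(out, "refit_failures") <- refit_fail
  if (track_visits) attr(out, "visits") <- visits_total
  out
}

#' Exact universal-code law on a tiny sample space
#'
#' Enumerates every ordered sample \eqn{\hat s \in \chi^N} for an SK model
#' or RBM and returns the normalized maximized-likelihood weights — the
#' exact NML law used as the oracle for [nml_mcmc_sample()].  Only feasible
#' for \eqn{(2^n)^N} up to a few thousand.
#'
#' @param model an `sk_model()` or `rbm_model()`.
#' @param N sample size.
#' @return Numeric vector of probabilities over the \eqn{(2^n)^N} ordered
#'   samples, indexed by \eqn{1 + \sum_i \mathrm{pid}_i (2^n)^{i-1}}.
#' @export
nml_exact_law <- function(model, N) {
  n <- if (model$kind == "rbm") model$n_v else model$n
  P <- 2L^n
  M <- P^N
  if (M > 2^16) stop("exact enumeration infeasible: (2^n)^N too large")
  state <- list()
  if (model$kind == "sk" && n > 2) {
    state$Tm <- sk_suffstats(n)
    state$theta <- numeric(ncol(state$Tm))
  }
  if (model$kind == "rbm") {
    state$V <- enumerate_01(n)
    state$a <- numeric(model$n_v); state$b <- numeric(model$n_h)
    state$w <- matrix(0, model$n_v, model$n_h)
  }
  lw <- numeric(M)
  memo <- new.env(parent = emptyenv())
  for (m in 0:(M - 1)) {
    rest <- m
    pid <- integer(N)
    for (i in seq_len(N)) {
      pid[i] <- rest %% P
      rest <- rest %/% P
    }
    counts <- tabulate(pid + 1L, nbins = P)
    key <- paste(counts, collapse = ",")
    got <- memo[[key]]
    if (is.null(got)) {
      got <- max_loglik_counts(model, counts, N, state)$w
      memo[[key]] <- got
    }
    lw[m + 1] <- got
  }
  p <- exp(lw - logsumexp(lw))
  p / sum(p)
}
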