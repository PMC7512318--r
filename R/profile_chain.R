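# Metropolis chain over Dirichlet frequency profiles (k_1..k_S, sum = N)
# under the tilted NML weight
#   log w(k) = -sum_s lgamma(k_s + 1) + (1 - beta) * sum_s k_s log k_s + const,
# which at beta = 0 is the exact NML profile law and for beta != 0 the
# exponentially tilted ensemble exp(N beta H[s]) * P(k).
#
# Move: one unit of count from a uniformly chosen occupied state to a
# uniformly chosen recipient state; the Hastings factor n_occ/n_occ'
# corrects for the changing number of occupied donors.
#
# Returns thinned post-burn-in profiles plus traces of the resolution and
# of max_s k_s at the snapshot times.
profile_chain <- function(S, N, beta = 0, n_samples = 1,
                          burn_in = 10 * S * N, thin = S * N,
                          init = NULL) {
  if (is.null(init)) {
    # start near a typical profile: iid draws from q(k|z*), total then
    # adjusted to N one ball at a time
    k <- tryCatch({
      qq <- q_k(solve_saddle(N / S)$z_star)
      kk <- sample(qq$k, S, replace = TRUE, prob = qq$p)
      d <- N - sum(kk)
      while (d != 0) {
        i <- sample.int(S, 1)
        if (d > 0) { kk[i] <- kk[i] + 1L; d <- d - 1 }
        else if (kk[i] > 0) { kk[i] <- kk[i] - 1L; d <- d + 1 }
      }
      kk
    }, error = function(e) {
      kk <- rep(N %/% S, S)
      rem <- N - sum(kk)
      if (rem > 0) kk[seq_len(rem)] <- kk[seq_len(rem)] + 1L
      kk
    })
  } else {
    stopifnot(length(init) == S, sum(init) == N)
    k <- as.integer(init)
  }
  occ_idx <- which(k > 0)           # occupied states, arbitrary order
  occ_pos <- integer(S)             # position of state in occ_idx (0 = empty)
  occ_pos[occ_idx] <- seq_along(occ_idx)
  n_occ <- length(occ_idx)
  kmax <- max(k)
  one_b <- 1 - beta
  # lookup tables over k = 0..N: log(k) and k log k (index k + 1)
  ltab <- c(NA_real_, log(seq_len(N)))
  xtab <- c(0, seq_len(N) * log(seq_len(N)))

  total <- burn_in + n_samples * thin
  samples <- vector("list", n_samples)
  h_trace <- numeric(n_samples)
  kmax_trace <- integer(n_samples)
  got <- 0L
  accepted <- 0
  next_snap <- burn_in + thin

  block <- 100000L
  done <- 0L
  while (done < total) {
    nb <- min(block, total - done)
    u_d <- stats::runif(nb)
    u_r <- stats::runif(nb)
    u_a <- log(stats::runif(nb))
    for (t in seq_len(nb)) {
      d <- occ_idx[1L + floor(u_d[t] * n_occ)]
      r <- 1L + floor(u_r[t] * S)
      if (r != d) {
        kd <- k[d]; kr <- k[r]
        dlw <- ltab[kd + 1L] - ltab[kr + 2L] +
          one_b * (xtab[kd] - xtab[kd + 1L] + xtab[kr + 2L] - xtab[kr + 1L])
        n_occ_new <- n_occ - (kd == 1L) + (kr == 0L)
        if (u_a[t] < dlw + ltab[n_occ + 1L] - ltab[n_occ_new + 1L]) {
          accepted <- accepted + 1
          k[d] <- kd - 1L
          k[r] <- kr + 1L
          if (kr == 0L) {           # recipient becomes occupied
            n_occ <- n_occ + 1L
            occ_idx[n_occ] <- r
            occ_pos[r] <- n_occ
          }
          if (kd == 1L) {           # donor becomes empty: swap-remove
            p <- occ_pos[d]
            last <- occ_idx[n_occ]
            occ_idx[p] <- last
            occ_pos[last] <- p
            occ_pos[d] <- 0L
            n_occ <- n_occ - 1L
          }
          if (kr + 1L > kmax) kmax <- kr + 1L
          else if (kd == kmax) kmax <- max(k)
        }
      }
      done <- done + 1L
      if (done == next_snap) {
        got <- got + 1L
        samples[[got]] <- k
        h_trace[got] <- log(N) - sum(xlogx(k)) / N
        kmax_trace[got] <- kmax
        next_snap <- next_snap + thin
      }
    }
  }
  list(samples = samples, resolution = h_trace, k_max = kmax_trace,
       accept_rate = accepted / total)
}
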