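# Independent brute-force oracles, deliberately written with different
# algorithms than the package internals.

# log of the NML normalizer by enumerating every ordered sample in S^N
brute_regret_samples <- function(S, N) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), N)))
  w <- apply(grid, 1, function(s) {
    k <- tabulate(s, S)
    prod((k[k > 0] / N)^(k[k > 0]))
  })
  log(sum(w))
}

# all partitions of N (descending parts), simple recursion
brute_partitions <- function(N, mx = N) {
  if (N == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(N, mx))) {
    for (rest in brute_partitions(N - p, p)) {
      out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

# entropies of a positive-count vector, direct formulas
brute_entropies <- function(k) {
  N <- sum(k)
  hs <- -sum(k / N * log(k / N))
  tk <- table(k)
  w <- as.numeric(names(tk)) * as.numeric(tk) / N
  hk <- -sum(w * log(w))
  c(hs = hs, hk = hk)
}

# random partition of N (collapse of a random composition)
random_partition <- function(N, max_parts = 8) {
  s <- sample.int(max_parts, N, replace = TRUE)
  as.integer(rle(sort(s))$lengths)
}

# exact two-state NML profile law over the up-count l = 0..N
brute_two_state_law <- function(N, beta = 0) {
  l <- 0:N
  lw <- lchoose(N, l) + ifelse(l > 0, l * log(l / N), 0) +
    ifelse(l < N, (N - l) * log((N - l) / N), 0)
  H <- -(ifelse(l > 0, l / N * log(l / N), 0) +
           ifelse(l < N, (N - l) / N * log((N - l) / N), 0))
  lt <- lw + N * beta * H
  p <- exp(lt - max(lt))
  list(l = l, p = p / sum(p), H = H, log_w = lw)
}

# exact NML law over ordered samples for a saturated pairwise spin model:
# the maximized likelihood is prod_s (k_s/N)^(k_s) over pattern counts
brute_saturated_spin_law <- function(n, N) {
  P <- 2^n
  M <- P^N
  w <- numeric(M)
  for (m in 0:(M - 1)) {
    rest <- m
    pid <- integer(N)
    for (i in seq_len(N)) {
      pid[i] <- rest %% P
      rest <- rest %/% P
    }
    k <- tabulate(pid + 1L, nbins = P)
    k <- k[k > 0]
    w[m + 1] <- prod((k / N)^k)
  }
  w / sum(w)
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
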