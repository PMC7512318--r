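# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(k^k e^{-k} / k!) with the 0^0 = 1 convention; b_k <= 1 for all k
log_bk <- function(k) {
  out <- k * log(pmax(k, 1)) - k - lgamma(k + 1)
  out[k == 0] <- 0
  out
}

# x log x with 0 log 0 := 0
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
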