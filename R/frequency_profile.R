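#' Frequency profile of a sample
#'
#' Tabulates a sample of discrete observations into its frequency profile:
#' the count \eqn{k_s} of each observed outcome, the degeneracy spectrum
#' \eqn{m_k} (number of outcomes observed exactly \eqn{k} times), the sample
#' size \eqn{N} and, when known, the cardinality \eqn{S} of the outcome space.
#' Unobserved outcomes have \eqn{k_s = 0} and do not enter the degeneracies.
#'
#' @param sample vector of observations (any atomic type; coerced to character
#'   labels) or, for multivariate observations, a matrix with one observation
#'   per row.
#' @param n_states cardinality of the outcome space including unobserved
#'   outcomes, or `NA` when unknown.
#' @return An object of class `freq_profile`: a list with elements `counts`
#'   (named integer vector over observed outcomes), `m_k` (named integer
#'   vector, names are the distinct counts \eqn{k}), `n_obs` and `n_states`.
#' @examples
#' fp <- frequency_profile(c("a", "a", "b", "c"))
#' resolution(fp)
#' relevance(fp)
#' @export
frequency_profile <- function(sample, n_states = NA) {
  if (is.matrix(sample)) {
    sample <- apply(sample, 1L, paste, collapse = " ")
  }
  if (length(sample) == 0L) stop("empty sample")
  counts <- table(sample)
  new_freq_profile(stats::setNames(as.integer(counts), names(counts)), n_states)
}

#' Build a frequency profile from counts
#'
#' @param counts non-negative integer vector of per-outcome counts (zero
#'   entries are allowed and are dropped from the degeneracies); names, if
#'   present, label the outcomes.
#' @param n_states outcome-space cardinality `S`, or `NA` if unknown. When
#'   given it must be at least the number of outcomes with positive count.
#' @return A `freq_profile` object.
#' @export
new_freq_profile <- function(counts, n_states = NA) {
  if (length(counts) == 0L) stop("empty sample")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(names(counts)))
    names(counts) <- paste0("s", seq_along(counts))
  observed <- counts[counts > 0]
  if (length(observed) == 0L) stop("empty sample")
  if (!is.na(n_states) && n_states < length(observed))
    stop("n_states smaller than number of observed outcomes")
  mk <- table(observed)
  structure(
    list(
      counts = observed,
      m_k = stats::setNames(as.integer(mk), names(mk)),
      n_obs = as.integer(sum(observed)),
      n_states = n_states
    ),
    class = "freq_profile"
  )
}

#' @export
print.freq_profile <- function(x, ...) {
  cat(sprintf(
    "<freq_profile> N = %d, observed outcomes = %d, S = %s\n",
    x$n_obs, length(x$counts),
    if (is.na(x$n_states)) "unknown" else format(x$n_states)
  ))
  cat(sprintf("  resolution %.6g nats, relevance %.6g nats\n",
              resolution(x), relevance(x)))
  invisible(x)
}

#' Resolution of a sample
#'
#' The Shannon entropy of the empirical outcome frequencies,
#' \eqn{\hat H[s] = -\sum_s (k_s/N)\log(k_s/N)}, in nats. It measures the
#' number of nats per observation needed to encode the sample at its own
#' level of detail: 0 for a constant sample, \eqn{\log N} when all
#' observations are distinct.
#'
#' @param profile a `freq_profile`.
#' @return Entropy in nats.
#' @export
resolution <- function(profile) {
  k <- profile$counts
  n <- profile$n_obs
  p <- k / n
  -sum(p * log(p))
}

#' Relevance of a sample
#'
#' The entropy of the frequency-of-frequencies,
#' \eqn{\hat H[k] = -\sum_k (k m_k/N) \log(k m_k/N)}, in nats: the portion of
#' the resolution that is informative about the generative process. Always
#' satisfies \eqn{0 \le \hat H[k] \le \hat H[s]}.
#'
#' @param profile a `freq_profile`.
#' @return Entropy in nats.
#' @export
relevance <- function(profile) {
  k <- as.numeric(names(profile$m_k))
  m <- profile$m_k
  w <- k * m / profile$n_obs
  -sum(w * log(w))
}

#' Coding cost of a sample under its universal code
#'
#' Total cost, in nats, of encoding the whole sample with the NML code of a
#' model whose maximized likelihood reproduces the empirical frequencies:
#' \eqn{N \hat H[s] + \bar R}, where \eqn{\bar R} is the model's regret
#' (parametric complexity).
#'
#' @param profile a `freq_profile`.
#' @param regret regret \eqn{\bar R \ge 0} in nats.
#' @return Coding cost in nats.
#' @export
coding_cost <- function(profile, regret) {
  if (regret < 0) stop("regret must be non-negative")
  profile$n_obs * resolution(profile) + regret
}

#' Resolution/relevance of random ball-in-box allocations
#'
#' Baseline curve for the resolution-relevance plane: for each number of
#' boxes `L`, `N` balls are dropped uniformly at random into the `L` boxes
#' and the resolution and relevance of the resulting occupancy profile are
#' averaged over `reps` replicates. Random samples trace a curve that stays
#' well below the maximally-informative-sample frontier.
#'
#' @param N number of balls (observations).
#' @param L_list integer vector of box counts.
#' @param reps replicates per `L`.
#' @param seed integer seed (optional).
#' @return A data.frame with columns `L`, `resolution`, `relevance`, `norm`
#'   (the \eqn{\log N} normalizer).
#' @export
random_baseline <- function(N, L_list, reps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (reps < 1) stop("reps must be >= 1")
  res <- lapply(L_list, function(L) {
    if (L < 1) stop("L must be >= 1")
    hs <- numeric(reps)
    hk <- numeric(reps)
    for (r in seq_len(reps)) {
      draws <- sample.int(L, N, replace = TRUE)
      k <- rle(sort(draws))$lengths
      fp <- new_freq_profile(k, n_states = L)
      hs[r] <- resolution(fp)
      hk[r] <- relevance(fp)
    }
    c(resolution = mean(hs), relevance = mean(hk))
  })
  out <- do.call(rbind, res)
  data.frame(L = L_list, resolution = out[, 1], relevance = out[, 2],
             norm = log(N))
}
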