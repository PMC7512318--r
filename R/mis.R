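#' Enumerate integer partitions
#'
#' All partitions of `N` into positive parts, in non-increasing part order.
#' Each partition is a candidate frequency profile (the multiset of positive
#' counts of an `N`-observation sample), so enumerating partitions enumerates
#' every attainable (resolution, relevance) pair at sample size `N`.
#'
#' @param N positive integer (capped at 60; the partition count grows
#'   sub-exponentially but the list becomes large).
#' @return List of integer vectors.
#' @keywords internal
partitions_of <- function(N) {
  stopifnot(N >= 1)
  if (N > 60) stop("partition enumeration capped at N = 60")
  # parts(n, max): partitions of n with parts <= max
  memo <- new.env(parent = emptyenv())
  parts <- function(n, mx) {
    if (n == 0L) return(list(integer(0)))
    key <- paste(n, mx)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- list()
    for (p in seq_len(min(n, mx))) {
      for (rest in parts(n - p, p)) out[[length(out) + 1L]] <- c(p, rest)
    }
    memo[[key]] <- out
    out
  }
  parts(N, N)
}

entropy_pair_from_parts <- function(k, N) {
  # k: positive counts summing to N; returns c(H_s, H_k)
  p <- k / N
  hs <- -sum(p * log(p))
  tk <- rle(sort(k))
  w <- tk$values * tk$lengths / N
  hk <- -sum(w * log(w))
  c(hs, hk)
}

#' Maximally-informative-sample (MIS) frontier
#'
#' The frontier of maximal relevance \eqn{\hat H[k]} at fixed resolution
#' \eqn{\hat H[s]} for samples of size `N`. Two constructions are available:
#'
#' * `mode = "powerlaw"`: the variational solution, a power-law degeneracy
#'   profile \eqn{m_k = c\,k^{-1-\mu}} whose support is truncated at the
#'   largest `k` with \eqn{m_k \ge 1} (fractional states below one are
#'   unphysical and would violate \eqn{\hat H[k] \le \hat H[s]}); the
#'   normalization `c` enforces \eqn{\sum_k k\,m_k = N}. Sweeping the
#'   trade-off slope \eqn{\mu} traces the frontier; \eqn{\mu = 1} is the
#'   Zipf point.
#' * `mode = "exact"`: brute-force maximization of \eqn{\hat H[k]} over all
#'   integer partitions of `N` (capped at `N <= 60`).
#'
#' @param N sample size (\eqn{\ge 2}).
#' @param mu_grid positive (or > -1) trade-off slopes for powerlaw mode;
#'   default covers \eqn{\mu \in (-0.95, 20)}.
#' @param mode `"powerlaw"` or `"exact"`.
#' @return An object of class `mis_curve`: list with `points` (data.frame
#'   `H_s`, `H_k`, `mu`, `c`), `N`, `mode`.
#' @export
mis_frontier <- function(N, mu_grid = NULL, mode = c("powerlaw", "exact")) {
  mode <- match.arg(mode)
  if (N < 2) stop("N must be >= 2")
  if (mode == "powerlaw") {
    if (is.null(mu_grid)) {
      mu_grid <- c(seq(-0.95, -0.05, by = 0.05),
                   exp(seq(log(0.05), log(20), length.out = 60)))
    }
    rows <- lapply(mu_grid, function(mu) {
      sol <- powerlaw_profile(N, mu)
      if (is.null(sol)) return(NULL)
      w <- sol$k * sol$m / N
      hs <- log(N) - sum(w * log(sol$k))
      hk <- -sum(w * log(w))
      data.frame(H_s = hs, H_k = min(hk, hs), mu = mu, c = sol$c)
    })
    pts <- do.call(rbind, rows)
    pts <- pts[order(pts$H_s), , drop = FALSE]
  } else {
    if (N > 60)
      stop("exact enumeration capped at N = 60; use mode = 'powerlaw'")
    parts <- partitions_of(N)
    hp <- t(vapply(parts, entropy_pair_from_parts, numeric(2), N = N))
    # max H_k at each attained H_s, then the non-dominated upper envelope
    hs <- round(hp[, 1], 12)
    agg <- tapply(hp[, 2], hs, max)
    pts <- data.frame(H_s = as.numeric(names(agg)), H_k = as.numeric(agg))
    pts <- pts[order(pts$H_s), , drop = FALSE]
    slope <- c(NA, diff(pts$H_k) / pmax(diff(pts$H_s), .Machine$double.eps))
    pts$mu <- -slope
    pts$c <- NA_real_
  }
  rownames(pts) <- NULL
  hull <- NULL
  if (mode == "exact") {
    # concave majorant of the attainable set (with the origin): the
    # integer-N analogue of the smooth large-N frontier
    hull <- upper_concave_hull(c(0, pts$H_s), c(0, pts$H_k))
  }
  structure(list(points = pts, hull = hull, N = N, mode = mode),
            class = "mis_curve")
}

# Andrew's monotone-chain upper hull -> data.frame(H_s, H_k)
upper_concave_hull <- function(x, y) {
  ord <- order(x, -y)
  x <- x[ord]; y <- y[ord]
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_along(x)) {
    while (length(hx) >= 2) {
      m <- length(hx)
      cross <- (hx[m] - hx[m - 1]) * (y[i] - hy[m - 1]) -
        (hy[m] - hy[m - 1]) * (x[i] - hx[m - 1])
      if (cross >= 0) { hx <- hx[-m]; hy <- hy[-m] } else break
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  data.frame(H_s = hx, H_k = hy)
}

# Solve m_k = c k^(-1-mu) on k = 1..kmax with kmax the largest k where
# m_k >= 1, c fixed by sum k m_k = N.  Fixed-point iteration on (c, kmax).
powerlaw_profile <- function(N, mu) {
  kmax <- N
  for (it in 1:200) {
    k <- seq_len(kmax)
    c0 <- N / sum(k^(-mu))
    km <- if (1 + mu > 0) min(N, max(1, floor(c0^(1 / (1 + mu))))) else N
    if (km == kmax) break
    kmax <- km
  }
  k <- seq_len(kmax)
  c0 <- N / sum(k^(-mu))
  m <- c0 * k^(-1 - mu)
  list(k = k, m = m, c = c0)
}

#' Evaluate the MIS frontier at a given resolution
#'
#' Interpolates the frontier curve at resolution `H0` (nats).  Exact-mode
#' curves are evaluated on their concave majorant.  Below the curve's range
#' the frontier is the diagonal \eqn{\hat H[k] = \hat H[s]} (attained by
#' profiles whose positive counts are all distinct), and the returned value
#' is always capped at `H0`.
#'
#' @param curve a `mis_curve`.
#' @param H0 resolution value(s) in nats, in \eqn{[0, \log N]}.
#' @return Maximal relevance (nats) at each `H0`.
#' @export
frontier_value <- function(curve, H0) {
  pts <- if (!is.null(curve$hull)) curve$hull else curve$points
  f <- stats::approx(pts$H_s, pts$H_k, xout = H0, rule = 2, ties = max)$y
  pmin(H0, f)
}

#' @export
print.mis_curve <- function(x, ...) {
  cat(sprintf("<mis_curve> N = %d, mode = %s, %d points\n",
              x$N, x$mode, nrow(x$points)))
  invisible(x)
}
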