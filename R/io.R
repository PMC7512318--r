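#' Read a count table
#'
#' Reads a two-column tab-separated file `outcome<TAB>count` (header
#' optional, UTF-8) into a [frequency profile][frequency_profile], for
#' rank-frequency and resolution/relevance analysis of empirical data such
#' as species-abundance or regulon-size tables.
#'
#' @param path file path.
#' @param n_states outcome-space cardinality if known (`NA` otherwise).
#' @return A `freq_profile`.
#' @export
read_count_table <- function(path, n_states = NA) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty count table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- parts[[1]]
  start <- 1L
  if (length(first) == 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
    start <- 2L  # header row
    if (length(lines) == 1L) stop("empty count table: ", path)
  }
  labs <- character(0); cnts <- numeric(0)
  for (i in start:length(parts)) {
    p <- parts[[i]]
    if (length(p) != 2)
      stop(sprintf("malformed line %d in %s: expected 'outcome<TAB>count'", i, path))
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v) || v != round(v) || v <= 0)
      stop(sprintf("non-integer or non-positive count on line %d in %s", i, path))
    labs <- c(labs, p[1]); cnts <- c(cnts, v)
  }
  if (anyDuplicated(labs))
    stop("duplicate outcome label: ", labs[duplicated(labs)][1])
  new_freq_profile(stats::setNames(as.integer(cnts), labs), n_states)
}

#' Write a frequency profile as a count table
#'
#' @param profile a `freq_profile`.
#' @param path output path.
#' @param header write a header line.
#' @export
write_count_table <- function(profile, path, header = TRUE) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (header) writeLines("outcome\tcount", con)
  writeLines(paste(names(profile$counts), profile$counts, sep = "\t"), con)
  invisible(path)
}

#' Rank-frequency table
#'
#' Orders the outcomes of a profile by decreasing count; straight lines in
#' the log-log rank plot indicate power-law frequency distributions
#' (slope \eqn{-1/\mu}).
#'
#' @param profile a `freq_profile`.
#' @return data.frame with columns `rank`, `outcome`, `count`.
#' @export
rank_table <- function(profile) {
  ord <- order(profile$counts, decreasing = TRUE)
  data.frame(rank = seq_along(ord),
             outcome = names(profile$counts)[ord],
             count = as.integer(profile$counts[ord]),
             row.names = NULL)
}

#' Export a rank plot as TSV
#'
#' Writes `rank<TAB>frequency`, sorted by descending frequency.
#'
#' @param profile a `freq_profile`.
#' @param path output path.
#' @export
write_rank_table <- function(profile, path) {
  rt <- rank_table(profile)
  utils::write.table(rt[, c("rank", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("rank", "frequency"))
  invisible(path)
}

#' Read / write spin samples
#'
#' Whitespace-separated matrix files, one observation per row: -1/+1
#' integers for paramagnet and SK samples, 0/1 for RBM visible units.
#'
#' @param path file path.
#' @param coding `"pm1"` or `"01"`.
#' @export
read_spin_sample <- function(path, coding = c("pm1", "01")) {
  coding <- match.arg(coding)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  spin_sample(m, coding)
}

#' @rdname read_spin_sample
#' @param x a `spin_sample`.
#' @export
write_spin_sample <- function(x, path) {
  utils::write.table(unclass(x), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize fitted parameters to JSON
#'
#' SK parameters are stored as the upper-triangle of `J` (row-major) plus
#' `h`; RBM parameters as `a`, `b` and row-major `w`, with the hidden-unit
#' convention flag.
#'
#' @param params an `sk_params` or `rbm_params`.
#' @param path output path.
#' @export
write_params <- function(params, path) {
  obj <- if (inherits(params, "sk_params")) {
    n <- length(params$h)
    list(model = "sk", n = n, h = params$h,
         J_upper = params$J[upper.tri(params$J)])
  } else if (inherits(params, "rbm_params")) {
    list(model = "rbm", n_v = length(params$a), n_h = length(params$b),
         a = params$a, b = params$b, w = as.vector(t(params$w)),
         hidden_unit_convention = params$hidden_unit_convention)
  } else stop("unsupported parameter object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$model == "sk") {
    n <- obj$n
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- obj$J_upper
    sk_params(J + t(J), obj$h)
  } else if (obj$model == "rbm") {
    w <- matrix(obj$w, obj$n_v, obj$n_h, byrow = TRUE)
    rbm_params(obj$a, obj$b, w, obj$hidden_unit_convention)
  } else stop("unknown model in ", path)
}

#' Generate test fixtures
#'
#' Writes synthetic data files with a known statistical structure plus a
#' manifest JSON recording kind, parameters and seed:
#'
#' * `balls`: `N` balls dropped uniformly into `L` boxes -> count table.
#' * `powerlaw`: degeneracy profile \eqn{m_k \approx c k^{-1-\mu}} -> count
#'   table whose rank plot has slope \eqn{\approx -1/\mu}.
#' * `planted_sk`: sample of size `N` from an SK model with random
#'   couplings (`J_sd/sqrt(n)`) and fields (`h_sd`) -> spin file.
#' * `planted_rbm`: sample from a random RBM -> 0/1 spin file.
#'
#' @param kind fixture kind.
#' @param params named list of parameters for the kind (see details).
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
make_fixture <- function(kind = c("balls", "powerlaw", "planted_sk", "planted_rbm"),
                         params, seed, dir) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data_path <- file.path(dir, paste0(kind, ".tsv"))
  if (kind == "balls") {
    N <- params$N; L <- params$L
    k <- rle(sort(sample.int(L, N, replace = TRUE)))$lengths
    write_count_table(new_freq_profile(k, n_states = L), data_path)
  } else if (kind == "powerlaw") {
    # rank-based construction: counts k_r = floor(C r^(-1/mu)), equivalent
    # to the degeneracy law m_k ~ c k^(-1-mu) but without a truncation
    # artifact at the top of the rank plot
    N <- params$N; mu <- params$mu
    total <- function(C) {
      r <- seq_len(max(1, floor(C^mu)))
      sum(floor(C * r^(-1 / mu)))
    }
    lo <- 1; hi <- N
    while (hi - lo > 1e-6 * hi) {
      mid <- (lo + hi) / 2
      if (total(mid) > N) hi <- mid else lo <- mid
    }
    r <- seq_len(max(1, floor(lo^mu)))
    counts <- floor(lo * r^(-1 / mu))
    counts <- counts[counts >= 1]
    counts <- c(counts, rep(1L, N - sum(counts)))  # pad tail singletons
    write_count_table(new_freq_profile(counts), data_path)
  } else if (kind == "planted_sk") {
    n <- params$n; N <- params$N
    J_sd <- if (is.null(params$J_sd)) 0.5 else params$J_sd
    h_sd <- if (is.null(params$h_sd)) 0.2 else params$h_sd
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- stats::rnorm(n * (n - 1) / 2, sd = J_sd / sqrt(n))
    J <- J + t(J)
    h <- stats::rnorm(n, sd = h_sd)
    states <- enumerate_pm1(n)
    lw <- sk_state_logw(states, J, h)
    p <- exp(lw - logsumexp(lw))
    idx <- sample.int(nrow(states), N, replace = TRUE, prob = p)
    write_spin_sample(spin_sample(states[idx, , drop = FALSE], "pm1"), data_path)
    write_params(sk_params(J, h), file.path(dir, "planted_sk_params.json"))
  } else {
    n_v <- params$n_v; n_h <- params$n_h; N <- params$N
    w_sd <- if (is.null(params$w_sd)) 0.7 else params$w_sd
    pars <- rbm_params(stats::rnorm(n_v, sd = 0.2), stats::rnorm(n_h, sd = 0.2),
                       matrix(stats::rnorm(n_v * n_h, sd = w_sd), n_v, n_h))
    V <- enumerate_01(n_v)
    lu <- as.numeric(V %*% pars$a) + rbm_hidden_term(V, pars)
    p <- exp(lu - logsumexp(lu))
    idx <- sample.int(nrow(V), N, replace = TRUE, prob = p)
    write_spin_sample(spin_sample(V[idx, , drop = FALSE], "01"), data_path)
    write_params(pars, file.path(dir, "planted_rbm_params.json"))
  }
  manifest <- file.path(dir, paste0(kind, "_manifest.json"))
  jsonlite::write_json(list(kind = kind, params = params, seed = seed),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, manifest))
}
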