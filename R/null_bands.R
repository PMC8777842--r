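# Turn a frequency-model spec into a draw function n -> p.
# Accepted: a function(n); a single numeric (fixed p); a numeric vector
# (resampled with replacement); NULL with a pairs table (empirical
# control-pool SNP-index distribution truncated to [0.05, 0.95]).
resolve_freq_model <- function(freq_model, pairs = NULL) {
  if (is.function(freq_model)) return(freq_model)
  if (is.numeric(freq_model) && length(freq_model) == 1) {
    p0 <- freq_model
    stopifnot(p0 >= 0, p0 <= 1)
    return(function(n) rep(p0, n))
  }
  if (is.numeric(freq_model)) {
    vals <- freq_model
    if (all(vals %in% c(0, 1))) {
      stop("degenerate frequency model: all values are 0 or 1", call. = FALSE)
    }
    return(function(n) sample(vals, n, replace = TRUE))
  }
  if (is.null(freq_model)) {
    if (is.null(pairs)) stop("freq_model is NULL and no pairs table was supplied", call. = FALSE)
    check_cols(pairs, "control_index", "pairs")
    vals <- pairs$control_index
    vals <- vals[vals >= 0.05 & vals <= 0.95]
    if (length(vals) < 10) {
      stop("degenerate frequency model: fewer than 10 control SNP indices in [0.05, 0.95]",
           call. = FALSE)
    }
    return(function(n) sample(vals, n, replace = TRUE))
  }
  stop("freq_model must be a function, a numeric, or NULL", call. = FALSE)
}

# Core two-stage null sampler: n draws of delta = case index - control index
# for one (case_depth, control_depth) pair under a common population
# frequency p per draw.
draw_null_delta <- function(n, case_depth, control_depth, n_per_pool,
                            draw_p, seq_error = 0) {
  p <- draw_p(n)
  two_n <- 2L * n_per_pool
  f_case <- stats::rbinom(n, two_n, p) / two_n
  f_ctrl <- stats::rbinom(n, two_n, p) / two_n
  pe <- function(f) f * (1 - seq_error) + (1 - f) * seq_error
  a_case <- stats::rbinom(n, case_depth, pe(f_case))
  a_ctrl <- stats::rbinom(n, control_depth, pe(f_ctrl))
  a_case / case_depth - a_ctrl / control_depth
}

#' Monte-Carlo null distribution of the delta SNP index at one site
#'
#' Simulates the no-QTL null for a single SNP with given case and control
#' read depths: per replicate, a common population frequency `p` is drawn
#' from `freq_model`, both pools draw alternate haplotype counts
#' `Binomial(2 n_per_pool, p)`, and read counts are
#' `Binomial(depth, pool fraction)` (optionally perturbed by a per-read
#' miscall rate). Returns the replicate deltas and the empirical 0.5%,
#' 2.5%, 97.5% and 99.5% quantiles, i.e. the pointwise 99% and 95% bands.
#'
#' @param case_depth,control_depth Read depths (>= 1) of the site in the two
#'   pools.
#' @param n_per_pool Diploid individuals per pool (default 20).
#' @param freq_model Population-frequency model: a `function(n)` returning
#'   `n` frequency draws, a single numeric (fixed `p`), or a numeric vector
#'   resampled with replacement. Default: Uniform(0, 1).
#' @param n_reps Monte-Carlo replicates (>= 1000).
#' @param seed Optional seed for reproducible bands.
#' @param seq_error Per-read miscall probability (default 0).
#' @return A list with `delta` (numeric vector of replicates) and
#'   `quantiles` (named vector `q005`, `q025`, `q975`, `q995`).
#' @export
simulate_null_delta <- function(case_depth, control_depth, n_per_pool = 20,
                                freq_model = stats::runif, n_reps = 10000,
                                seed = NULL, seq_error = 0) {
  stopifnot(case_depth >= 1, control_depth >= 1, n_reps >= 1000)
  draw_p <- resolve_freq_model(freq_model)
  probe <- draw_p(1000L)
  if (all(probe %in% c(0, 1))) {
    stop("degenerate frequency model: all draws are 0 or 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- draw_null_delta(n_reps, case_depth, control_depth, n_per_pool, draw_p, seq_error)
  q <- stats::quantile(d, probs = c(0.005, 0.025, 0.975, 0.995), names = FALSE)
  list(delta = d, quantiles = stats::setNames(q, c("q005", "q025", "q975", "q995")))
}

#' Attach null confidence bands to sliding-window statistics
#'
#' For every non-empty window, simulates the null distribution of the window
#' mean delta SNP index using the window's actual per-SNP depth pairs: each
#' member SNP is simulated independently under the two-stage binomial null
#' (common population frequency per replicate) and the per-replicate window
#' mean is formed, exactly mirroring how the observed trendline averages
#' per-SNP deltas. The stored bands are the empirical 95% (`ci95_*`) and
#' 99% (`ci99_*`) pointwise quantiles.
#'
#' @param window_stats Output of [window_mean_delta()].
#' @param pairs The paired-delta table the windows were computed from
#'   (supplies per-SNP depths, and the default frequency model).
#' @param n_per_pool Diploid individuals per pool (default 20).
#' @param freq_model See [simulate_null_delta()]; `NULL` (default) resamples
#'   the empirical control-pool SNP-index distribution truncated to
#'   `[0.05, 0.95]`.
#' @param n_reps Monte-Carlo replicates per window (default 2000).
#' @param seed Optional seed.
#' @param seq_error Per-read miscall probability (default 0).
#' @return `window_stats` with added columns `ci95_lo`, `ci95_hi`,
#'   `ci99_lo`, `ci99_hi` (`NA` for empty windows); attributes `n_reps` and
#'   `seed` record the simulation settings.
#' @export
window_null_bands <- function(window_stats, pairs, n_per_pool = 20,
                              freq_model = NULL, n_reps = 2000, seed = NULL,
                              seq_error = 0) {
  check_cols(window_stats, c("chrom", "win_start", "win_end", "n_snps"), "window_stats")
  check_cols(pairs, c("chrom", "pos", "case_depth", "control_depth"), "pairs")
  draw_p <- resolve_freq_model(freq_model, pairs)
  if (!is.null(seed)) set.seed(seed)
  pairs <- pairs[order(pairs$chrom, pairs$pos), ]
  ws <- window_stats
  for (col in c("ci95_lo", "ci95_hi", "ci99_lo", "ci99_hi")) ws[[col]] <- NA_real_
  for (ch in unique(ws$chrom)) {
    p <- pairs[pairs$chrom == ch, , drop = FALSE]
    wi <- which(ws$chrom == ch)
    if (nrow(p) == 0) next
    n <- nrow(p)
    two_n <- 2L * n_per_pool
    # per-SNP replicate matrix of null deltas (n x n_reps); SNPs independent
    P <- matrix(draw_p(n * n_reps), n, n_reps)
    Fc <- matrix(stats::rbinom(n * n_reps, two_n, P), n, n_reps) / two_n
    Fn <- matrix(stats::rbinom(n * n_reps, two_n, P), n, n_reps) / two_n
    if (seq_error > 0) {
      Fc <- Fc * (1 - seq_error) + (1 - Fc) * seq_error
      Fn <- Fn * (1 - seq_error) + (1 - Fn) * seq_error
    }
    rm(P)
    D <- matrix(stats::rbinom(n * n_reps, p$case_depth, Fc), n, n_reps) / p$case_depth -
      matrix(stats::rbinom(n * n_reps, p$control_depth, Fn), n, n_reps) / p$control_depth
    rm(Fc, Fn)
    C <- apply(D, 2, cumsum)
    rm(D)
    if (n == 1) C <- matrix(C, nrow = 1)
    C <- rbind(0, C)
    lo <- findInterval(ws$win_start[wi] - 0.5, p$pos)
    hi <- findInterval(ws$win_end[wi] - 0.5, p$pos)
    for (j in seq_along(wi)) {
      k <- hi[j] - lo[j]
      if (k == 0) next
      means <- (C[hi[j] + 1, ] - C[lo[j] + 1, ]) / k
      q <- stats::quantile(means, probs = c(0.005, 0.025, 0.975, 0.995), names = FALSE)
      ws$ci99_lo[wi[j]] <- q[1]
      ws$ci95_lo[wi[j]] <- q[2]
      ws$ci95_hi[wi[j]] <- q[3]
      ws$ci99_hi[wi[j]] <- q[4]
    }
  }
  attr(ws, "n_reps") <- n_reps
  attr(ws, "seed") <- seed
  ws
}
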