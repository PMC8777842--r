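#' Match two contrasts at shared SNPs
#'
#' Inner-joins the paired-delta tables of two case/control contrasts (both
#' built against the same control pool) on `(chrom, pos, ref, alt)`, giving
#' one row per SNP with both contrasts' delta SNP indices. This is the
#' paired sample underlying the region-level signed-rank comparison.
#'
#' @param pairs_a,pairs_b Paired-delta tables (see [pair_pools()]).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `delta_a`,
#'   `delta_b`, sorted by position, with attribute `match_report` holding
#'   per-contrast and matched counts.
#' @export
match_contrasts <- function(pairs_a, pairs_b) {
  check_cols(pairs_a, c(snp_key, "delta"), "pairs_a")
  check_cols(pairs_b, c(snp_key, "delta"), "pairs_b")
  check_unique_keys(pairs_a, "pairs_a")
  check_unique_keys(pairs_b, "pairs_b")
  a <- pairs_a[, c(snp_key, "delta")]
  names(a)[5] <- "delta_a"
  b <- pairs_b[, c(snp_key, "delta")]
  names(b)[5] <- "delta_b"
  m <- dplyr::inner_join(a, b, by = snp_key)
  m <- sort_by_position(m)
  if (nrow(m) == 0) {
    message("match_contrasts: the two contrasts share no SNPs; downstream tests will be skipped")
  }
  attr(m, "match_report") <- tibble::tibble(
    n_a = nrow(pairs_a), n_b = nrow(pairs_b), n_matched = nrow(m))
  m
}

#' Define regions of consecutive SNPs
#'
#' Builds the three region systems used for the region-level comparison of
#' two contrasts:
#' \describe{
#'   \item{`cytoband`}{SNPs grouped by the cytogenetic band containing them.}
#'   \item{`snp50`}{one region per SNP, holding that SNP, its 25 preceding
#'     and 24 following neighbors on the same chromosome (truncated near
#'     chromosome ends, so terminal regions hold fewer than 50 SNPs).}
#'   \item{`win4m10k`}{4 Mb windows advanced by 10 kb (configurable),
#'     members by genomic position; only windows holding at least one SNP
#'     become regions.}
#' }
#'
#' @param x A position-sorted SNP table (e.g. a [match_contrasts()] result).
#' @param kind One of `"cytoband"`, `"snp50"`, `"win4m10k"`.
#' @param cytobands Cytoband table from [read_cytobands()] (required for
#'   `kind = "cytoband"`).
#' @param window_size,slide Window geometry for `kind = "win4m10k"`.
#' @param extents Optional named chromosome lengths for `win4m10k`.
#' @param n_before,n_after Neighborhood shape for `snp50` (defaults 25/24).
#' @return A list with `regions` (tibble `region_id`, `kind`, `chrom`,
#'   `label`, `start`, `end`) and `members` (tibble `region_id`, `row` —
#'   row indices into `x`).
#' @export
define_regions <- function(x, kind = c("cytoband", "snp50", "win4m10k"),
                           cytobands = NULL, window_size = 4e6, slide = 1e4,
                           extents = NULL, n_before = 25, n_after = 24) {
  kind <- match.arg(kind)
  check_cols(x, c("chrom", "pos"), "x")
  if (is.unsorted(order(x$chrom, x$pos))) x <- x[order(x$chrom, x$pos), ]
  if (kind == "cytoband") {
    if (is.null(cytobands)) stop("kind = 'cytoband' requires a cytobands table", call. = FALSE)
    regions <- list(); members <- list(); rid <- 0L
    for (ch in unique(x$chrom)) {
      b <- cytobands[cytobands$chrom == ch, , drop = FALSE]
      rows <- which(x$chrom == ch)
      if (nrow(b) == 0 || length(rows) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = x$pos[rows], width = 1),
        IRanges::IRanges(start = b$start + 1, end = b$end))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      for (bi in sort(unique(sh))) {
        rid <- rid + 1L
        mem <- rows[qh[sh == bi]]
        regions[[rid]] <- tibble::tibble(
          region_id = rid, kind = kind, chrom = ch,
          label = paste0(ch, b$band_name[bi]),
          start = b$start[bi], end = b$end[bi])
        members[[rid]] <- tibble::tibble(region_id = rid, row = mem)
      }
    }
  } else if (kind == "snp50") {
    regions <- list(); members <- list(); base_id <- 0L
    for (ch in unique(x$chrom)) {
      rows <- which(x$chrom == ch)  # contiguous block after sorting
      n <- length(rows)
      i <- seq_len(n)
      lo <- pmax(1L, i - n_before)
      hi <- pmin(n, i + n_after)
      len <- hi - lo + 1L
      ids <- base_id + i
      regions[[ch]] <- tibble::tibble(
        region_id = ids, kind = kind, chrom = ch,
        label = sprintf("%s:%d", ch, x$pos[rows]),
        start = as.numeric(x$pos[rows[lo]]), end = as.numeric(x$pos[rows[hi]]))
      members[[ch]] <- tibble::tibble(
        region_id = rep(ids, len),
        row = rows[1] - 1L + sequence(len, from = lo))
      base_id <- base_id + n
    }
  } else {
    regions <- list(); members <- list(); base_id <- 0L
    for (ch in unique(x$chrom)) {
      rows <- which(x$chrom == ch)
      pos <- x$pos[rows]
      extent <- if (is.null(extents)) max(pos) else extents[[ch]]
      w <- make_windows(extent, window_size, slide)
      lo <- findInterval(w$win_start - 0.5, pos)
      hi <- findInterval(w$win_end - 0.5, pos)
      keep <- hi > lo
      w <- w[keep, , drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]
      len <- hi - lo
      ids <- base_id + seq_along(lo)
      regions[[ch]] <- tibble::tibble(
        region_id = ids, kind = kind, chrom = ch,
        label = sprintf("%s:%g-%g", ch, w$win_start, w$win_end),
        start = w$win_start, end = w$win_end)
      members[[ch]] <- tibble::tibble(
        region_id = rep(ids, len),
        row = rows[1] - 1L + sequence(len, from = lo + 1L))
      base_id <- base_id + length(ids)
    }
  }
  list(regions = dplyr::bind_rows(regions), members = dplyr::bind_rows(members))
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Tests whether paired differences are symmetric about zero. Zero
#' differences are dropped (classic convention) or, with
#' `zero_method = "pratt"`, ranked and then discarded. The exact null
#' distribution (base `psignrank`) is used when the effective sample size
#' is at most `exact_max_n` and the absolute differences are tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. All differences equal to zero yield `p = 1`.
#'
#' @param d Numeric vector of paired differences.
#' @param zero_method `"wilcox"` (drop zeros before ranking, default) or
#'   `"pratt"` (rank with zeros, then drop their ranks).
#' @param exact_max_n Largest tie-free sample size for the exact branch
#'   (default 25).
#' @return A list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_effective`, `n_zeros`, `method` (`"exact"`, `"normal"`, or
#'   `"degenerate"`).
#' @export
wilcoxon_signed_rank <- function(d, zero_method = c("wilcox", "pratt"),
                                 exact_max_n = 25) {
  zero_method <- match.arg(zero_method)
  stopifnot(is.numeric(d), length(d) >= 1)
  n_zeros <- sum(d == 0)
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n_effective = 0L,
                n_zeros = n_zeros, method = "degenerate"))
  }
  if (zero_method == "wilcox") {
    dd <- d[d != 0]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    dd <- d[keep]
    r <- r_all[keep]
  }
  n <- length(dd)
  V <- sum(r[dd > 0])
  ties <- any(duplicated(r))
  if (zero_method == "wilcox" && n <= exact_max_n && !ties) {
    mu2 <- n * (n + 1) / 4
    p <- if (V > mu2) {
      stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      stats::psignrank(V, n)
    }
    return(list(statistic = V, p_value = min(2 * p, 1), n_effective = n,
                n_zeros = n_zeros, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48)
  if (zero_method == "pratt") {
    # zeros removed after ranking shift the mean/variance of V
    n0 <- n_zeros
    ntot <- length(d)
    mu <- (ntot * (ntot + 1) / 4) - (n0 * (n0 + 1) / 4)
    tie_tab_all <- table(rank(abs(d)))
    sigma <- sqrt(ntot * (ntot + 1) * (2 * ntot + 1) / 24 -
                    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
                    sum(tie_tab_all^3 - tie_tab_all) / 48)
  }
  z <- V - mu
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  list(statistic = V, p_value = min(p, 1), n_effective = n,
       n_zeros = n_zeros, method = "normal")
}

#' Per-test Bonferroni threshold
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of tests (>= 1).
#' @return The per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop("m must be a single count >= 1", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 1)
  alpha / m
}

#' Storey q-values with smoother pi0 estimate
#'
#' Estimates the proportion of true nulls pi0 with the lambda-grid smoother
#' (a natural cubic smoothing spline through
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over
#' `lambda = 0, 0.05, ..., 0.90`, evaluated at the largest lambda) and
#' converts p-values to q-values by the step-down minimum of
#' `pi0 * m * p_(j) / j`. With `pi0_method = "fixed"` the single-lambda
#' estimator at `lambda_fixed` is used instead. Forcing `pi0 = 1`
#' reproduces Benjamini-Hochberg step-up values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed pi0 (overrides estimation).
#' @param pi0_method `"smoother"` (default) or `"fixed"`.
#' @param lambda Grid for the smoother (default `seq(0, 0.90, 0.05)`).
#' @param lambda_fixed Lambda for the fixed-lambda estimator (default 0.5).
#' @return A list with `qvalues` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, pi0 = NULL, pi0_method = c("smoother", "fixed"),
                           lambda = seq(0, 0.90, by = 0.05), lambda_fixed = 0.5) {
  pi0_method <- match.arg(pi0_method)
  stopifnot(all(p >= 0), all(p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2) {
      message("storey_qvalues: fewer than 2 p-values; pi0 fixed at 1")
      pi0 <- 1
    } else if (pi0_method == "fixed") {
      pi0 <- min(1, mean(p > lambda_fixed) / (1 - lambda_fixed))
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(1, pi0)
      if (pi0 <= 0) {
        warning("storey_qvalues: smoother pi0 estimate <= 0; flooring at 1e-8", call. = FALSE)
        pi0 <- 1e-8
      }
    }
  }
  ord <- order(p)
  p_ord <- p[ord]
  q_ord <- pi0 * m * p_ord / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q_ord <- pmin(q_ord, 1)
  q <- numeric(m)
  q[ord] <- q_ord
  list(qvalues = q, pi0 = pi0)
}

#' Region-level comparison of two contrasts
#'
#' For each region of consecutive SNPs, tests whether the per-SNP
#' differences `delta_a - delta_b` between two contrasts are symmetric
#' about zero (Wilcoxon signed-rank). Regions with fewer than `min_n`
#' matched SNPs are reported untested (`NA` p and q). Across tested regions
#' of the chosen kind, the Bonferroni threshold is `alpha / m_tested` and
#' Storey q-values are computed; `significant_p` flags `p < alpha/m`,
#' `significant_q` flags `q < alpha`. Y-chromosome regions are excluded by
#' default (unequal male-female ratios between pools make them unreliable).
#'
#' @param matched A [match_contrasts()] table.
#' @param kind Region kind: `"cytoband"`, `"snp50"` or `"win4m10k"`.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum matched SNPs for a testable region (default 5; the
#'   two-sided exact p-value cannot fall below 1/16 with fewer pairs).
#' @param cytobands,window_size,slide,extents Passed to [define_regions()].
#' @param drop_chroms Chromosomes excluded from testing (default `"Y"`).
#' @param zero_method,exact_max_n Passed to [wilcoxon_signed_rank()].
#' @param pi0_method Passed to [storey_qvalues()].
#' @return A tibble with one row per region: `region_id`, `kind`, `chrom`,
#'   `label`, `start`, `end`, `n_pairs`, `statistic`, `p_value`, `q_value`,
#'   `bonferroni_alpha`, `significant_p`, `significant_q`, `tested`.
#' @export
run_region_comparison <- function(matched, kind = c("cytoband", "snp50", "win4m10k"),
                                  alpha = 0.05, min_n = 5, cytobands = NULL,
                                  window_size = 4e6, slide = 1e4, extents = NULL,
                                  drop_chroms = "Y",
                                  zero_method = "wilcox", exact_max_n = 25,
                                  pi0_method = "smoother") {
  kind <- match.arg(kind)
  check_cols(matched, c("chrom", "pos", "delta_a", "delta_b"), "matched")
  matched <- matched[!matched$chrom %in% drop_chroms, , drop = FALSE]
  if (nrow(matched) == 0) {
    message("run_region_comparison: no SNPs to test")
    return(empty_region_results())
  }
  matched <- matched[order(matched$chrom, matched$pos), ]
  regions <- define_regions(matched, kind, cytobands = cytobands,
                            window_size = window_size, slide = slide,
                            extents = extents)
  if (nrow(regions$regions) == 0) {
    message("run_region_comparison: no testable regions")
    return(empty_region_results())
  }
  d_all <- matched$delta_a - matched$delta_b
  mem <- split(regions$members$row, regions$members$region_id)
  res <- regions$regions
  res$n_pairs <- lengths(mem)[as.character(res$region_id)]
  res$statistic <- NA_real_
  res$p_value <- NA_real_
  testable <- which(res$n_pairs >= min_n)
  for (i in testable) {
    w <- wilcoxon_signed_rank(d_all[mem[[as.character(res$region_id[i])]]],
                              zero_method = zero_method, exact_max_n = exact_max_n)
    res$statistic[i] <- if (is.null(w$statistic)) NA_real_ else w$statistic
    res$p_value[i] <- w$p_value
  }
  m_tested <- length(testable)
  res$q_value <- NA_real_
  if (m_tested > 0) {
    res$bonferroni_alpha <- bonferroni_threshold(alpha, m_tested)
    res$q_value[testable] <- storey_qvalues(res$p_value[testable],
                                            pi0_method = pi0_method)$qvalues
  } else {
    message("run_region_comparison: no region reaches min_n; nothing tested")
    res$bonferroni_alpha <- NA_real_
  }
  res$significant_p <- !is.na(res$p_value) & res$p_value < res$bonferroni_alpha
  res$significant_q <- !is.na(res$q_value) & res$q_value < alpha
  res$tested <- seq_len(nrow(res)) %in% testable
  tibble::as_tibble(res)
}

empty_region_results <- function() {
  tibble::tibble(region_id = integer(), kind = character(), chrom = character(),
                 label = character(), start = numeric(), end = numeric(),
                 n_pairs = integer(), statistic = numeric(), p_value = numeric(),
                 q_value = numeric(), bonferroni_alpha = numeric(),
                 significant_p = logical(), significant_q = logical(),
                 tested = logical())
}
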