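# Independent oracles and fixture builders shared across test files.
# Every oracle is coded from the definition, independently of the package
# implementation it checks.

# Exact two-sided signed-rank p-value by enumeration over all 2^n sign
# assignments of the nonzero differences.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  w_obs <- sum(r[d > 0])
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# Benjamini-Hochberg step-up, coded directly from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  for (i in seq_along(ord)) {
    j <- ord[i]
    rank_j <- m - i + 1
    prev <- min(prev, m * p[j] / rank_j)
    q[j] <- prev
  }
  q
}

# Brute-force window means: loop over windows, logical mask per window.
brute_force_window_means <- function(pos, delta, windows) {
  n <- nrow(windows)
  out_n <- integer(n)
  out_mean <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- pos >= windows$win_start[i] & pos < windows$win_end[i]
    out_n[i] <- sum(sel)
    if (out_n[i] > 0) out_mean[i] <- sum(delta[sel]) / out_n[i]
  }
  list(n_snps = out_n, mean_delta = out_mean)
}

# Independent Monte-Carlo of the no-QTL null delta: simulates every diploid
# individual's two haplotypes explicitly (rather than one pooled binomial
# draw) and samples reads one pool at a time.
oracle_null_delta <- function(n_reps, case_depth, control_depth, n_ind, draw_p) {
  out <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    p <- draw_p(1)
    hap_case <- rbinom(2 * n_ind, 1, p)
    hap_ctrl <- rbinom(2 * n_ind, 1, p)
    f_case <- mean(hap_case)
    f_ctrl <- mean(hap_ctrl)
    out[r] <- rbinom(1, case_depth, f_case) / case_depth -
      rbinom(1, control_depth, f_ctrl) / control_depth
  }
  out
}

# Tibble builder for raw pool variant records.
make_records <- function(chrom, pos, depth, alt_depth,
                         ref = "A", alt = "G", mismatch_count = NA_real_,
                         pool_label = "P") {
  tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt,
                 depth = as.integer(depth), alt_depth = as.integer(alt_depth),
                 mismatch_count = mismatch_count, pool_label = pool_label)
}

# Write a small VCF from header fragments + body lines.
write_test_vcf <- function(body_lines, path, sample = "ET",
                           info_meta = character()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000000>",
    "##contig=<ID=2,length=100000000>",
    info_meta,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  writeLines(c(hdr, body_lines), path)
  path
}

# Hand-built 12-record case/control fixture exercising the whole cascade.
# Per-stage hand counts (case pool):
#   raw: 12
#   call_filter (mismatch <= 6 & depth >= 5): drops #2 (depth 4) and
#     #3 (mismatch 7)                                    -> 10
#   depth_filter (>= 20): drops #4 (depth 19) and #5 (depth 10) -> 8
#   index_filter (>= 0.3): drops #6 (0.25) and #7 (0.29 = 29/100) -> 6
# Control pool: 10 records, all passing, at positions 100..1000;
# case survivors sit at 100,200,300,400,1100,1200 of which 100..400 are
# shared with the control -> 4 pairs.
cascade_fixture <- function() {
  case <- make_records(
    chrom = "1",
    pos = c(100, 150, 160, 170, 180, 190, 195, 200, 300, 400, 1100, 1200),
    depth = c(40, 4, 30, 19, 10, 40, 100, 50, 60, 25, 30, 44),
    alt_depth = c(20, 2, 15, 9, 5, 10, 29, 25, 30, 10, 15, 22),
    mismatch_count = c(0, 1, 7, 2, 3, 0, 1, 2, 0, 6, 1, 0),
    pool_label = "ET")
  control <- make_records(
    chrom = "1",
    pos = seq(100, 1000, by = 100),
    depth = rep(40, 10),
    alt_depth = rep(18, 10),
    mismatch_count = rep(0, 10),
    pool_label = "N")
  list(case = case, control = control,
       expected = list(call = 10, depth = 8, index = 6, paired = 4))
}
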