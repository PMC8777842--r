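test_that("contrast matching intersects on the full variant key", {
  fx <- cascade_fixture()
  et <- suppressMessages(snp_index_cascade(fx$case, fx$control, "ET/N"))$pairs
  m_same <- match_contrasts(et, et)
  expect_equal(nrow(m_same), nrow(et))
  expect_identical(m_same$delta_a, m_same$delta_b)

  # disjoint sets match to nothing
  other <- et
  other$pos <- other$pos + 5L
  expect_message(m0 <- match_contrasts(et, other), "share no SNPs")
  expect_equal(nrow(m0), 0L)

  # known-overlap fixture against a set-intersection oracle
  set.seed(41)
  mk <- function(pos) tibble::tibble(chrom = "1", pos = pos, ref = "A", alt = "G",
                                     delta = rnorm(length(pos)))
  a <- mk(sort(sample.int(5000, 300)))
  b <- mk(sort(sample.int(5000, 280)))
  m <- match_contrasts(a, b)
  expect_equal(m$pos, sort(intersect(a$pos, b$pos)))
  rep <- attr(m, "match_report")
  expect_equal(rep$n_matched, length(intersect(a$pos, b$pos)))

  expect_error(match_contrasts(rbind(a, a[1, ]), b), "duplicate")
})

test_that("snp50 regions hold the 25 preceding and 24 following neighbors, truncated", {
  x <- tibble::tibble(chrom = "1", pos = seq(100, by = 100, length.out = 60),
                      delta_a = 0, delta_b = 0)
  regs <- define_regions(x, "snp50")
  expect_equal(nrow(regs$regions), 60L)
  mem <- split(regs$members$row, regs$members$region_id)

  # center i = 30: members 5..54, exactly 50
  expect_equal(mem[["30"]], 5:54)
  # center i = 1: truncated to self + 24 following
  expect_equal(mem[["1"]], 1:25)
  # center i = 60: 25 preceding + self
  expect_equal(mem[["60"]], 35:60)
  expect_true(all(lengths(mem) <= 50))

  # enumeration oracle over every center
  for (i in seq_len(60)) {
    expect_equal(mem[[as.character(i)]], max(1, i - 25):min(60, i + 24))
  }

  # regions never span chromosomes
  x2 <- tibble::tibble(chrom = rep(c("1", "2"), each = 30),
                       pos = rep(seq(100, by = 100, length.out = 30), 2),
                       delta_a = 0, delta_b = 0)
  regs2 <- define_regions(x2, "snp50")
  mem2 <- split(regs2$members$row, regs2$members$region_id)
  expect_true(all(vapply(mem2, function(r) length(unique(x2$chrom[r])) == 1, TRUE)))
  expect_true(all(lengths(mem2) <= 30))
})

test_that("exact signed-rank p-values match full enumeration", {
  # all-positive n = 6: the two one-sided tails each hold a single assignment
  p6 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(p6$method, "exact")
  expect_equal(p6$p_value, 2 / 2^6)

  set.seed(53)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- rnorm(n)
    mine <- wilcoxon_signed_rank(d)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p_value, enumerate_signed_rank_p(d))
  }

  # degenerate all-zero vector
  z <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(z$p_value, 1)
  expect_equal(z$n_effective, 0L)
  expect_equal(z$method, "degenerate")
})

test_that("signed-rank branches agree with the stats-package reference", {
  set.seed(59)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    digits <- sample(c(1, 2, 6), 1)  # low precision induces ties
    d <- round(rnorm(n), digits)
    d <- d[d != 0]
    if (length(d) < 3) next
    mine <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = (mine$method == "exact"),
                                               correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
  }
})

test_that("Bonferroni thresholds divide the level by the test count", {
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("Storey q-values reduce to BH at pi0 = 1 and behave under the null", {
  set.seed(67)
  for (i in 1:20) {
    p <- runif(sample(10:200, 1))
    q <- storey_qvalues(p, pi0 = 1)$qvalues
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  }

  # all p = 1
  expect_true(all(storey_qvalues(rep(1, 20))$qvalues == 1))

  # uniform null: pi0 near 1, almost nothing called
  set.seed(71)
  pu <- runif(1000)
  s <- storey_qvalues(pu)
  expect_gte(s$pi0, 0.85)
  expect_lte(s$pi0, 1.0)
  expect_lte(mean(s$qvalues < 0.05), 0.01)

  # monotone in p and order-invariant
  p <- runif(500)
  q <- storey_qvalues(p)$qvalues
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  perm <- sample.int(500)
  q_perm <- storey_qvalues(p[perm])$qvalues
  expect_equal(q_perm, q[perm])
})

test_that("identical contrasts yield no significant regions", {
  set.seed(73)
  x <- tibble::tibble(chrom = "1", pos = sort(sample.int(1e6, 200)),
                      ref = "A", alt = "G", delta = rnorm(200, 0, 0.1))
  m <- match_contrasts(x, x)
  rc <- run_region_comparison(m, "snp50")
  expect_true(all(rc$p_value[rc$tested] == 1))
  expect_false(any(rc$significant_p))
  expect_false(any(rc$significant_q))
})

test_that("region comparison flags a planted differential region and honors min_n", {
  set.seed(79)
  n <- 600
  x <- tibble::tibble(chrom = "1", pos = sort(sample.int(6e6, n)), ref = "A", alt = "G")
  x$delta_a <- rnorm(n, 0, 0.1)
  x$delta_b <- rnorm(n, 0, 0.1)
  shift <- x$pos >= 2e6 & x$pos <= 3e6
  x$delta_a[shift] <- x$delta_a[shift] + 0.3
  rc <- run_region_comparison(x, "snp50")
  core <- rc$start >= 2e6 & rc$end <= 3e6
  expect_gt(sum(core), 10)
  expect_true(all(rc$significant_q[core]))
  outside <- rc$tested & rc$end < 2e6
  expect_gt(mean(!rc$significant_q[outside]), 0.95)

  # untested small regions carry NA and FALSE flags
  few <- tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                        delta_a = c(1, 1, 1), delta_b = c(0, 0, 0))
  rc2 <- run_region_comparison(few, "snp50", min_n = 5)
  expect_true(all(is.na(rc2$p_value)))
  expect_false(any(rc2$significant_q))

  # Y-chromosome regions are excluded by default
  y <- tibble::tibble(chrom = "Y", pos = seq(100, 6000, by = 100), ref = "A", alt = "G",
                      delta_a = 0.5, delta_b = 0)
  rcy <- run_region_comparison(y, "snp50")
  expect_equal(nrow(rcy), 0L)
})

test_that("the three region systems rank a planted signal concordantly", {
  cfg <- sim_config(n_snps = 8000, depth_mean = 40, seed = 83,
                    qtls = list(qtl_spec("2", 24e6, 26e6, 0.25, "ET")))
  sim <- simulate_pooled_exome(cfg)
  et <- suppressMessages(snp_index_cascade(sim$pools$ET, sim$pools$N, "ET/N"))
  xt <- suppressMessages(snp_index_cascade(sim$pools$XT, sim$pools$N, "XT/N"))
  m <- match_contrasts(et$pairs, xt$pairs)
  cyto <- tibble::tibble(chrom = rep(c("1", "2", "3"), each = 10),
                         start = rep(seq(0, 45e6, by = 5e6), 3),
                         end = rep(seq(5e6, 50e6, by = 5e6), 3),
                         band_name = rep(sprintf("b%d", 1:10), 3),
                         stain = "gneg")
  exts <- stats::setNames(cfg$chromosomes$length, cfg$chromosomes$chrom)
  top_hits <- vapply(c("cytoband", "snp50", "win4m10k"), function(k) {
    rc <- run_region_comparison(m, k, cytobands = cyto, extents = exts)
    best <- rc[rc$tested, ][which.min(rc$p_value[rc$tested]), ]
    best$chrom == "2" & best$end >= 24e6 & best$start <= 26e6
  }, TRUE)
  expect_true(all(top_hits))
})
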