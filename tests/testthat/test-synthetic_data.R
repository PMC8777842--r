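test_that("baseline frequency draws follow the configured Beta law", {
  cfg <- sim_config(n_snps = 10000, freq_alpha = 1, freq_beta = 1, seed = 3,
                    loci = NULL)
  f <- simulate_population_frequencies(cfg)
  expect_true(all(f$freq > 0 & f$freq < 1))
  se <- sqrt(1 / 12 / nrow(f))
  expect_lt(abs(mean(f$freq) - 0.5), 3 * se)

  cfg2 <- sim_config(n_snps = 10000, freq_alpha = 2, freq_beta = 8, seed = 3,
                     loci = NULL)
  f2 <- simulate_population_frequencies(cfg2)
  se2 <- sqrt(0.2 * 0.8 / (2 + 8 + 1) / nrow(f2))
  expect_lt(abs(mean(f2$freq) - 0.2), 3 * se2)

  # determinism and sortedness
  f3 <- simulate_population_frequencies(cfg)
  expect_identical(f, f3)
  for (ch in unique(f$chrom)) expect_false(is.unsorted(f$pos[f$chrom == ch]))

  expect_error(simulate_population_frequencies(
    sim_config(n_snps = 1000, chromosomes = tibble::tibble(chrom = "1", length = 500),
               loci = NULL)), "exceeds")
})

test_that("positions respect the target loci", {
  cfg <- sim_config(n_snps = 3000, seed = 5)
  f <- simulate_population_frequencies(cfg)
  loci <- cfg$loci
  inside <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    b <- loci[loci$chrom == f$chrom[i], ]
    inside[i] <- any(b$start < f$pos[i] & f$pos[i] <= b$end)
  }
  expect_true(all(inside))
})

test_that("pool counts obey the two-stage binomial sampling law", {
  cfg <- sim_config(n_snps = 100, seed = 1, seq_error = 0)
  # boundary frequencies are deterministic
  f0 <- simulate_population_frequencies(cfg)
  f0$freq <- 0
  r0 <- simulate_pool_counts(f0, cfg)
  expect_true(all(r0$alt_depth == 0))
  f1 <- f0
  f1$freq <- 1
  r1 <- simulate_pool_counts(f1, cfg)
  expect_true(all(r1$alt_depth == r1$depth))

  # mean and variance of the SNP index at freq 0.5 against an independent
  # per-individual-haplotype Monte-Carlo oracle
  n_rep <- 20000
  cfgm <- sim_config(n_snps = n_rep, seed = 2, seq_error = 0, loci = NULL)
  fm <- simulate_population_frequencies(cfgm)
  fm$freq <- 0.5
  set.seed(11)
  rm_ <- simulate_pool_counts(fm, cfgm)
  idx <- rm_$alt_depth / rm_$depth

  set.seed(12)
  oracle <- replicate(n_rep, {
    f <- mean(rbinom(2 * 20, 1, 0.5))
    d <- max(1, round(rgamma(1, shape = (39.3 / 16.3)^2, rate = 39.3 / 16.3^2)))
    rbinom(1, d, f) / d
  })
  expect_lt(abs(mean(idx) - 0.5), 3 * sd(oracle) / sqrt(n_rep))
  v_se <- sd((oracle - mean(oracle))^2) / sqrt(n_rep)
  expect_lt(abs(var(idx) - var(oracle)), 3 * sqrt(2) * v_se)
})

test_that("plant_qtl shifts only the targeted span and clips to [0, 1]", {
  f <- tibble::tibble(chrom = rep(c("1", "2"), each = 5),
                      pos = rep(c(10L, 20L, 30L, 40L, 50L), 2),
                      freq = rep(c(0.1, 0.5, 0.9, 0.3, 0.7), 2))
  q0 <- qtl_spec("1", 15, 45, delta = 0, pools = "ET")
  expect_identical(plant_qtl(f, q0), f)

  q <- qtl_spec("1", 15, 45, delta = 0.3, pools = "ET")
  g <- plant_qtl(f, q)
  expect_equal(g$freq[f$chrom == "1"], c(0.1, 0.8, 1.0, 0.6, 0.7))
  expect_identical(g$freq[f$chrom == "2"], f$freq[f$chrom == "2"])

  qe <- qtl_spec("1", 1000, 2000, delta = 0.2, pools = "ET")
  expect_warning(plant_qtl(f, qe), "no simulated SNPs")
})

test_that("a planted frequency shift surfaces as the expected mean delta", {
  cfg <- sim_config(n_snps = 6000, depth_mean = 40, seed = 21,
                    chromosomes = tibble::tibble(chrom = "1", length = 10e6),
                    loci = NULL, freq_alpha = 1, freq_beta = 1,
                    qtls = list(qtl_spec("1", 4e6, 6e6, 0.25, "ET")))
  sim <- simulate_pooled_exome(cfg)
  et <- compute_snp_index(sim$pools$ET)
  n <- compute_snp_index(sim$pools$N)
  pr <- pair_pools(et, n, "ET/N")$pairs
  in_q <- pr$pos >= 4e6 & pr$pos <= 6e6
  expect_gt(sum(in_q), 200)
  # with p ~ U(0,1) the clipped shift min(0.25, 1 - p) has mean
  # 0.25 * 0.75 + E[1-p | p > .75] * 0.25 = 0.21875
  expect_lt(abs(mean(pr$delta[in_q]) - 0.21875), 0.03)
  expect_lt(abs(mean(pr$delta[!in_q])), 0.02)
})

test_that("emitted datasets round-trip and are byte-identical under one seed", {
  cfg <- sim_config(n_snps = 800, seed = 17,
                    qtls = list(qtl_spec("1", 1e6, 3e6, 0.2, c("ET", "XT"))))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_dataset(cfg, d1, force = TRUE)
  p2 <- emit_dataset(cfg, d2, force = TRUE)
  for (f in c("vcf_ET", "vcf_XT", "vcf_N", "cytobands", "loci", "truth")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), label = f)
  }

  sim <- simulate_pooled_exome(cfg)
  back <- suppressMessages(read_pool_vcf(p1[["vcf_ET"]], "ET"))
  expect_identical(back$pos, sim$pools$ET$pos)
  expect_identical(back$depth, sim$pools$ET$depth)
  expect_identical(back$alt_depth, sim$pools$ET$alt_depth)

  truth <- read_results_table(p1[["truth"]])
  expect_equal(nrow(truth), 1L)
  expect_equal(truth$delta, 0.2)
  expect_equal(truth$pools, "ET+XT")

  # no QTLs -> empty truth table; refuse to clobber without force
  cfg0 <- sim_config(n_snps = 100, seed = 1)
  d3 <- withr::local_tempdir()
  p3 <- emit_dataset(cfg0, d3, force = TRUE)
  expect_equal(nrow(read_results_table(p3[["truth"]])), 0L)
  expect_error(emit_dataset(cfg0, d3), "force")
})

test_that("emitted depth moments and null mean delta match the configuration", {
  cfg <- sim_config(n_snps = 12000, seed = 9, loci = NULL)
  sim <- simulate_pooled_exome(cfg)
  for (lb in names(sim$pools)) {
    expect_lt(abs(mean(sim$pools[[lb]]$depth) - 39.3) / 39.3, 0.05)
    expect_lt(abs(sd(sim$pools[[lb]]$depth) - 16.3) / 16.3, 0.05)
  }
  et <- compute_snp_index(sim$pools$ET)
  n <- compute_snp_index(sim$pools$N)
  pr <- pair_pools(et, n, "ET/N")$pairs
  se <- sd(pr$delta) / sqrt(nrow(pr))
  expect_lt(abs(mean(pr$delta)), 3 * se)
})
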