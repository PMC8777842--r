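#' Configuration for the synthetic pooled-exome generator
#'
#' Bundles every parameter of the generator into a validated list. Defaults
#' reproduce the study design the pipeline targets: three pools of 20 diploid
#' individuals, overdispersed per-site read depth with mean 39.3 and SD 16.3,
#' and a symmetric Beta(2, 2) baseline distribution of population alternate
#' allele frequencies shared by all pools.
#'
#' @param n_individuals_per_pool Diploid individuals contributing equimolar
#'   DNA to each pool (default 20).
#' @param n_snps Number of segregating SNV positions to simulate.
#' @param chromosomes Data frame with columns `chrom` (name) and `length`
#'   (bp). Default: three 50 Mb chromosomes, a desk-scale stand-in for the
#'   human genome.
#' @param depth_mean,depth_sd Mean and standard deviation of the per-site
#'   total read depth, modeled as a discretized Gamma floored at 1 read
#'   (overdispersed relative to Poisson, matching exome capture data).
#' @param seq_error Per-read miscall probability (a true-allele read is
#'   observed as the other allele with this probability).
#' @param freq_alpha,freq_beta Shape parameters of the Beta distribution of
#'   baseline population alternate-allele frequencies.
#' @param qtls List of planted frequency shifts created with [qtl_spec()].
#' @param loci Optional tibble of exome target loci (`chrom`, `start`, `end`
#'   0-based half-open, `name`). SNP positions are drawn uniformly inside the
#'   loci. `NULL` (positions uniform over whole chromosomes) or `"default"`
#'   (a deterministic tiling of 50 kb loci every 200 kb, i.e. 25% exome
#'   coverage, mimicking sparse capture targets).
#' @param weight_sd SD (log scale) of optional lognormal per-individual
#'   pooling-weight jitter; 0 (default) means exactly equimolar pooling.
#' @param pool_labels Labels of the two case pools and the control pool.
#' @param seed RNG seed governing every stochastic stage.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals_per_pool = 20,
                       n_snps = 24000,
                       chromosomes = tibble::tibble(chrom = c("1", "2", "3"),
                                                    length = rep(50e6, 3)),
                       depth_mean = 39.3,
                       depth_sd = 16.3,
                       seq_error = 0.002,
                       freq_alpha = 2,
                       freq_beta = 2,
                       qtls = list(),
                       loci = "default",
                       weight_sd = 0,
                       pool_labels = c(case_a = "ET", case_b = "XT", control = "N"),
                       seed = 1L) {
  stopifnot(n_individuals_per_pool >= 1, n_snps >= 1,
            depth_mean > 0, depth_sd > 0,
            seq_error >= 0, seq_error < 0.5,
            freq_alpha > 0, freq_beta > 0,
            all(chromosomes$length > 0), weight_sd >= 0)
  chromosomes <- tibble::as_tibble(chromosomes)
  check_cols(chromosomes, c("chrom", "length"), "chromosomes")
  if (identical(loci, "default")) {
    loci <- default_target_loci(chromosomes)
  }
  if (!is.null(loci)) {
    loci <- tibble::as_tibble(loci)
    check_cols(loci, c("chrom", "start", "end"), "loci")
    if (!"name" %in% names(loci)) loci$name <- sprintf("locus_%d", seq_len(nrow(loci)))
    loci <- merge_loci(loci)
  }
  if (length(qtls) > 0 && !all(vapply(qtls, inherits, TRUE, "qtl_spec"))) {
    stop("qtls must be a list of qtl_spec() objects", call. = FALSE)
  }
  structure(list(
    n_individuals_per_pool = as.integer(n_individuals_per_pool),
    n_snps = as.integer(n_snps),
    chromosomes = chromosomes,
    depth_mean = depth_mean, depth_sd = depth_sd,
    seq_error = seq_error,
    freq_alpha = freq_alpha, freq_beta = freq_beta,
    qtls = qtls, loci = loci, weight_sd = weight_sd,
    pool_labels = pool_labels,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic sparse "exome": 50 kb loci every 200 kb on each chromosome.
default_target_loci <- function(chromosomes, locus_len = 5e4, spacing = 2e5) {
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    starts <- seq(0, chromosomes$length[i] - locus_len, by = spacing)
    tibble::tibble(chrom = chromosomes$chrom[i], start = starts,
                   end = starts + locus_len,
                   name = sprintf("%s_L%04d", chromosomes$chrom[i], seq_along(starts)))
  })
  dplyr::bind_rows(out)
}

#' Specify a planted QTL frequency shift
#'
#' Describes an additive shift of the alternate-allele frequency inside a
#' genomic region, applied to one or both case pools. Shifted frequencies
#' are clipped to `[0, 1]`.
#'
#' @param chrom Chromosome name.
#' @param start,end Region span in bp (1-based, inclusive), `start < end`.
#' @param delta Additive frequency shift in `[-1, 1]`.
#' @param pools Character vector naming the affected case pools (subset of
#'   the configured case labels, e.g. `"ET"`).
#' @return A list of class `"qtl_spec"`.
#' @export
qtl_spec <- function(chrom, start, end, delta, pools) {
  stopifnot(start < end, delta >= -1, delta <= 1, length(pools) >= 1)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 delta = delta, pools = pools),
            class = "qtl_spec")
}

#' Draw baseline population allele frequencies and SNP positions
#'
#' Positions are sampled uniformly without replacement over the target loci
#' (or over whole chromosomes when no loci are configured) and sorted;
#' baseline alternate-allele frequencies are i.i.d.
#' Beta(`freq_alpha`, `freq_beta`). Reference/alternate alleles are assigned
#' at random. Setting `cfg$seed` makes the draw reproducible.
#'
#' @param cfg A [sim_config()] object.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `freq`.
#' @export
simulate_population_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(cfg$loci)) {
    space <- tibble::tibble(chrom = cfg$chromosomes$chrom,
                            start = 0, end = cfg$chromosomes$length)
  } else {
    space <- cfg$loci
  }
  len <- space$end - space$start
  total <- sum(len)
  if (cfg$n_snps > total) {
    stop(sprintf("n_snps (%d) exceeds the %d available positions", cfg$n_snps, total),
         call. = FALSE)
  }
  offs <- sort(sample.int(total, cfg$n_snps))
  cum <- cumsum(len)
  iv <- findInterval(offs - 1, c(0, cum), rightmost.closed = FALSE)
  pos <- as.integer(space$start[iv] + (offs - c(0, cum)[iv]))  # 1-based position
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  x <- tibble::tibble(chrom = space$chrom[iv], pos = pos, ref = ref, alt = unname(alt),
                      freq = stats::rbeta(cfg$n_snps, cfg$freq_alpha, cfg$freq_beta))
  x <- x[order(x$chrom, x$pos), ]
  # collisions are possible when loci overlap chromosome starts; enforce uniqueness
  x <- x[!duplicated(paste(x$chrom, x$pos)), ]
  x
}

#' Apply a planted QTL shift to one pool's frequency track
#'
#' Adds `qtl$delta` to the alternate-allele frequency of every SNP inside the
#' region and clips to `[0, 1]`. Positions outside the region are unchanged.
#' A region containing no SNPs triggers a warning and returns the input
#' unmodified.
#'
#' @param freqs Tibble with columns `chrom`, `pos`, `freq` (one pool's track).
#' @param qtl A [qtl_spec()] object.
#' @return `freqs` with the shift applied.
#' @export
plant_qtl <- function(freqs, qtl) {
  stopifnot(inherits(qtl, "qtl_spec"))
  check_cols(freqs, c("chrom", "pos", "freq"), "freqs")
  hit <- freqs$chrom == qtl$chrom & freqs$pos >= qtl$start & freqs$pos <= qtl$end
  if (!any(hit)) {
    warning(sprintf("planted QTL region %s:%g-%g contains no simulated SNPs; no-op",
                    qtl$chrom, qtl$start, qtl$end), call. = FALSE)
    return(freqs)
  }
  freqs$freq[hit] <- pmin(1, pmax(0, freqs$freq[hit] + qtl$delta))
  freqs
}

#' Simulate read counts for one pool
#'
#' Implements the two-stage pool-seq sampling model. For each SNP with
#' population frequency `p`: the pool's alternate haplotype count is
#' `k ~ Binomial(2n, p)` over the `n` diploid individuals, giving pool allele
#' fraction `f = k / 2n`; total depth `d` is a discretized
#' Gamma(`depth_mean`, `depth_sd`) floored at one read; and the observed
#' alternate read count is `Binomial(d, f(1-e) + (1-f)e)` with miscall rate
#' `e = seq_error`. With `weight_sd > 0`, per-individual lognormal pooling
#' weights replace the equimolar `f`.
#'
#' @param freqs Tibble with columns `chrom`, `pos`, `ref`, `alt`, `freq`
#'   (this pool's frequency track).
#' @param cfg A [sim_config()] object.
#' @param pool_label Label stamped on the records.
#' @return A tibble of pool variant records (`chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_depth`, `mismatch_count = NA`, `pool_label`).
#' @export
simulate_pool_counts <- function(freqs, cfg, pool_label = "pool") {
  stopifnot(inherits(cfg, "sim_config"))
  check_cols(freqs, c("chrom", "pos", "freq"), "freqs")
  stopifnot(all(freqs$freq >= 0), all(freqs$freq <= 1))
  n <- nrow(freqs)
  n_ind <- cfg$n_individuals_per_pool
  if (cfg$weight_sd > 0) {
    g <- matrix(stats::rbinom(n * n_ind, 2L, rep(freqs$freq, n_ind)), nrow = n)
    w <- stats::rlnorm(n_ind, 0, cfg$weight_sd)
    f <- as.numeric(g %*% w) / (2 * sum(w))
  } else {
    k <- stats::rbinom(n, 2L * n_ind, freqs$freq)
    f <- k / (2 * n_ind)
  }
  shape <- (cfg$depth_mean / cfg$depth_sd)^2
  rate <- cfg$depth_mean / cfg$depth_sd^2
  d <- pmax(1L, as.integer(round(stats::rgamma(n, shape = shape, rate = rate))))
  pe <- f * (1 - cfg$seq_error) + (1 - f) * cfg$seq_error
  a <- stats::rbinom(n, d, pe)
  tibble::tibble(chrom = freqs$chrom, pos = freqs$pos,
                 ref = freqs$ref, alt = freqs$alt,
                 depth = d, alt_depth = a,
                 mismatch_count = NA_real_, pool_label = pool_label)
}

#' Simulate a full pooled-exome dataset in memory
#'
#' Draws shared baseline population frequencies, applies any planted QTL
#' shifts to the designated case pools, and samples read counts for the two
#' case pools and the control pool. All randomness is governed by
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements `pools` (named list of record tibbles, one
#'   per pool label), `freqs` (baseline truth frequencies), `truth` (tibble
#'   of planted QTLs) and `cfg`.
#' @export
simulate_pooled_exome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- simulate_population_frequencies(cfg)  # seeds the RNG stream
  labels <- cfg$pool_labels
  tracks <- stats::setNames(rep(list(base), length(labels)), labels)
  for (qtl in cfg$qtls) {
    for (p in qtl$pools) {
      if (!p %in% labels) stop(sprintf("QTL names unknown pool '%s'", p), call. = FALSE)
      tracks[[p]] <- plant_qtl(tracks[[p]], qtl)
    }
  }
  pools <- lapply(stats::setNames(labels, labels), function(lb) {
    simulate_pool_counts(tracks[[lb]], cfg, pool_label = lb)
  })
  truth <- if (length(cfg$qtls) == 0) {
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                   delta = numeric(), pools = character())
  } else {
    dplyr::bind_rows(lapply(cfg$qtls, function(q) {
      tibble::tibble(chrom = q$chrom, start = q$start, end = q$end,
                     delta = q$delta, pools = paste(q$pools, collapse = "+"))
    }))
  }
  list(pools = pools, freqs = base, truth = truth, cfg = cfg)
}

#' Write a simulated dataset to standard files
#'
#' Runs [simulate_pooled_exome()] and writes one single-sample VCF per pool,
#' a synthetic cytogenetic-band file (UCSC dialect), the target-locus BED, a
#' truth table of planted QTLs, and a JSON manifest recording the seed and a
#' hash of the configuration. All outputs are plain text and byte-identical
#' across runs with the same configuration.
#'
#' @param cfg A [sim_config()] object.
#' @param outdir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Named character vector of written file paths, invisibly.
#' @export
emit_dataset <- function(cfg, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force) {
    stop(sprintf("output directory %s exists and is not empty (use force = TRUE)", outdir),
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_pooled_exome(cfg)
  paths <- c()
  for (lb in names(sim$pools)) {
    p <- file.path(outdir, paste0(lb, ".vcf"))
    write_pool_vcf(sim$pools[[lb]], cfg$chromosomes, p, sample_name = lb)
    paths[paste0("vcf_", lb)] <- p
  }
  cyto_path <- file.path(outdir, "cytoband.txt")
  write_synthetic_cytobands(cfg$chromosomes, cyto_path)
  paths["cytobands"] <- cyto_path
  bed_path <- file.path(outdir, "target_loci.bed")
  loci <- if (is.null(cfg$loci)) {
    tibble::tibble(chrom = cfg$chromosomes$chrom, start = 0,
                   end = cfg$chromosomes$length,
                   name = paste0(cfg$chromosomes$chrom, "_full"))
  } else cfg$loci
  writeLines(sprintf("%s\t%d\t%d\t%s", loci$chrom, as.integer(loci$start),
                     as.integer(loci$end), loci$name), bed_path)
  paths["loci"] <- bed_path
  truth_path <- file.path(outdir, "qtl_truth.tsv")
  write_results_table(sim$truth, truth_path)
  paths["truth"] <- truth_path
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(list(seed = cfg$seed,
                            config_hash = rlang::hash(unclass(cfg)),
                            n_snps = nrow(sim$freqs),
                            pools = names(sim$pools)),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths["manifest"] <- manifest_path
  invisible(paths)
}

# Minimal single-sample VCFv4.2 writer (GT:AD:DP) for simulated pools.
write_pool_vcf <- function(records, chromosomes, path, sample_name) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pooldelta-simulator",
    sprintf("##contig=<ID=%s,length=%d>", chromosomes$chrom, as.integer(chromosomes$length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t./.:%d,%d:%d",
                  records$chrom, records$pos, records$ref, records$alt,
                  records$depth - records$alt_depth, records$alt_depth, records$depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Synthetic Giemsa bands: ten 5 Mb-scale bands per chromosome, p-arm then q-arm.
write_synthetic_cytobands <- function(chromosomes, path) {
  rows <- lapply(seq_len(nrow(chromosomes)), function(i) {
    L <- chromosomes$length[i]
    n_band <- 10L
    edges <- round(seq(0, L, length.out = n_band + 1))
    half <- n_band %/% 2
    nm <- c(sprintf("p%d", half:1), sprintf("q%d", 1:(n_band - half)))
    stain <- rep(c("gneg", "gpos50"), length.out = n_band)
    sprintf("%s\t%d\t%d\t%s\t%s", chromosomes$chrom[i],
            as.integer(edges[-(n_band + 1)]), as.integer(edges[-1]), nm, stain)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}
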