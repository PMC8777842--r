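#' Call-level filter (mismatch and minimum call depth)
#'
#' First stage of the filter cascade: removes variant calls supported by
#' read clusters with too many mismatches (alignment-error proxies) or too
#' little depth. The mismatch criterion applies only when records carry a
#' `mismatch_count` annotation; otherwise it is skipped with a message.
#'
#' @param records Pool variant records (see [read_pool_vcf()]).
#' @param max_mismatch Maximum tolerated mismatch count (default 6; calls
#'   with more than this many mismatches are removed).
#' @param min_call_depth Minimum read depth for a credible call (default 5;
#'   sites with fewer reads are removed).
#' @return The surviving records.
#' @export
call_filter <- function(records, max_mismatch = 6, min_call_depth = 5) {
  check_cols(records, c("depth"))
  keep <- records$depth >= min_call_depth
  if ("mismatch_count" %in% names(records) && any(!is.na(records$mismatch_count))) {
    keep <- keep & (is.na(records$mismatch_count) | records$mismatch_count <= max_mismatch)
  } else {
    message("call_filter: no mismatch annotation present; mismatch criterion skipped")
  }
  records[keep, , drop = FALSE]
}

#' Compute the SNP index of each record
#'
#' The SNP index is the ratio of variant-supporting reads to all reads at a
#' site: `alt_depth / depth`. Zero-depth records cannot carry an index and
#' are dropped with a message.
#'
#' @param records Pool variant records.
#' @return The records with an added `snp_index` column.
#' @export
compute_snp_index <- function(records) {
  check_cols(records, c("depth", "alt_depth"))
  n_zero <- sum(records$depth == 0)
  if (n_zero > 0) {
    message(sprintf("compute_snp_index: dropped %d zero-depth record(s)", n_zero))
    records <- records[records$depth > 0, , drop = FALSE]
  }
  records$snp_index <- records$alt_depth / records$depth
  records
}

#' Depth filter
#'
#' Retains SNP positions with total depth at or above `min_depth`
#' (default 20), the pipeline's statistical-analysis depth cutoff.
#'
#' @param records Records carrying a `depth` column.
#' @param min_depth Minimum retained depth.
#' @return The surviving records.
#' @export
depth_filter <- function(records, min_depth = 20) {
  check_cols(records, "depth")
  records[records$depth >= min_depth, , drop = FALSE]
}

#' SNP-index filter
#'
#' Retains positions whose SNP index is at or above `min_index`
#' (default 0.3). Applied per pool, before pairing, so that each pool's
#' survivor set matches its own column of the staged filter report.
#'
#' @param records Records carrying a `snp_index` column.
#' @param min_index Minimum retained SNP index.
#' @return The surviving records.
#' @export
index_filter <- function(records, min_index = 0.3) {
  check_cols(records, "snp_index")
  records[records$snp_index >= min_index, , drop = FALSE]
}

#' Pair case and control pools at shared SNPs
#'
#' Inner-joins two filtered, indexed record sets on `(chrom, pos, ref, alt)`
#' and computes the delta SNP index (case minus control) at every shared
#' site. Duplicate keys within a pool are an error.
#'
#' @param case_records,control_records Filtered records carrying `snp_index`.
#' @param contrast_label Label for the contrast, e.g. `"ET/N"`.
#' @return A list with `pairs` (tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `case_index`, `control_index`, `case_depth`, `control_depth`,
#'   `delta`, `contrast_label`) and `report` (one-row tibble of per-pool and
#'   paired counts).
#' @export
pair_pools <- function(case_records, control_records, contrast_label = "case/control") {
  check_cols(case_records, c(snp_key, "depth", "snp_index"), "case_records")
  check_cols(control_records, c(snp_key, "depth", "snp_index"), "control_records")
  check_unique_keys(case_records, "case pool")
  check_unique_keys(control_records, "control pool")
  a <- case_records[, c(snp_key, "depth", "snp_index")]
  names(a)[5:6] <- c("case_depth", "case_index")
  b <- control_records[, c(snp_key, "depth", "snp_index")]
  names(b)[5:6] <- c("control_depth", "control_index")
  pairs <- dplyr::inner_join(a, b, by = snp_key)
  pairs$delta <- pairs$case_index - pairs$control_index
  pairs$contrast_label <- contrast_label
  pairs <- sort_by_position(pairs)
  report <- tibble::tibble(stage = "paired", contrast = contrast_label,
                           case_n = nrow(case_records),
                           control_n = nrow(control_records),
                           paired_n = nrow(pairs))
  list(pairs = tibble::as_tibble(pairs), report = report)
}

#' Combine two pools into one at the read level
#'
#' Forms the union of two pools' variant records: at every site present in
#' either pool, total and alternate read depths are summed (a read-level
#' union, equivalent to merging the two libraries), and the SNP index is the
#' index of the summed counts. Conflicting alleles at the same position are
#' an error.
#'
#' @param pool_a_records,pool_b_records Raw pool variant records.
#' @param pool_label Label for the combined pool (default joins the two
#'   input labels with `"+"`).
#' @return Combined pool variant records.
#' @export
combine_pools <- function(pool_a_records, pool_b_records, pool_label = NULL) {
  check_cols(pool_a_records, c(snp_key, "depth", "alt_depth"), "pool_a_records")
  check_cols(pool_b_records, c(snp_key, "depth", "alt_depth"), "pool_b_records")
  check_unique_keys(pool_a_records, "pool A")
  check_unique_keys(pool_b_records, "pool B")
  refs <- rbind(pool_a_records[, c("chrom", "pos", "ref")],
                pool_b_records[, c("chrom", "pos", "ref")])
  by_pos <- unique(refs)
  dup <- by_pos[duplicated(paste(by_pos$chrom, by_pos$pos)), , drop = FALSE]
  if (nrow(dup) > 0) {
    stop(sprintf("conflicting reference alleles between pools at %s:%d",
                 dup$chrom[1], dup$pos[1]), call. = FALSE)
  }
  if (is.null(pool_label)) {
    la <- unique(pool_a_records$pool_label)
    lb <- unique(pool_b_records$pool_label)
    pool_label <- paste(c(la, lb), collapse = "+")
  }
  a <- pool_a_records[, c(snp_key, "depth", "alt_depth", "mismatch_count")]
  b <- pool_b_records[, c(snp_key, "depth", "alt_depth", "mismatch_count")]
  m <- dplyr::full_join(a, b, by = snp_key, suffix = c("_a", "_b"))
  zero <- function(x) ifelse(is.na(x), 0L, x)
  m$depth <- zero(m$depth_a) + zero(m$depth_b)
  m$alt_depth <- zero(m$alt_depth_a) + zero(m$alt_depth_b)
  m$mismatch_count <- pmax(m$mismatch_count_a, m$mismatch_count_b, na.rm = TRUE)
  m$mismatch_count[is.na(m$mismatch_count_a) & is.na(m$mismatch_count_b)] <- NA_real_
  out <- m[, c(snp_key, "depth", "alt_depth", "mismatch_count")]
  out$pool_label <- pool_label
  sort_by_position(tibble::as_tibble(out))
}

#' Run the full filter cascade for one case/control contrast
#'
#' Applies the staged cascade — call filter, SNP-index computation, depth
#' filter, SNP-index filter — to both pools, then pairs the survivors.
#' Returns the paired deltas together with a staged filter report whose
#' per-pool counts are non-increasing down the cascade.
#'
#' @param case_records,control_records Raw pool variant records.
#' @param contrast_label Contrast label, e.g. `"ET/N"`.
#' @param max_mismatch,min_call_depth Call-filter thresholds (see
#'   [call_filter()]).
#' @param min_depth Depth-filter threshold (see [depth_filter()]).
#' @param min_index SNP-index-filter threshold (see [index_filter()]).
#' @return A list with `pairs` (see [pair_pools()]) and `report`, a tibble
#'   with one row per cascade stage and columns `stage`, `case_n`,
#'   `control_n`, `paired_n` (paired count only at the final stage).
#' @export
snp_index_cascade <- function(case_records, control_records,
                              contrast_label = "case/control",
                              max_mismatch = 6, min_call_depth = 5,
                              min_depth = 20, min_index = 0.3) {
  stages <- list()
  ca <- call_filter(case_records, max_mismatch, min_call_depth)
  co <- call_filter(control_records, max_mismatch, min_call_depth)
  stages[["call_filter"]] <- c(nrow(ca), nrow(co))
  ca <- compute_snp_index(ca)
  co <- compute_snp_index(co)
  ca <- depth_filter(ca, min_depth)
  co <- depth_filter(co, min_depth)
  stages[["depth_filter"]] <- c(nrow(ca), nrow(co))
  ca <- index_filter(ca, min_index)
  co <- index_filter(co, min_index)
  stages[["index_filter"]] <- c(nrow(ca), nrow(co))
  paired <- pair_pools(ca, co, contrast_label)
  report <- tibble::tibble(
    stage = c(names(stages), "paired"),
    contrast = contrast_label,
    case_n = unname(c(vapply(stages, `[`, 0, 1), nrow(ca))),
    control_n = unname(c(vapply(stages, `[`, 0, 2), nrow(co))),
    paired_n = c(rep(NA_integer_, length(stages)), nrow(paired$pairs))
  )
  list(pairs = paired$pairs, report = report)
}
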