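#' Build the spacer-concatenated plotting coordinate
#'
#' Exome loci are sparse, so genome-wide delta SNP-index plots concatenate
#' the target loci per chromosome and insert a fixed-length spacer (default
#' 200 bp of "N") between adjacent loci. The i-th locus (0-based) starts at
#' plot offset `sum(len of earlier loci) + i * spacer_len`.
#'
#' @param loci Merged, sorted target loci (tibble with `chrom`, `start`,
#'   `end` 0-based half-open, optional `name`), e.g. from
#'   [read_target_loci()].
#' @param spacer_len Spacer length in bp between adjacent loci (default 200).
#' @return A tibble of class `"concat_map"` with columns `chrom`, `start`,
#'   `end`, `name`, `len`, `plot_start` (0-based plot offset of the locus
#'   start; offsets restart at 0 on each chromosome). The spacer length is
#'   stored in the `"spacer_len"` attribute.
#' @export
build_concat_map <- function(loci, spacer_len = 200) {
  check_cols(loci, c("chrom", "start", "end"), "loci")
  stopifnot(spacer_len >= 0)
  if (!"name" %in% names(loci)) loci$name <- sprintf("locus_%d", seq_len(nrow(loci)))
  loci <- loci[order(loci$chrom, loci$start), ]
  out <- lapply(split(loci, loci$chrom), function(b) {
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop(sprintf("loci on chromosome %s overlap; merge them first", b$chrom[1]),
           call. = FALSE)
    }
    len <- b$end - b$start
    b$len <- len
    b$plot_start <- cumsum(c(0, len[-length(len)])) +
      (seq_along(len) - 1) * spacer_len
    b
  })
  res <- dplyr::bind_rows(out)
  res <- res[order(res$chrom, res$start), ]
  attr(res, "spacer_len") <- spacer_len
  class(res) <- c("concat_map", class(res))
  res
}

#' Map genomic positions to concatenated plot coordinates
#'
#' @param cmap A [build_concat_map()] object.
#' @param chrom,pos Vectors of chromosome names and 1-based genomic
#'   positions; each position must fall inside a target locus.
#' @return Numeric vector of 0-based plot coordinates (per chromosome).
#' @export
genomic_to_plot <- function(cmap, chrom, pos) {
  stopifnot(inherits(cmap, "concat_map"), length(chrom) == length(pos))
  chrom <- norm_chrom(chrom)
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    b <- cmap[cmap$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(b) == 0) {
      stop(sprintf("position %s:%d lies on a chromosome absent from the concat map",
                   ch, pos[sel[1]]), call. = FALSE)
    }
    # locus containing 1-based pos: start < pos <= end (0-based half-open interval)
    iv <- findInterval(pos[sel] - 1, b$start)
    bad <- iv == 0 | (pos[sel] - 1) >= b$end[pmax(iv, 1)]
    if (any(bad)) {
      j <- sel[bad][1]
      stop(sprintf("position %s:%d falls outside every target locus", ch, pos[j]),
           call. = FALSE)
    }
    out[sel] <- b$plot_start[iv] + (pos[sel] - 1 - b$start[iv])
  }
  out
}

#' Enumerate sliding windows over one chromosome span
#'
#' Windows are half-open spans `[k * slide, k * slide + window_size)` for
#' `k = 0, 1, ...` while the start lies inside the chromosome; trailing
#' windows are truncated at the chromosome end.
#'
#' @param extent Chromosome span in bp.
#' @param window_size Window width in bp (default 4 Mb, the configuration
#'   retained as best-resolving in the sliding-window scan).
#' @param slide Step between window starts in bp (default 10 kb).
#' @return A tibble with columns `win_start`, `win_end` (half-open).
#' @export
make_windows <- function(extent, window_size = 4e6, slide = 1e4) {
  if (!(slide > 0) || !(window_size > 0)) {
    stop("window_size and slide must be positive", call. = FALSE)
  }
  if (window_size < slide) stop("window_size must be >= slide", call. = FALSE)
  stopifnot(extent > 0)
  starts <- slide * (seq_len(ceiling(extent / slide)) - 1)
  starts <- starts[starts < extent]
  tibble::tibble(win_start = starts,
                 win_end = pmin(starts + window_size, extent))
}

#' Sliding-window mean delta SNP index
#'
#' Computes, per chromosome, the number of paired SNPs and the arithmetic
#' mean of their delta SNP index in every sliding window. A SNP belongs to a
#' window when `win_start <= pos < win_end`. Empty windows are retained with
#' `mean_delta = NA` so trendline gaps stay visible.
#'
#' @param pairs Paired-delta table (see [pair_pools()]), sorted or not.
#' @param window_size,slide Window geometry in bp (defaults 4 Mb / 10 kb).
#' @param extents Optional named numeric vector of chromosome lengths; by
#'   default each chromosome extends to its last observed SNP.
#' @return A tibble with columns `chrom`, `win_start`, `win_end`, `n_snps`,
#'   `mean_delta`.
#' @export
window_mean_delta <- function(pairs, window_size = 4e6, slide = 1e4, extents = NULL) {
  check_cols(pairs, c("chrom", "pos", "delta"), "pairs")
  pairs <- pairs[order(pairs$chrom, pairs$pos), ]
  chroms <- if (is.null(extents)) unique(pairs$chrom) else names(extents)
  out <- lapply(chroms, function(ch) {
    p <- pairs[pairs$chrom == ch, , drop = FALSE]
    extent <- if (is.null(extents)) max(p$pos) else extents[[ch]]
    w <- make_windows(extent, window_size, slide)
    pos <- p$pos
    lo <- findInterval(w$win_start - 0.5, pos)
    hi <- findInterval(w$win_end - 0.5, pos)
    n <- hi - lo
    sums <- vapply(seq_len(nrow(w)), function(i) {
      if (n[i] == 0) return(NA_real_)
      sum(p$delta[(lo[i] + 1):hi[i]])
    }, 0)
    tibble::tibble(chrom = ch, win_start = w$win_start, win_end = w$win_end,
                   n_snps = n, mean_delta = sums / n)
  })
  dplyr::bind_rows(out)
}

#' Per-region SNP count summary
#'
#' Counts the SNPs of a paired table falling in each region of a
#' [define_regions()] result and summarizes the counts as mean and SD —
#' the like-for-like companion of the per-region SNP-count statistics
#' reported for cytobands, 50-SNP groups and 4 Mb / 10 kb windows.
#'
#' @param pairs The paired table the regions were defined on.
#' @param regions A [define_regions()] result.
#' @return A list with `per_region` (tibble `region_id`, `label`, `n_snps`)
#'   and `summary` (tibble `n_regions`, `mean`, `sd`).
#' @export
region_snp_counts <- function(pairs, regions) {
  stopifnot(is.list(regions), all(c("regions", "members") %in% names(regions)))
  cnt <- table(factor(regions$members$region_id, levels = regions$regions$region_id))
  per_region <- tibble::tibble(region_id = regions$regions$region_id,
                               label = regions$regions$label,
                               n_snps = as.integer(cnt))
  list(per_region = per_region,
       summary = tibble::tibble(n_regions = nrow(per_region),
                                mean = mean(per_region$n_snps),
                                sd = stats::sd(per_region$n_snps)))
}
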