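#' Genome-wide delta SNP-index plot with trendline and null bands
#'
#' Draws the per-SNP delta SNP index as a scatter, the sliding-window mean
#' as a thick red trendline, and the Monte-Carlo null bands as yellow
#' (99%, p < 0.01) and green (95%, p < 0.05) lines, one panel per
#' chromosome. When a concatenation map is supplied, x-coordinates are the
#' spacer-concatenated locus positions; otherwise genomic positions are
#' used. Alongside the ggplot object, the exact numeric series rendered are
#' returned so downstream checks can assert on data rather than pixels.
#'
#' @param pairs Paired-delta table (see [pair_pools()]).
#' @param window_stats Window statistics, ideally with null-band columns
#'   from [window_null_bands()].
#' @param concat_map Optional [build_concat_map()] object.
#' @param point_alpha Scatter transparency.
#' @return A list with `plot` (ggplot), `points` (tibble `chrom`, `x`,
#'   `delta`) and `series` (tibble `chrom`, `x`, `n_snps`, `mean_delta` and
#'   any `ci*` columns; non-empty windows only, `x` at the window's member
#'   midpoint).
#' @export
plot_delta_genome <- function(pairs, window_stats, concat_map = NULL,
                              point_alpha = 0.3) {
  check_cols(pairs, c("chrom", "pos", "delta"), "pairs")
  check_cols(window_stats, c("chrom", "win_start", "win_end", "n_snps", "mean_delta"),
             "window_stats")
  if (nrow(pairs) == 0) stop("plot_delta_genome: empty pairs table", call. = FALSE)
  pairs <- pairs[order(pairs$chrom, pairs$pos), ]
  if (is.null(concat_map)) {
    px <- pairs$pos
  } else {
    px <- genomic_to_plot(concat_map, pairs$chrom, pairs$pos)
  }
  points <- tibble::tibble(chrom = pairs$chrom, x = px, delta = pairs$delta)

  ws <- window_stats[window_stats$n_snps > 0, , drop = FALSE]
  # window x = midpoint of its member SNPs in the plotting coordinate, so
  # spacer-concatenated trendlines stay inside the loci
  wx <- numeric(nrow(ws))
  for (ch in unique(ws$chrom)) {
    sel <- which(ws$chrom == ch)
    p <- pairs[pairs$chrom == ch, , drop = FALSE]
    xs <- points$x[points$chrom == ch]
    lo <- findInterval(ws$win_start[sel] - 0.5, p$pos)
    hi <- findInterval(ws$win_end[sel] - 0.5, p$pos)
    wx[sel] <- (xs[lo + 1] + xs[hi]) / 2
  }
  series <- tibble::tibble(chrom = ws$chrom, x = wx)
  for (col in c("win_start", "win_end", "n_snps", "mean_delta",
                "ci95_lo", "ci95_hi", "ci99_lo", "ci99_hi")) {
    if (col %in% names(ws)) series[[col]] <- ws[[col]]
  }
  g <- ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$delta)) +
    ggplot2::geom_point(alpha = point_alpha, size = 0.4, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey70") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = if (is.null(concat_map)) "genomic position (bp)" else
      "concatenated locus position (bp)",
      y = expression(Delta * "(SNP index)")) +
    ggplot2::theme_minimal()
  if (all(c("ci99_lo", "ci99_hi") %in% names(series))) {
    g <- g +
      ggplot2::geom_line(data = series, ggplot2::aes(y = .data$ci99_lo), colour = "gold2") +
      ggplot2::geom_line(data = series, ggplot2::aes(y = .data$ci99_hi), colour = "gold2") +
      ggplot2::geom_line(data = series, ggplot2::aes(y = .data$ci95_lo), colour = "green3") +
      ggplot2::geom_line(data = series, ggplot2::aes(y = .data$ci95_hi), colour = "green3")
  }
  g <- g + ggplot2::geom_line(data = series,
                              ggplot2::aes(y = .data$mean_delta),
                              colour = "red", linewidth = 1)
  list(plot = g, points = points, series = series)
}

#' Manhattan plot of region-level p or q values
#'
#' Plots `-log10` of the region-level Wilcoxon p-values (with the Bonferroni
#' threshold line) or Storey q-values (with the 0.05 line) against genomic
#' position, chromosomes laid side by side. All regions must be of one kind.
#'
#' @param results A [run_region_comparison()] table (single region kind).
#' @param value `"p"` or `"q"`.
#' @param alpha Significance level for the q-value line (default 0.05).
#' @return A list with `plot` (ggplot) and `series` (tibble `chrom`,
#'   `label`, `x` — cumulative genome coordinate of the region midpoint —
#'   `value`, `height`, `line` — the threshold height drawn).
#' @export
plot_manhattan <- function(results, value = c("p", "q"), alpha = 0.05) {
  value <- match.arg(value)
  check_cols(results, c("kind", "chrom", "label", "start", "end",
                        "p_value", "q_value", "bonferroni_alpha"), "results")
  if (nrow(results) == 0) stop("plot_manhattan: empty results", call. = FALSE)
  if (length(unique(results$kind)) > 1) {
    stop("plot_manhattan: results mix several region kinds; plot one at a time",
         call. = FALSE)
  }
  res <- results[!is.na(results$p_value), , drop = FALSE]
  chroms <- unique(res$chrom)
  extent <- vapply(chroms, function(ch) max(res$end[res$chrom == ch]), 0)
  offset <- stats::setNames(cumsum(c(0, extent[-length(extent)])), chroms)
  v <- if (value == "p") res$p_value else res$q_value
  line <- if (value == "p") {
    h <- unique(res$bonferroni_alpha)
    -log10(h[1])
  } else {
    -log10(alpha)
  }
  series <- tibble::tibble(
    chrom = res$chrom, label = res$label,
    x = offset[res$chrom] + (res$start + res$end) / 2,
    value = v,
    height = -log10(pmax(v, .Machine$double.xmin)),
    line = line)
  g <- ggplot2::ggplot(series, ggplot2::aes(x = .data$x, y = .data$height,
                                            colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = line, linetype = "dashed", colour = "red") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "genome position (bp, chromosomes concatenated)",
                  y = if (value == "p") expression(-log[10](italic(p))) else
                    expression(-log[10](italic(Q)))) +
    ggplot2::theme_minimal()
  list(plot = g, series = series)
}
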