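#' Read per-pool variant records from a VCF
#'
#' Parses a single-sample VCF (v4.x) holding the pooled variant calls of one
#' sequencing pool and returns one row per biallelic SNV with total and
#' alternate read depths. Multi-allelic sites are split into one record per
#' alternate allele; following the SNP-index definition ("variant reads over
#' all reads"), every split record keeps the full site depth as its
#' denominator. Indels and other non-SNV alleles are dropped with a message.
#'
#' @param path Path to a VCF file with one sample column.
#' @param pool_label Identifier attached to every record (e.g. `"ET"`, `"XT"`,
#'   `"N"`).
#' @param depth_field Preferred source of the total site depth: `"AD"` (sum of
#'   the per-allele depths in FORMAT/AD, the default) or `"DP"` (FORMAT/DP,
#'   falling back to INFO/DP). Whichever is chosen, FORMAT/AD must be present
#'   to supply the per-allele alternate depth.
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_depth`, `mismatch_count` (from the optional INFO/MM annotation; `NA`
#'   when absent) and `pool_label`, sorted by `(chrom, pos, ref, alt)`.
#'   Chromosome names are stored without a `"chr"` prefix.
#' @export
read_pool_vcf <- function(path, pool_label, depth_field = c("AD", "DP")) {
  depth_field <- match.arg(depth_field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty_pool_records(pool_label))
  }
  chrom <- norm_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_str <- fix[, "ALT"]

  ad_str <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "AD") else NULL
  dp_fmt <- if (ncol(v@gt) >= 2) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL
  dp_info <- suppressWarnings(vcfR::extract.info(v, element = "DP", as.numeric = TRUE))
  mm_info <- suppressWarnings(vcfR::extract.info(v, element = "MM", as.numeric = TRUE))
  if (is.null(ad_str) || all(is.na(ad_str))) {
    stop(sprintf("VCF %s carries no FORMAT/AD allele depths (first site %s:%d); cannot derive alt_depth",
                 path, chrom[1], pos[1]), call. = FALSE)
  }
  ad_list <- lapply(strsplit(ifelse(is.na(ad_str[, 1]), "", ad_str[, 1]), ","),
                    function(a) suppressWarnings(as.integer(a)))
  alt_list <- strsplit(alt_str, ",")

  out <- vector("list", length(pos))
  n_dropped_nonsnv <- 0L
  for (i in seq_along(pos)) {
    ad <- ad_list[[i]]
    if (length(ad) < 2 || anyNA(ad)) {
      stop(sprintf("missing or malformed depth fields at site %s:%d in %s",
                   chrom[i], pos[i], path), call. = FALSE)
    }
    depth_i <- if (depth_field == "AD") {
      sum(ad)
    } else if (!is.null(dp_fmt) && !is.na(dp_fmt[i, 1])) {
      as.integer(dp_fmt[i, 1])
    } else if (!is.na(dp_info[i])) {
      as.integer(dp_info[i])
    } else {
      stop(sprintf("missing DP depth field at site %s:%d in %s",
                   chrom[i], pos[i], path), call. = FALSE)
    }
    alts <- alt_list[[i]]
    keep <- nchar(ref[i]) == 1L & nchar(alts) == 1L & alts %in% c("A", "C", "G", "T")
    n_dropped_nonsnv <- n_dropped_nonsnv + sum(!keep)
    if (!any(keep)) next
    idx <- which(keep)
    out[[i]] <- tibble::tibble(
      chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[idx],
      depth = depth_i, alt_depth = ad[1L + idx],
      mismatch_count = if (is.null(mm_info)) NA_real_ else mm_info[i]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_pool_records(pool_label))
  if (any(res$alt_depth > res$depth)) {
    bad <- res[res$alt_depth > res$depth, ][1, ]
    stop(sprintf("alt depth exceeds total depth at %s:%d in %s",
                 bad$chrom, bad$pos, path), call. = FALSE)
  }
  res$pool_label <- pool_label
  if (is.unsorted(order(res$chrom, res$pos))) {
    # ordering is re-established below either way; warn so unsorted inputs are visible
    warning(sprintf("records in %s were not position-sorted; sorting", path), call. = FALSE)
  }
  res <- sort_by_position(res)
  if (n_dropped_nonsnv > 0) {
    message(sprintf("read_pool_vcf: dropped %d non-SNV allele(s) from %s", n_dropped_nonsnv, path))
  }
  res
}

empty_pool_records <- function(pool_label) {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    depth = integer(), alt_depth = integer(), mismatch_count = numeric(),
    pool_label = character()
  )
}

#' Read a UCSC-style cytogenetic band file
#'
#' Expects the 5-column tab-separated `cytoBand.txt` dialect:
#' chromosome, 0-based start, exclusive end, band name, Giemsa stain.
#' Bands on one chromosome must be non-overlapping.
#'
#' @param path Path to the cytoband file (no header).
#' @return A tibble with columns `chrom` (bare, no `"chr"` prefix), `start`
#'   (0-based inclusive), `end` (exclusive), `band_name`, `stain`, sorted
#'   within chromosome.
#' @export
read_cytobands <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "band_name", "stain"),
                         colClasses = c("character", "numeric", "numeric", "character", "character"))
  x <- tibble::as_tibble(x)
  x$chrom <- norm_chrom(x$chrom)
  if (any(!is.finite(x$start) | !is.finite(x$end) | x$start >= x$end)) {
    bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start >= x$end)[1]
    stop(sprintf("malformed cytoband interval on line %d of %s", bad, path), call. = FALSE)
  }
  x <- x[order(x$chrom, x$start), ]
  overlap <- unlist(lapply(split(x, x$chrom), function(b) {
    n <- nrow(b)
    if (n < 2) return(FALSE)
    any(b$start[-1] < b$end[-n])
  }))
  if (any(overlap)) {
    stop(sprintf("overlapping cytobands on chromosome %s in %s",
                 names(overlap)[overlap][1], path), call. = FALSE)
  }
  x
}

#' Read target loci from a BED file
#'
#' Reads a BED3/BED4 file of exome target loci, merges overlapping or
#' book-ended intervals per chromosome, and returns them sorted. Merged
#' intervals concatenate the names of their members with `"+"`.
#'
#' @param path Path to a BED file (0-based half-open intervals, no header).
#' @return A tibble with columns `chrom`, `start` (0-based), `end`
#'   (exclusive) and `name`.
#' @export
read_target_loci <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), name = character()))
  }
  parts <- strsplit(lines, "\t")
  n_fld <- lengths(parts)
  if (any(n_fld < 3)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 which(n_fld < 3)[1], path), call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
  if (length(bad) > 0) {
    stop(sprintf("malformed BED coordinates on line %d of %s", bad[1], path), call. = FALSE)
  }
  x <- tibble::tibble(
    chrom = norm_chrom(vapply(parts, `[[`, "", 1)),
    start = start, end = end,
    name = ifelse(n_fld >= 4, vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, ""),
                  NA_character_)
  )
  x$name[is.na(x$name)] <- sprintf("locus_%d", seq_len(nrow(x)))[is.na(x$name)]
  merge_loci(x)
}

# Merge overlapping/book-ended 0-based half-open loci per chromosome (IRanges).
merge_loci <- function(x) {
  out <- lapply(split(x, x$chrom), function(b) {
    ir <- IRanges::IRanges(start = b$start + 1, end = b$end)  # to 1-based closed
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    nm <- vapply(S4Vectors::mcols(red)$revmap, function(ii) {
      paste(unique(b$name[ii]), collapse = "+")
    }, "")
    tibble::tibble(chrom = b$chrom[1],
                   start = IRanges::start(red) - 1,
                   end = as.numeric(IRanges::end(red)),
                   name = nm)
  })
  res <- dplyr::bind_rows(out)
  res[order(res$chrom, res$start), ]
}

#' Write a pipeline result table to TSV
#'
#' Writes any of the pipeline's tabular outputs (paired deltas, window
#' statistics, region test results, ...) as a tab-separated file with a
#' header. Doubles are serialized with full round-trip precision, so reading
#' the file back with [read_results_table()] reproduces the values exactly.
#'
#' @param x A data frame of homogeneous records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a table written by [write_results_table()]
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(chrom = readr::col_character(),
                                          .default = readr::col_guess()))
}
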