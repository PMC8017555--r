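#' QC-classify HiChIP valid pairs
#'
#' Deduplicates valid interaction pairs on the exact coordinate/strand tuple
#' (chrom1, pos1, strand1, chrom2, pos2, strand2), keeping the first
#' occurrence, and classifies the unique pairs as trans (different
#' chromosomes), cis long-range (same chromosome, separation strictly
#' greater than \code{cis_cutoff}) or cis short-range. Percentages are
#' reported relative to the total number of valid pairs, so the three
#' category percentages sum to the unique percentage — the partition
#' identity that standard Hi-C QC tables exhibit.
#'
#' @param pairs data.frame of valid pairs with columns \code{read_id},
#'   \code{chrom1}, \code{pos1}, \code{strand1}, \code{chrom2}, \code{pos2},
#'   \code{strand2}.
#' @param cis_cutoff separation (bp) above which a cis pair is long-range
#'   (default 20000).
#' @return list of class \code{qc_report} with counts
#'   (\code{total_valid}, \code{unique_valid}, \code{duplicates},
#'   \code{cis_long}, \code{cis_short}, \code{trans}) and matching
#'   percentages \code{pct_*} relative to \code{total_valid}.
#' @export
qc_valid_pairs <- function(pairs, cis_cutoff = 20000) {
  stop_if(!is.data.frame(pairs) || nrow(pairs) == 0L,
          "qc_valid_pairs needs a non-empty pair table")
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  dup <- duplicated(key)
  uni <- pairs[!dup, , drop = FALSE]
  is_trans <- uni$chrom1 != uni$chrom2
  sep <- abs(uni$pos2 - uni$pos1)
  is_cis_long <- !is_trans & sep > cis_cutoff
  is_cis_short <- !is_trans & !is_cis_long
  total <- nrow(pairs)
  counts <- list(
    total_valid = total,
    unique_valid = nrow(uni),
    duplicates = sum(dup),
    cis_long = sum(is_cis_long),
    cis_short = sum(is_cis_short),
    trans = sum(is_trans)
  )
  pct <- lapply(counts[c("unique_valid", "duplicates", "cis_long",
                         "cis_short", "trans")],
                function(k) 100 * k / total)
  names(pct) <- paste0("pct_", c("unique", "duplicates", "cis_long",
                                 "cis_short", "trans"))
  structure(c(counts, pct, list(cis_cutoff = cis_cutoff)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Valid pairs: %d (unique %.1f%%, duplicates %.1f%%)\n",
              x$total_valid, x$pct_unique, x$pct_duplicates))
  cat(sprintf("  cis long-range (>%d bp): %.1f%%\n", x$cis_cutoff, x$pct_cis_long))
  cat(sprintf("  cis short-range: %.1f%%\n", x$pct_cis_short))
  cat(sprintf("  trans: %.1f%%\n", x$pct_trans))
  invisible(x)
}

#' Bin cis valid pairs into fixed-resolution contact counts
#'
#' Assigns each end of every unique cis pair to a genomic bin
#' (\code{floor((pos - 1) / resolution)}, so 1-based positions 1..resolution
#' fall in bin 0) and aggregates counts per unordered bin pair. Trans pairs
#' are discarded and their count reported via a message. Input pairs should
#' already be deduplicated (see \code{\link{qc_valid_pairs}}).
#'
#' @param pairs data.frame of valid pairs (same columns as
#'   \code{\link{qc_valid_pairs}}).
#' @param resolution bin width in bp (default 5000).
#' @return data.frame of class \code{bin_pairs} with columns \code{chrom},
#'   \code{bin_i}, \code{bin_j} (\code{bin_i <= bin_j}), \code{count} and
#'   \code{distance} (mid-to-mid, i.e. \code{(bin_j - bin_i) * resolution});
#'   the resolution is attached as attribute \code{resolution}.
#' @export
bin_pairs <- function(pairs, resolution = 5000) {
  stop_if(!is.numeric(resolution) || resolution <= 0,
          "resolution must be a positive number of bp")
  cis <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  n_trans <- nrow(pairs) - nrow(cis)
  if (n_trans > 0) message(sprintf("discarding %d trans pair(s)", n_trans))
  b1 <- floor((cis$pos1 - 1) / resolution)
  b2 <- floor((cis$pos2 - 1) / resolution)
  bi <- pmin(b1, b2)
  bj <- pmax(b1, b2)
  key <- paste(cis$chrom1, bi, bj, sep = "\r")
  agg <- tapply(rep(1L, length(key)), key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    bin_i = as.integer(vapply(parts, `[`, "", 2L)),
    bin_j = as.integer(vapply(parts, `[`, "", 3L)),
    count = as.integer(agg),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$bin_i, out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  out$distance <- (out$bin_j - out$bin_i) * resolution
  attr(out, "resolution") <- resolution
  class(out) <- c("bin_pairs", "data.frame")
  out
}
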