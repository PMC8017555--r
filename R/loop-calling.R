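#' Enumerate the candidate bin-pair universe for loop testing
#'
#' All cis bin pairs whose mid-to-mid separation lies in
#' \code{[d_min, d_max]}, including pairs with zero observed count. This is
#' the multiplicity universe over which the decay model is normalized and
#' BH adjustment is performed.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param resolution bin width in bp.
#' @param d_min,d_max distance bounds in bp.
#' @return data.frame with \code{chrom}, \code{bin_i}, \code{bin_j},
#'   \code{distance}.
#' @keywords internal
#' @export
candidate_bin_pairs <- function(chrom_sizes, resolution,
                                d_min = 20000, d_max = 2e6) {
  stop_if(is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""),
          "chrom_sizes must be a named vector")
  g_min <- max(1L, as.integer(ceiling(d_min / resolution)))
  g_max <- as.integer(floor(d_max / resolution))
  out <- lapply(names(chrom_sizes), function(ch) {
    n_bins <- as.integer(ceiling(chrom_sizes[[ch]] / resolution))
    gaps <- g_min:g_max
    gaps <- gaps[gaps < n_bins]
    if (length(gaps) == 0L) return(NULL)
    n_per_gap <- n_bins - gaps
    i <- unlist(lapply(seq_along(gaps),
                       function(t) 0:(n_per_gap[t] - 1L)), use.names = FALSE)
    g <- rep(gaps, n_per_gap)
    data.frame(chrom = ch, bin_i = i, bin_j = i + g,
               distance = g * resolution, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit an equal-occupancy distance-decay model to binned contacts
#'
#' Partitions the in-range candidate bin pairs (observed and zero-count
#' alike) into \code{n_distance_bins} distance strata of approximately equal
#' pair counts, estimates the per-pair contact probability in each stratum
#' as (stratum count sum) / (total count * pairs in stratum), and enforces
#' monotone non-increase over distance with weighted
#' pool-adjacent-violators. Queries interpolate linearly between stratum
#' mean distances and are clamped at the range ends.
#'
#' @param binpairs \code{bin_pairs} table from \code{\link{bin_pairs}}.
#' @param chrom_sizes named chromosome lengths (bp).
#' @param n_distance_bins number of equal-occupancy distance strata
#'   (default 200).
#' @param d_min,d_max modeled distance range in bp (defaults 20 kb, 2 Mb).
#' @return object of class \code{decay_model} with the stratum mean
#'   distances, fitted per-pair probabilities, and the total in-range count.
#' @export
fit_distance_decay <- function(binpairs, chrom_sizes, n_distance_bins = 200,
                               d_min = 20000, d_max = 2e6) {
  resolution <- attr(binpairs, "resolution")
  stop_if(is.null(resolution), "binpairs must carry a resolution attribute")
  cand <- candidate_bin_pairs(chrom_sizes, resolution, d_min, d_max)
  stop_if(is.null(cand) || nrow(cand) < n_distance_bins,
          "fewer candidate bin pairs (%d) than distance strata (%d)",
          if (is.null(cand)) 0L else nrow(cand), n_distance_bins)

  # candidate pairs per distance gap, pooled over chromosomes
  gap <- cand$distance / resolution
  n_per_gap <- table(gap)
  gaps <- as.integer(names(n_per_gap))
  n_per_gap <- as.integer(n_per_gap)

  obs <- binpairs[binpairs$distance >= d_min & binpairs$distance <= d_max, ,
                  drop = FALSE]
  k_per_gap <- integer(length(gaps))
  if (nrow(obs) > 0) {
    og <- obs$distance / resolution
    agg <- tapply(obs$count, og, sum)
    idx <- match(as.integer(names(agg)), gaps)
    keep <- !is.na(idx)
    k_per_gap[idx[keep]] <- as.integer(agg[keep])
  }
  total_k <- sum(k_per_gap)

  # equal-occupancy strata over candidate pairs, in distance order
  ord <- order(gaps)
  gaps <- gaps[ord]; n_per_gap <- n_per_gap[ord]; k_per_gap <- k_per_gap[ord]
  cum_pairs <- cumsum(n_per_gap)
  total_pairs <- cum_pairs[length(cum_pairs)]
  n_strata <- min(n_distance_bins, length(gaps))
  stratum <- pmin(ceiling(cum_pairs / (total_pairs / n_strata)), n_strata)

  n_s <- as.numeric(tapply(n_per_gap, stratum, sum))
  k_s <- as.numeric(tapply(k_per_gap, stratum, sum))
  d_s <- as.numeric(tapply(gaps * n_per_gap, stratum, sum)) / n_s * resolution

  if (total_k == 0) {
    warning("all in-range counts are zero; returning a flat decay model")
    p_s <- rep(1 / total_pairs, length(n_s))
  } else {
    p_raw <- k_s / (total_k * n_s)
    p_s <- pava_decreasing(p_raw, w = n_s)
  }
  structure(
    list(distance = d_s, p = p_s, n_pairs = n_s, total_count = total_k,
         d_min = d_min, d_max = d_max, resolution = resolution),
    class = "decay_model"
  )
}

#' Query a decay model at arbitrary distances
#'
#' @param model \code{decay_model} from \code{\link{fit_distance_decay}}.
#' @param d distances in bp.
#' @return per-pair contact probabilities, non-increasing in \code{d}.
#' @export
decay_prob <- function(model, d) {
  stopifnot(inherits(model, "decay_model"))
  if (length(model$distance) == 1L) return(rep(model$p, length(d)))
  stats::approx(model$distance, model$p, xout = d, rule = 2)$y
}

#' Estimate per-bin multiplicative coverage bias
#'
#' Marginal coverage of each genomic bin (sum of counts over all pairs
#' touching the bin), normalized so the mean bias over covered bins is 1.
#' Bins with zero coverage get bias 0 and are excluded from loop testing.
#'
#' When a fitted decay model is supplied, the coverage of each bin is
#' divided by its position-expected coverage
#' \eqn{e_i = \sum_j p(d_{ij})} over in-range partners before
#' normalization. This matters on short chromosomes: bins near an end see
#' partners on one side only, so their raw marginal coverage
#' underestimates their true bias and end-proximal pairs would otherwise
#' be systematically over-called.
#'
#' @param binpairs \code{bin_pairs} table.
#' @param chrom_sizes named chromosome lengths (bp).
#' @param decay optional \code{decay_model}; when supplied, coverage is
#'   taken over in-range pairs and corrected for position-expected
#'   coverage.
#' @param d_min,d_max distance range used with \code{decay}.
#' @return data.frame with \code{chrom}, \code{bin}, \code{coverage},
#'   \code{bias}.
#' @export
estimate_bias <- function(binpairs, chrom_sizes, decay = NULL,
                          d_min = 20000, d_max = 2e6) {
  resolution <- attr(binpairs, "resolution")
  stop_if(is.null(resolution), "binpairs must carry a resolution attribute")
  stop_if(nrow(binpairs) == 0L, "empty bin-pair table")
  grid <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n_bins <- as.integer(ceiling(chrom_sizes[[ch]] / resolution))
    data.frame(chrom = ch, bin = 0:(n_bins - 1L), stringsAsFactors = FALSE)
  }))
  key <- paste(grid$chrom, grid$bin)
  use <- binpairs
  if (!is.null(decay)) {
    use <- use[use$distance >= d_min & use$distance <= d_max, , drop = FALSE]
  }
  cov <- numeric(nrow(grid))
  add <- function(ch, b, k) {
    idx <- match(paste(ch, b), key)
    agg <- tapply(k, idx, sum)
    cov[as.integer(names(agg))] <<- cov[as.integer(names(agg))] + agg
  }
  add(use$chrom, use$bin_i, use$count)
  add(use$chrom, use$bin_j, use$count)
  grid$coverage <- cov
  if (!is.null(decay)) {
    cand <- candidate_bin_pairs(chrom_sizes, resolution, d_min, d_max)
    p_d <- decay_prob(decay, cand$distance)
    e <- numeric(nrow(grid))
    acc <- function(ch, b, p) {
      idx <- match(paste(ch, b), key)
      agg <- tapply(p, idx, sum)
      e[as.integer(names(agg))] <<- e[as.integer(names(agg))] + agg
    }
    acc(cand$chrom, cand$bin_i, p_d)
    acc(cand$chrom, cand$bin_j, p_d)
    ratio <- ifelse(cov > 0 & e > 0, cov / e, 0)
  } else {
    ratio <- cov
  }
  nz <- ratio > 0
  grid$bias <- ifelse(nz, ratio / mean(ratio[nz]), 0)
  grid
}

#' Call FDR-significant loops with a bias-corrected binomial model
#'
#' For every candidate bin pair in the distance range, the expected contact
#' probability is \eqn{\pi_{ij} = p(d_{ij}) b_i b_j / Z}, where p(d) is the
#' fitted decay probability, b the per-bin bias, and Z renormalizes over the
#' candidate universe so probabilities sum to 1. The observed count k is
#' tested against Binomial(N, \eqn{\pi_{ij}}) with N the total in-range
#' count; upper-tail p-values are BH-adjusted over all candidates with
#' nonzero expected probability, and pairs with q below the FDR threshold
#' are reported as loops.
#'
#' @param binpairs \code{bin_pairs} table.
#' @param decay \code{decay_model} fitted on the same binning.
#' @param bias bias table from \code{\link{estimate_bias}}.
#' @param chrom_sizes named chromosome lengths (bp).
#' @param d_min,d_max distance filter in bp (defaults 20 kb and 2 Mb).
#' @param fdr FDR threshold in (0, 1] (default 0.01).
#' @param source label for the library/cell line (default "sample").
#' @return data.frame of class \code{loops} with columns \code{chrom1},
#'   \code{start1}, \code{end1}, \code{chrom2}, \code{start2}, \code{end2}
#'   (half-open 0-based anchors of one bin each), \code{count}, \code{mu},
#'   \code{p_value}, \code{q_value}, \code{distance}, \code{source};
#'   resolution attached as an attribute.
#' @export
call_loops <- function(binpairs, decay, bias, chrom_sizes,
                       d_min = 20000, d_max = 2e6, fdr = 0.01,
                       source = "sample") {
  stop_if(!is.numeric(fdr) || fdr <= 0 || fdr > 1, "fdr must be in (0, 1]")
  resolution <- attr(binpairs, "resolution")
  stop_if(!identical(resolution, decay$resolution),
          "decay model and binning use different resolutions")
  cand <- candidate_bin_pairs(chrom_sizes, resolution, d_min, d_max)
  bias_key <- paste(bias$chrom, bias$bin)
  b_i <- bias$bias[match(paste(cand$chrom, cand$bin_i), bias_key)]
  b_j <- bias$bias[match(paste(cand$chrom, cand$bin_j), bias_key)]
  p_d <- decay_prob(decay, cand$distance)
  w <- p_d * b_i * b_j
  testable <- which(w > 0)
  stop_if(length(testable) == 0L, "no testable candidate pairs")
  pi_ij <- w[testable] / sum(w[testable])

  obs <- binpairs[binpairs$distance >= d_min & binpairs$distance <= d_max, ,
                  drop = FALSE]
  k <- integer(length(testable))
  m <- match(paste(obs$chrom, obs$bin_i, obs$bin_j),
             paste(cand$chrom[testable], cand$bin_i[testable],
                   cand$bin_j[testable]))
  keep <- !is.na(m)
  k[m[keep]] <- obs$count[keep]
  N <- sum(k)

  pval <- rep(1, length(testable))
  nz <- k > 0
  pval[nz] <- stats::pbinom(k[nz] - 1L, N, pi_ij[nz], lower.tail = FALSE)
  qval <- stats::p.adjust(pval, method = "BH")

  sig <- which(qval <= fdr & nz)
  idx <- testable[sig]
  out <- data.frame(
    chrom1 = cand$chrom[idx],
    start1 = cand$bin_i[idx] * resolution,
    end1 = (cand$bin_i[idx] + 1) * resolution,
    chrom2 = cand$chrom[idx],
    start2 = cand$bin_j[idx] * resolution,
    end2 = (cand$bin_j[idx] + 1) * resolution,
    count = k[sig],
    mu = N * pi_ij[sig],
    p_value = pval[sig],
    q_value = qval[sig],
    distance = cand$distance[idx],
    source = rep(source, length(sig)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom1, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resolution") <- resolution
  class(out) <- c("loops", "data.frame")
  out
}

#' Merge loop sets called from different libraries
#'
#' Union of loop records; loops whose two anchors are bin-identical are
#' collapsed into one record carrying the deduplicated union of source
#' labels and the statistics of the most significant (minimum-q) member.
#'
#' @param loop_sets list of \code{loops} tables at the same resolution.
#' @return merged \code{loops} table.
#' @export
merge_loops <- function(loop_sets) {
  stop_if(length(loop_sets) == 0L, "no loop sets to merge")
  res <- unique(vapply(loop_sets, function(x) attr(x, "resolution"), 0))
  stop_if(length(res) != 1L, "loop sets were called at different resolutions")
  all <- do.call(rbind, lapply(loop_sets, as.data.frame))
  key <- paste(all$chrom1, all$start1, all$chrom2, all$start2)
  merged <- lapply(split(seq_len(nrow(all)), key), function(rows) {
    sub <- all[rows, , drop = FALSE]
    best <- sub[which.min(sub$q_value), , drop = FALSE]
    srcs <- sort(unique(unlist(strsplit(sub$source, ",", fixed = TRUE))))
    best$source <- paste(srcs, collapse = ",")
    best
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom1, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resolution") <- res
  class(out) <- c("loops", "data.frame")
  out
}
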