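#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study and validates ranges.
#' Defaults describe the conditions the pipeline is designed for: 15 GWAS
#' risk loci of 100 SNPs with moderately strong local LD, a well-powered
#' causal signal, one 1 Mb chromosome of 5 kb bins with a million cis
#' contacts following a power-law distance decay (the contact density per
#' Mb of a deeply sequenced HiChIP library), ten planted loops at 5-fold
#' over background, forty genes, and a 20 vs 20 tumor/normal expression
#' matrix with a quarter of genes shifted two log2-fold.
#'
#' @param seed integer RNG seed; all generators are pure functions of
#'   (config, seed).
#' @param n_haplotypes haplotypes backing the genotype panel (default
#'   \code{2 * n_individuals}).
#' @param n_snps_per_locus,n_loci panel dimensions per locus and locus count.
#' @param adjacent_corr target correlation of neighboring SNP dosages,
#'   in [0, 1).
#' @param maf_range allele-frequency range (0, 0.5], lower bound > 0.
#' @param n_individuals GWAS sample size.
#' @param causal_effect per-allele effect of the planted causal variant on
#'   a standardized quantitative trait.
#' @param snp_spacing bp between adjacent panel SNPs.
#' @param chrom_length,bin_resolution chromosome length and contact bin
#'   width (bp).
#' @param sequencing_depth total cis contact count.
#' @param decay_exponent power-law exponent of contact probability vs
#'   distance (> 0).
#' @param bias_sd SD of log per-bin multiplicative bias (>= 0).
#' @param loop_fold fold-change applied to planted loop means (>= 1).
#' @param n_planted_loops planted loop count.
#' @param overdispersion negative-binomial overdispersion of counts
#'   (0 = Poisson, the default, which keeps the loop-caller null exact).
#' @param n_genes,gene_span_range gene count and span range (bp).
#' @param n_tumor,n_normal expression group sizes.
#' @param de_fraction,de_lfc fraction of genes shifted in tumors and the
#'   log2 shift.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_haplotypes = NULL,
                       n_snps_per_locus = 100L,
                       n_loci = 15L,
                       adjacent_corr = 0.6,
                       maf_range = c(0.05, 0.5),
                       n_individuals = 5000L,
                       causal_effect = 0.14,
                       snp_spacing = 500L,
                       chrom_length = 1e6,
                       bin_resolution = 5000L,
                       sequencing_depth = 1e6,
                       decay_exponent = 1,
                       bias_sd = 0.3,
                       loop_fold = 5,
                       n_planted_loops = 10L,
                       overdispersion = 0,
                       n_genes = 40L,
                       gene_span_range = c(5000, 20000),
                       n_tumor = 20L,
                       n_normal = 20L,
                       de_fraction = 0.25,
                       de_lfc = 2) {
  if (is.null(n_haplotypes)) n_haplotypes <- 2L * n_individuals
  stop_if(n_haplotypes < 2, "need at least 2 haplotypes")
  stop_if(n_snps_per_locus < 1, "need at least 1 SNP per locus")
  stop_if(adjacent_corr < 0 || adjacent_corr >= 1,
          "adjacent_corr must lie in [0, 1)")
  stop_if(maf_range[1] <= 0 || maf_range[2] > 0.5 ||
            maf_range[1] >= maf_range[2],
          "degenerate maf_range: need 0 < lower < upper <= 0.5")
  stop_if(decay_exponent <= 0, "decay_exponent must be > 0")
  stop_if(bias_sd < 0, "bias_sd must be >= 0")
  stop_if(loop_fold < 1, "loop_fold must be >= 1")
  stop_if(n_planted_loops < 0, "n_planted_loops must be >= 0")
  stop_if(de_fraction < 0 || de_fraction > 1, "de_fraction must be in [0, 1]")
  stop_if(sequencing_depth < 0, "sequencing_depth must be >= 0")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# Draw one haplotype block by first-order Markov copying: each SNP copies
# the previous SNP's allele with probability adjacent_corr, else draws a
# fresh Bernoulli(maf). With a shared maf this gives adjacent dosage
# correlation equal to adjacent_corr in expectation. adjacent_corr may be
# a per-SNP vector (copy probability into each SNP), giving LD blocks of
# varying strength.
sim_haplotypes <- function(n_hap, mafs, adjacent_corr) {
  m <- length(mafs)
  corr <- rep_len(adjacent_corr, m)
  H <- matrix(0L, n_hap, m)
  H[, 1] <- stats::rbinom(n_hap, 1L, mafs[1])
  if (m > 1) for (j in 2:m) {
    copy <- stats::runif(n_hap) < corr[j]
    fresh <- stats::rbinom(n_hap, 1L, mafs[j])
    H[, j] <- ifelse(copy, H[, j - 1], fresh)
  }
  H
}

#' Simulate an LD-structured genotype panel
#'
#' Haplotypes follow a first-order Markov copying process calibrated so the
#' dosage correlation of neighboring SNPs is \code{adjacent_corr} on
#' average; per-SNP MAFs are drawn uniformly from \code{maf_range}.
#' Columns that come out monomorphic by sampling chance have a single
#' haplotype allele flipped so the panel is valid.
#'
#' @param config \code{sim_config}.
#' @param seed RNG seed (default \code{config$seed}).
#' @param pos_offset position of the first SNP (bp, default 1).
#' @param adjacent_corr copy probability, scalar or per-SNP vector
#'   (default \code{config$adjacent_corr}).
#' @return \code{genotype_panel} (see \code{\link{genotype_panel}}).
#' @export
sim_panel <- function(config, seed = config$seed, pos_offset = 1,
                      adjacent_corr = config$adjacent_corr) {
  set.seed(seed)
  m <- config$n_snps_per_locus
  n <- config$n_individuals
  mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  H <- sim_haplotypes(2L * n, mafs, adjacent_corr)
  for (j in seq_len(m)) {  # guard against monomorphic columns at tiny n
    s <- sum(H[, j])
    if (s == 0L) H[1, j] <- 1L
    if (s == 2L * n) H[1, j] <- 0L
  }
  G <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
       H[seq(2, 2 * n, by = 2), , drop = FALSE]
  pos <- pos_offset + (seq_len(m) - 1L) * config$snp_spacing
  genotype_panel(G, pos)
}

#' Simulate GWAS summary statistics for one locus
#'
#' Phenotype \eqn{y = effect \cdot g_{causal} + noise} with unit total
#' variance; every panel SNP is then tested by marginal least squares,
#' yielding per-variant slope and standard error — the summary-statistic
#' input to fine-mapping.
#'
#' @param panel \code{genotype_panel}.
#' @param causal_variant id of the causal SNP (must be in the panel).
#' @param effect per-allele effect size.
#' @param seed RNG seed for the phenotype noise.
#' @param locus_id,chrom labels attached to the records.
#' @return list with \code{records} (data.frame: variant_id, chrom, pos,
#'   beta, se, locus_id) and \code{truth} (the causal variant id).
#' @export
sim_gwas_locus <- function(panel, causal_variant, effect, seed = 1,
                           locus_id = "locus1", chrom = panel$chrom) {
  n <- nrow(panel$dosage)
  stop_if(n < 10, "need at least 10 individuals for a GWAS locus")
  ci <- match(causal_variant, panel$variant_id)
  stop_if(is.na(ci), "causal variant '%s' is not in the panel", causal_variant)
  set.seed(seed)
  g <- panel$dosage[, ci]
  var_g <- stats::var(g)
  noise_var <- 1 - effect^2 * var_g
  stop_if(noise_var <= 0,
          "effect too large: explained variance exceeds total variance 1")
  y <- effect * g + stats::rnorm(n, sd = sqrt(noise_var))

  Gc <- scale(panel$dosage, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  ssx <- colSums(Gc^2)
  beta <- as.numeric(crossprod(Gc, yc)) / ssx
  rss <- sum(yc^2) - beta^2 * ssx
  se <- sqrt(pmax(rss, 0) / (n - 2) / ssx)
  list(
    records = data.frame(
      variant_id = panel$variant_id, chrom = chrom, pos = panel$pos,
      beta = beta, se = se, locus_id = locus_id, stringsAsFactors = FALSE),
    truth = list(causal_variant = causal_variant)
  )
}

#' Simulate binned HiChIP contact counts
#'
#' Counts for each cis bin pair are Poisson (or negative binomial when
#' \code{overdispersion > 0}) around
#' \eqn{\mu_{ij} = depth \cdot p(d_{ij}) b_i b_j} with a power-law decay
#' \eqn{p(d) \propto d^{-decay\_exponent}} and log-normal per-bin bias;
#' planted loop pairs have their means multiplied by \code{loop_fold}.
#'
#' @param config \code{sim_config}.
#' @param seed RNG seed (default \code{config$seed}).
#' @param planted_loops optional data.frame with \code{bin_i}, \code{bin_j}
#'   (overrides random placement); separations must respect the
#'   20 kb - 2 Mb loop-calling range.
#' @param chrom chromosome label.
#' @return list with \code{binpairs} (\code{bin_pairs} table of nonzero
#'   counts), \code{truth} (planted loop anchor coordinates) and
#'   \code{chrom_sizes}.
#' @export
sim_contacts <- function(config, seed = config$seed, planted_loops = NULL,
                         chrom = "chr1") {
  set.seed(seed)
  res <- config$bin_resolution
  n_bins <- as.integer(ceiling(config$chrom_length / res))
  g_min <- as.integer(ceiling(20000 / res))
  g_max <- min(n_bins - 1L, as.integer(floor(2e6 / res)))

  if (is.null(planted_loops)) {
    n_pl <- config$n_planted_loops
    planted_loops <- if (n_pl > 0) {
      # log-uniform separations: loop distances in H3K27ac contact maps
      # are strongly short-range skewed (median well under the range
      # midpoint)
      gaps <- pmin(round(exp(stats::runif(n_pl, log(g_min), log(g_max)))),
                   g_max)
      i <- vapply(gaps, function(g)
        sample.int(n_bins - g, 1L) - 1L, 0L)
      unique(data.frame(bin_i = i, bin_j = i + gaps))
    } else data.frame(bin_i = integer(), bin_j = integer())
  }
  stop_if(any(planted_loops$bin_j >= n_bins | planted_loops$bin_i < 0),
          "planted loop bin beyond chromosome end")
  sep <- (planted_loops$bin_j - planted_loops$bin_i) * res
  stop_if(any(sep < 20000 | sep > 2e6),
          "planted loops must lie within the 20 kb - 2 Mb range")

  # all cis pairs with gap >= 1
  gaps <- 1:(n_bins - 1L)
  n_per_gap <- n_bins - gaps
  i <- unlist(lapply(gaps, function(g) 0:(n_bins - 1L - g)), use.names = FALSE)
  g <- rep(gaps, n_per_gap)
  j <- i + g
  bias <- exp(stats::rnorm(n_bins, 0, config$bias_sd))
  bias <- bias / mean(bias)
  w <- (g * res)^(-config$decay_exponent) * bias[i + 1L] * bias[j + 1L]
  mu <- config$sequencing_depth * w / sum(w)
  if (nrow(planted_loops) > 0) {
    key <- paste(i, j)
    hit <- match(paste(planted_loops$bin_i, planted_loops$bin_j), key)
    stop_if(anyNA(hit), "planted loop outside the candidate pair grid")
    mu[hit] <- mu[hit] * config$loop_fold
  }
  k <- if (config$overdispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$overdispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  nz <- k > 0
  bp <- data.frame(chrom = rep(chrom, sum(nz)), bin_i = i[nz],
                   bin_j = j[nz], count = k[nz], stringsAsFactors = FALSE)
  bp$distance <- (bp$bin_j - bp$bin_i) * res
  attr(bp, "resolution") <- res
  class(bp) <- c("bin_pairs", "data.frame")
  truth <- data.frame(
    chrom = rep(chrom, nrow(planted_loops)),
    start1 = planted_loops$bin_i * res, end1 = (planted_loops$bin_i + 1) * res,
    start2 = planted_loops$bin_j * res, end2 = (planted_loops$bin_j + 1) * res)
  cs <- stats::setNames(config$chrom_length, chrom)
  list(binpairs = bp, truth = truth, chrom_sizes = cs)
}

#' Simulate raw valid-pair records with a known QC composition
#'
#' Generates unique cis-long, cis-short and trans records in the requested
#' proportions of the total, then appends exact duplicate copies of
#' randomly chosen records to reach the duplicate fraction.
#'
#' @param n_pairs total records to emit.
#' @param frac_dup,frac_trans,frac_cis_short requested composition; the
#'   remainder is cis long-range. Must be >= 0 and sum to <= 1.
#' @param chrom_length chromosome length (bp).
#' @param cis_cutoff long/short boundary (bp, default 20000).
#' @param seed RNG seed.
#' @return data.frame of valid pairs (read_id, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2).
#' @export
sim_valid_pairs <- function(n_pairs, frac_dup = 0.15, frac_trans = 0.12,
                            frac_cis_short = 0.18, chrom_length = 2e6,
                            cis_cutoff = 20000, seed = 1) {
  fr <- c(frac_dup, frac_trans, frac_cis_short)
  stop_if(any(fr < 0), "fractions must be >= 0")
  stop_if(sum(fr) > 1, "duplicate + trans + cis-short fractions exceed 1")
  set.seed(seed)
  n_dup <- round(frac_dup * n_pairs)
  n_trans <- round(frac_trans * n_pairs)
  n_short <- round(frac_cis_short * n_pairs)
  n_long <- n_pairs - n_dup - n_trans - n_short
  stop_if(n_long < 0, "fractions leave no room for cis long-range pairs")

  strands <- function(k) sample(c("+", "-"), k, replace = TRUE)
  mk_cis <- function(k, min_sep, max_sep) {
    if (k == 0) return(NULL)
    p1 <- sample.int(chrom_length - max_sep - 1L, k, replace = TRUE)
    sep <- min_sep + sample.int(max_sep - min_sep, k, replace = TRUE)
    data.frame(chrom1 = "chr1", pos1 = p1, strand1 = strands(k),
               chrom2 = "chr1", pos2 = p1 + sep, strand2 = strands(k),
               stringsAsFactors = FALSE)
  }
  long <- mk_cis(n_long, cis_cutoff,
                 as.integer(max(chrom_length %/% 2, cis_cutoff + 2)))
  short <- mk_cis(n_short, 0L, cis_cutoff)
  trans <- if (n_trans > 0) {
    data.frame(chrom1 = "chr1",
               pos1 = sample.int(chrom_length, n_trans, replace = TRUE),
               strand1 = strands(n_trans),
               chrom2 = "chr2",
               pos2 = sample.int(chrom_length, n_trans, replace = TRUE),
               strand2 = strands(n_trans), stringsAsFactors = FALSE)
  } else NULL
  uni <- rbind(long, short, trans)
  # enforce tuple uniqueness (collisions are astronomically rare but would
  # silently shift the duplicate count)
  key <- do.call(paste, uni)
  while (anyDups <- anyDuplicated(key)) {
    d <- which(duplicated(key))
    uni$pos1[d] <- uni$pos1[d] + 1L
    key <- do.call(paste, uni)
  }
  uni <- uni[sample.int(nrow(uni)), , drop = FALSE]
  dups <- if (n_dup > 0) uni[sample.int(nrow(uni), n_dup, replace = FALSE), ,
                             drop = FALSE] else NULL
  out <- rbind(uni, dups)
  out <- cbind(read_id = sprintf("r%07d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a heritability-enrichment study panel
#'
#' Builds a genotype panel with LD blocks of varying strength (block-wise
#' copy probabilities, as real genomes mix strong and weak LD regions — and
#' as the LD-score regression needs to separate its intercept from the
#' polygenic term), a binary annotation marking a random category of SNPs,
#' and per-SNP heritabilities in which the category carries
#' \code{fold} times its SNP-share of the total heritability:
#' category SNPs get \code{fold * h2_total / m}; the remainder is spread
#' over the other SNPs, so the true enrichment statistic equals
#' \code{fold}.
#'
#' @param m,n SNP and individual counts (defaults 2000 each).
#' @param category_fraction fraction of SNPs in the annotated category.
#' @param fold planted heritability enrichment of the category.
#' @param h2_total total trait heritability.
#' @param n_ld_blocks LD blocks along the panel.
#' @param corr_range copy-probability range across blocks.
#' @param maf_range,spacing as in \code{\link{sim_config}}.
#' @param seed RNG seed.
#' @return list with \code{panel}, \code{annotations} (m x 2 matrix:
#'   base, category), \code{per_snp_h2}, \code{category_index}.
#' @export
sim_enrichment_study <- function(m = 2000, n = 2000,
                                 category_fraction = 0.1, fold = 5,
                                 h2_total = 0.5, n_ld_blocks = 40,
                                 corr_range = c(0.2, 0.95),
                                 maf_range = c(0.05, 0.5), spacing = 5000,
                                 seed = 1) {
  set.seed(seed)
  corr_block <- stats::runif(n_ld_blocks, corr_range[1], corr_range[2])
  block_of <- rep(seq_len(n_ld_blocks),
                  each = ceiling(m / n_ld_blocks))[seq_len(m)]
  corr <- corr_block[block_of]
  cfg <- sim_config(seed = seed, n_snps_per_locus = m, n_individuals = n,
                    maf_range = maf_range, snp_spacing = spacing)
  panel <- sim_panel(cfg, seed = seed + 1L, adjacent_corr = corr)
  m_c <- round(category_fraction * m)
  idx <- sort(sample.int(m, m_c))
  ann <- cbind(base = rep(1L, m),
               category = as.integer(seq_len(m) %in% idx))
  per <- rep((1 - fold * category_fraction) * h2_total / (m - m_c), m)
  stop_if(per[1] < 0, "fold x category_fraction exceeds 1")
  per[idx] <- fold * h2_total / m
  list(panel = panel, annotations = ann, per_snp_h2 = per,
       category_index = idx)
}

#' Simulate GWAS chi-square statistics with planted heritability structure
#'
#' Draws standardized per-SNP effects with the supplied per-SNP
#' heritabilities, builds a polygenic phenotype on the panel individuals,
#' and returns the marginal association chi-squares
#' \eqn{\chi^2_j = n \, r^2(x_j, y)} — the input to stratified LD-score
#' regression. Tagging through LD arises naturally from the panel.
#'
#' @param panel \code{genotype_panel}.
#' @param per_snp_h2 vector of per-SNP heritabilities (variance of the
#'   standardized effect), summing to the total h2 (< 1).
#' @param seed RNG seed.
#' @return list with \code{chisq} (length m) and \code{N} (sample size).
#' @export
sim_gwas_chisq <- function(panel, per_snp_h2, seed = 1) {
  X <- scale(panel$dosage)
  n <- nrow(X); m <- ncol(X)
  stop_if(length(per_snp_h2) != m, "per_snp_h2 must have one entry per SNP")
  h2 <- sum(per_snp_h2)
  stop_if(h2 >= 1, "total heritability must be < 1")
  set.seed(seed)
  beta <- stats::rnorm(m, 0, sqrt(per_snp_h2))
  y <- as.numeric(X %*% beta) + stats::rnorm(n, 0, sqrt(1 - h2))
  ys <- (y - mean(y)) / stats::sd(y)
  r <- as.numeric(crossprod(X, ys)) / n
  list(chisq = n * r^2, N = n)
}

#' Simulate a non-overlapping gene annotation
#'
#' Places \code{n_genes} disjoint gene bodies with random strands along the
#' chromosome, separated by random gaps, each with 1-4 exons tiling part of
#' the body. The TSS is the body start on '+' and the last base on '-'.
#'
#' @param config \code{sim_config}.
#' @param seed RNG seed (default \code{config$seed}).
#' @param chrom chromosome label.
#' @return \code{gene_annotation} object.
#' @export
sim_genome_annotation <- function(config, seed = config$seed, chrom = "chr1") {
  set.seed(seed)
  n <- config$n_genes
  spans <- round(stats::runif(n, config$gene_span_range[1],
                              config$gene_span_range[2]))
  slack <- config$chrom_length - sum(spans)
  stop_if(slack <= n, "infeasible packing: genes do not fit the chromosome")
  cuts <- sort(sample.int(slack - 1L, n))
  gaps <- diff(c(0L, cuts))  # n gaps before each gene; rest trails
  starts <- cumsum(gaps) + c(0, cumsum(spans))[seq_len(n)]
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n)),
    symbol = sprintf("GENE%03d", seq_len(n)),
    chrom = chrom,
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = starts,
    end = starts + spans,
    stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_len(n), function(idx) {
    k <- sample(1:4, 1)
    body <- c(genes$start[idx], genes$end[idx])
    if (k == 1) {
      data.frame(gene_id = genes$gene_id[idx], chrom = chrom,
                 start = body[1], end = body[2], stringsAsFactors = FALSE)
    } else {
      inner <- sort(sample((body[1] + 1):(body[2] - 1), 2 * k - 2))
      bounds <- c(body[1], inner, body[2])
      odd <- seq(1, length(bounds) - 1, by = 2)
      data.frame(gene_id = genes$gene_id[idx], chrom = chrom,
                 start = bounds[odd], end = bounds[odd + 1],
                 stringsAsFactors = FALSE)
    }
  }))
  gene_annotation(genes, exons)
}

#' Simulate accessibility peaks covering given positions
#'
#' Random fixed-width peaks plus one peak centered on each position that
#' must be covered (e.g. a planted causal variant), merged and sorted.
#'
#' @param chrom_length chromosome length (bp).
#' @param n_peaks random peak count.
#' @param peak_width width in bp.
#' @param cover 1-based positions that must fall inside a peak.
#' @param seed RNG seed.
#' @param chrom chromosome label.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}
#'   (half-open 0-based).
#' @export
sim_peaks <- function(chrom_length = 2e6, n_peaks = 50, peak_width = 500,
                      cover = integer(), seed = 1, chrom = "chr1") {
  set.seed(seed)
  centers <- sample.int(chrom_length, n_peaks)
  centers <- c(centers, cover)
  start <- pmax(centers - peak_width %/% 2, 0)
  end <- pmin(start + peak_width, chrom_length)
  gr <- GenomicRanges::reduce(granges0(rep(chrom, length(start)), start, end))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Simulate a tumor/normal expression matrix with planted shifts
#'
#' Log2 expression is normal around gene-specific baselines (log-normal on
#' the raw scale); a random \code{de_fraction} of genes is shifted by
#' \code{de_lfc} in the tumor group.
#'
#' @param annotation \code{gene_annotation} (gene ids become rownames).
#' @param config \code{sim_config}.
#' @param seed RNG seed (default \code{config$seed}).
#' @return list with \code{expr} (genes x samples log2 matrix),
#'   \code{labels} (factor normal/tumor) and \code{truth}
#'   (\code{de_gene_ids}).
#' @export
sim_expression <- function(annotation, config, seed = config$seed) {
  stop_if(config$n_tumor < 2 || config$n_normal < 2,
          "need at least 2 samples per group")
  set.seed(seed)
  ids <- annotation$genes$gene_id
  n_g <- length(ids)
  n_s <- config$n_tumor + config$n_normal
  base <- stats::runif(n_g, 3, 8)
  expr <- matrix(stats::rnorm(n_g * n_s, mean = base, sd = 1), n_g, n_s)
  labels <- factor(rep(c("normal", "tumor"),
                       c(config$n_normal, config$n_tumor)),
                   levels = c("normal", "tumor"))
  n_de <- round(config$de_fraction * n_g)
  de <- if (n_de > 0) sort(sample.int(n_g, n_de)) else integer()
  if (length(de) > 0) {
    expr[de, labels == "tumor"] <- expr[de, labels == "tumor"] + config$de_lfc
  }
  dimnames(expr) <- list(ids,
                         paste0(ifelse(labels == "tumor", "T", "N"),
                                seq_len(n_s)))
  list(expr = expr, labels = labels, truth = list(de_gene_ids = ids[de]))
}
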