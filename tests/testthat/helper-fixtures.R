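# Small constructed fixtures shared across test files.

# a hand-built annotation: two genes on chr1 ('+' and '-') and one on chr2
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("GA", "GB", "GC"),
    symbol = c("GENEA", "GENEB", "GENEC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(10000, 50000, 5000),
    end = c(30000, 70000, 9000),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = c("GA", "GA", "GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10000, 18000, 26000, 50000, 5000),
    end = c(12000, 20000, 30000, 70000, 9000),
    stringsAsFactors = FALSE
  )
  gene_annotation(genes, exons)
}

# build a loops table from anchor starts (one-bin anchors)
make_loops <- function(start1, start2, chrom = "chr1", resolution = 5000,
                       q = 1e-4, source = "cellA") {
  n <- length(start1)
  out <- data.frame(
    chrom1 = chrom, start1 = start1, end1 = start1 + resolution,
    chrom2 = chrom, start2 = start2, end2 = start2 + resolution,
    count = rep(20L, n), mu = rep(5, n),
    p_value = rep(q / 10, n), q_value = rep(q, n),
    distance = start2 - start1, source = rep(source, n),
    stringsAsFactors = FALSE
  )
  attr(out, "resolution") <- resolution
  class(out) <- c("loops", "data.frame")
  out
}

# bin-pair table straight from (i, j, count) triplets
make_binpairs <- function(bin_i, bin_j, count, chrom = "chr1",
                          resolution = 5000) {
  out <- data.frame(chrom = chrom, bin_i = bin_i, bin_j = bin_j,
                    count = as.integer(count), stringsAsFactors = FALSE)
  out$distance <- (out$bin_j - out$bin_i) * resolution
  attr(out, "resolution") <- resolution
  class(out) <- c("bin_pairs", "data.frame")
  out
}

# random loops for round-trip tests
random_loops <- function(n, seed = 1, resolution = 5000) {
  set.seed(seed)
  i <- sample.int(200, n, replace = TRUE)
  gap <- sample(4:100, n, replace = TRUE)
  q <- 10^-stats::runif(n, 1, 12)
  out <- data.frame(
    chrom1 = "chr1", start1 = i * resolution, end1 = (i + 1) * resolution,
    chrom2 = "chr1", start2 = (i + gap) * resolution,
    end2 = (i + gap + 1) * resolution,
    count = sample.int(100, n, replace = TRUE),
    mu = round(stats::runif(n, 0.1, 20), 6),
    p_value = q / 10, q_value = q, distance = gap * resolution,
    source = sample(c("cellA", "cellB", "cellA,cellB"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  attr(out, "resolution") <- resolution
  class(out) <- c("loops", "data.frame")
  out
}
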