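toy_pairs <- function() {
  # 10 records: 2 exact duplicates; unique split 4 cis-long / 2 cis-short /
  # 2 trans
  base <- data.frame(
    read_id = paste0("r", 1:8),
    chrom1 = c(rep("chr1", 6), "chr1", "chr1"),
    pos1 = c(1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000),
    strand1 = "+",
    chrom2 = c(rep("chr1", 6), "chr2", "chr2"),
    pos2 = c(31000, 42000, 53000, 64000, 15000, 16000, 9000, 9500),
    strand2 = "-",
    stringsAsFactors = FALSE
  )
  rbind(base, transform(base[1:2, ], read_id = c("r9", "r10")))
}

test_that("QC classifies the hand-counted toy set", {
  qc <- qc_valid_pairs(toy_pairs())
  expect_equal(qc$total_valid, 10L)
  expect_equal(qc$duplicates, 2L)
  expect_equal(qc$unique_valid, 8L)
  expect_equal(qc$cis_long, 4L)
  expect_equal(qc$cis_short, 2L)
  expect_equal(qc$trans, 2L)
  expect_equal(qc$pct_cis_long, 40)
  expect_equal(qc$pct_cis_short, 20)
  expect_equal(qc$pct_trans, 20)
  expect_equal(qc$pct_unique, 80)
  expect_error(qc_valid_pairs(toy_pairs()[0, ]), "non-empty")
})

test_that("QC percentages always partition the unique percentage", {
  for (s in 1:5) {
    vp <- sim_valid_pairs(2000, frac_dup = runif(1, 0, 0.3),
                          frac_trans = runif(1, 0, 0.3),
                          frac_cis_short = runif(1, 0, 0.3), seed = s)
    qc <- qc_valid_pairs(vp)
    expect_equal(qc$pct_cis_long + qc$pct_cis_short + qc$pct_trans,
                 qc$pct_unique, tolerance = 1e-12)
    expect_equal(qc$duplicates + qc$unique_valid, qc$total_valid)
  }
  # all-trans input has no cis signal
  vp <- sim_valid_pairs(500, frac_dup = 0, frac_trans = 1,
                        frac_cis_short = 0, seed = 2)
  qc <- qc_valid_pairs(vp)
  expect_equal(qc$pct_cis_long, 0)
  expect_equal(qc$pct_trans, 100)
})

test_that("binning follows the floor((pos-1)/res) convention", {
  p <- data.frame(read_id = c("a", "b", "c"), chrom1 = "chr1",
                  pos1 = c(1, 5000, 5001), strand1 = "+", chrom2 = "chr1",
                  pos2 = c(30000, 30000, 30000), strand2 = "-")
  bp <- bin_pairs(p, 5000)
  expect_equal(bp$bin_i, c(0L, 1L))  # positions 1 and 5000 share bin 0
  expect_equal(bp$count, c(2L, 1L))  # first two aggregate into (0, 5)
  # worked example: (12000, 33000) at 5 kb -> bins (2, 6), d = 20 kb
  p2 <- data.frame(read_id = "x", chrom1 = "chr1", pos1 = 12000,
                   strand1 = "+", chrom2 = "chr1", pos2 = 33000,
                   strand2 = "+")
  bp2 <- bin_pairs(p2, 5000)
  expect_equal(c(bp2$bin_i, bp2$bin_j, bp2$distance), c(2, 6, 20000))
  expect_error(bin_pairs(p2, 0), "positive")
})

test_that("decay model is flat for constant counts and tracks a power law", {
  cs <- c(chr1 = 1e6)
  # constant counts at every gap: isotonic fit must be flat
  cand <- candidate_bin_pairs(cs, 5000)
  bp <- make_binpairs(cand$bin_i, cand$bin_j, rep(3L, nrow(cand)))
  dm <- fit_distance_decay(bp, cs, n_distance_bins = 50)
  expect_lt(diff(range(dm$p)), 1e-12)

  # planted power law (exponent 1): fitted log-log slope within 0.15 of -1
  cfg <- sim_config(seed = 1, bias_sd = 0, n_planted_loops = 0,
                    loop_fold = 1)
  sc <- sim_contacts(cfg, seed = 1)
  dm <- fit_distance_decay(sc$binpairs, sc$chrom_sizes)
  fit <- stats::lm(log(dm$p) ~ log(dm$distance),
                   weights = dm$n_pairs, subset = dm$p > 0)
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.15)

  # queried probabilities never increase with distance
  d <- seq(20000, 990000, by = 1000)
  expect_true(all(diff(decay_prob(dm, d)) <= 1e-15))
})

test_that("all-zero counts give a flat model with a warning", {
  bp <- make_binpairs(c(0L, 1L), c(10L, 20L), c(0L, 0L))
  expect_warning(dm <- fit_distance_decay(bp, c(chr1 = 5e5),
                                          n_distance_bins = 10), "flat")
  expect_lt(diff(range(dm$p)), 1e-15)
})

test_that("coverage bias normalizes to mean 1 over covered bins", {
  cs <- c(chr1 = 20000)
  # uniform coverage: pairs (0,1) and (2,3), each count 1
  b <- estimate_bias(make_binpairs(c(0L, 2L), c(1L, 3L), c(1L, 1L)), cs)
  expect_equal(b$bias, rep(1, 4))
  # coverage {3,1,1,1}: bin 0 has double the mean coverage -> bias 2
  b <- estimate_bias(make_binpairs(c(0L, 0L, 0L), c(1L, 2L, 3L),
                                   c(1L, 1L, 1L)), cs)
  expect_equal(b$bias[b$bin == 0], 2)
  expect_equal(mean(b$bias[b$coverage > 0]), 1, tolerance = 1e-6)
})

test_that("loop p-values match the brute-force binomial tail", {
  # the worked point: N = 10000, pi = 1e-4, k = 10
  p_impl <- stats::pbinom(9, 10000, 1e-4, lower.tail = FALSE)
  p_orac <- oracle_binom_tail(10, 10000, 1e-4)
  expect_equal(p_impl, p_orac, tolerance = 1e-10)
  expect_lt(p_orac, 1e-6)
  expect_gt(p_orac, 1e-8)
})

test_that("called loops respect the distance filter and skip zero counts", {
  cfg <- sim_config(seed = 3)
  sc <- sim_contacts(cfg, seed = 3)
  dm <- fit_distance_decay(sc$binpairs, sc$chrom_sizes)
  bias <- estimate_bias(sc$binpairs, sc$chrom_sizes, decay = dm)
  loops <- call_loops(sc$binpairs, dm, bias, sc$chrom_sizes)
  expect_true(all(loops$distance >= 20000 & loops$distance <= 2e6))
  expect_true(all(loops$count > 0))
  expect_true(all(loops$q_value >= 0 & loops$q_value <= 1))
  expect_error(call_loops(sc$binpairs, dm, bias, sc$chrom_sizes, fdr = 0),
               "fdr")
})

test_that("merging loop sets is idempotent and unions sources", {
  a <- make_loops(c(0, 10000), c(100000, 200000), source = "cellA")
  b <- make_loops(c(10000, 50000), c(200000, 400000), source = "cellB")
  # self-merge changes nothing
  m <- merge_loops(list(a, a))
  expect_equal(nrow(m), 2L)
  expect_equal(sort(m$source), c("cellA", "cellA"))
  # one shared loop carries both labels; disjoint rest adds up
  m <- merge_loops(list(a, b))
  expect_equal(nrow(m), 3L)
  shared <- m[m$start1 == 10000, ]
  expect_equal(shared$source, "cellA,cellB")
  # mixed resolutions refuse to merge
  b2 <- b
  attr(b2, "resolution") <- 10000
  expect_error(merge_loops(list(a, b2)), "resolution")
})
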