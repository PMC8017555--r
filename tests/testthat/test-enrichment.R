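small_panel <- function(m = 20, n = 50, seed = 1, spacing = 1000) {
  cfg <- sim_config(seed = seed, n_snps_per_locus = m, n_individuals = n,
                    snp_spacing = spacing, adjacent_corr = 0.5)
  sim_panel(cfg, seed = seed)
}

test_that("LD scores: self term, duplicate columns, and oracle equality", {
  # isolated SNPs (window smaller than spacing): base score is the self
  # term, exactly 1 after the small-sample adjustment
  p <- small_panel(m = 5, n = 40, seed = 2, spacing = 10000)
  ld <- compute_ld_scores(p, cbind(base = rep(1, 5)), window_bp = 500)
  expect_equal(unname(ld[, "base"]), rep(1, 5), tolerance = 1e-12)

  # two perfectly correlated SNPs: each base score is 2
  G <- cbind(p$dosage[, 1], p$dosage[, 1], p$dosage[, 3])
  dup <- genotype_panel(G, pos = c(100, 200, 1000))
  ld2 <- compute_ld_scores(dup, cbind(base = rep(1, 3)), window_bp = 150)
  expect_equal(unname(ld2[1:2, "base"]), c(2, 2), tolerance = 1e-10)

  # random panels match the O(m^2) brute force to 1e-10
  for (s in 1:3) {
    p <- small_panel(m = 50, n = 60, seed = s)
    ann <- cbind(base = rep(1, 50),
                 cat = as.integer(seq_len(50) %% 3 == 0))
    impl <- compute_ld_scores(p, ann, window_bp = 20000)
    orac <- oracle_ld_scores(p$dosage, p$pos, ann, 20000)
    expect_equal(unname(impl[, ]), unname(orac), tolerance = 1e-10)
  }
  expect_error(compute_ld_scores(small_panel(n = 3, m = 5),
                                 cbind(base = rep(1, 5))), "individuals")
  expect_error(compute_ld_scores(small_panel(), cbind(cat = rep(0, 20))),
               "base category")
})

test_that("SLDSC has an exact null fixed point and unit base enrichment", {
  p <- small_panel(m = 100, n = 60, seed = 4)
  ann <- cbind(base = rep(1L, 100),
               cat = as.integer(seq_len(100) <= 30))
  ld <- compute_ld_scores(p, ann, window_bp = 10000)
  # all chi-square exactly 1: zero heritability, intercept 1
  f0 <- fit_sldsc(rep(1, 100), ld, ann, N = 5000)
  expect_equal(max(abs(f0$tau)), 0, tolerance = 1e-10)
  expect_equal(f0$intercept, 1, tolerance = 1e-10)

  # base-only model: enrichment is identically 1
  g <- sim_gwas_chisq(p, rep(0.3 / 100, 100), seed = 1)
  f1 <- fit_sldsc(g$chisq, ld[, "base", drop = FALSE],
                  ann[, "base", drop = FALSE], N = g$N)
  expect_equal(unname(f1$enrichment["base"]), 1)

  # collinear categories are refused by name
  ann_bad <- cbind(ann, cat2 = ann[, "cat"])
  ld_bad <- compute_ld_scores(p, ann_bad, window_bp = 10000)
  expect_error(fit_sldsc(g$chisq, ld_bad, ann_bad, N = g$N), "cat2")
})

test_that("ssGSEA matches the worked example and is rank-invariant", {
  v <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  # unweighted running sum: 0.5 + 1 + 0.5 + 0 = 2
  expect_equal(ssgsea(v, c("g1", "g2"), alpha = 0), 2)
  # invariance under doubling and under any increasing transform
  es <- ssgsea(v, c("g1", "g3"))
  expect_equal(ssgsea(v * 2, c("g1", "g3")), es)
  expect_equal(ssgsea(exp(v), c("g1", "g3")), es)
  expect_error(ssgsea(v, character(0)), "empty")
  expect_error(ssgsea(v, names(v)), "full gene universe")
  expect_error(ssgsea(v, "nope"), "absent")
})

test_that("ssGSEA equals the quadratic-time oracle on random fixtures", {
  set.seed(21)
  for (r in 1:25) {
    n <- 30
    v <- stats::setNames(rnorm(n), paste0("g", 1:n))
    gs <- sample(names(v), sample(2:10, 1))
    a <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea(v, gs, alpha = a), oracle_ssgsea(v, gs, a),
                 tolerance = 1e-10)
  }
})

test_that("ssGSEA scores separate tumor from normal on planted shifts", {
  cfg <- sim_config(seed = 10, n_genes = 150, de_fraction = 0.2,
                    de_lfc = 2, chrom_length = 3e6)
  ann <- sim_genome_annotation(cfg, seed = 10)
  ex <- sim_expression(ann, cfg, seed = 10)
  es <- ssgsea_scores(ex$expr, ex$truth$de_gene_ids)
  tt <- stats::t.test(es[ex$labels == "tumor"], es[ex$labels == "normal"],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("Welch DE handles nulls, shifts and degenerate genes", {
  # identical group means and variances: t = 0
  x <- matrix(rep(c(1, 2, 1, 2), 5), nrow = 5, byrow = TRUE)
  de <- diff_expression(x, c("a", "a", "b", "b"))
  expect_equal(de$t, rep(0, 5))
  # zero variance in both groups flags the gene
  expect_warning(
    de3 <- diff_expression(matrix(rep(1, 8), 2), rep(c("a", "b"), each = 2)),
    "zero variance")
  expect_true(all(de3$undefined))

  # planted 2-lfc shift at n = 20/20 is recovered
  set.seed(2)
  hits <- vapply(1:20, function(r) {
    m <- matrix(rnorm(100 * 40), 100)
    m[1, 21:40] <- m[1, 21:40] + 2
    de <- diff_expression(m, rep(c("n", "t"), each = 20))
    de$significant[1]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment equals the step-up oracle", {
  set.seed(31)
  for (r in 1:100) {
    p <- runif(sample(5:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})
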