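test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(maf_range = c(0.3, 0.1)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(adjacent_corr = 1), "adjacent_corr")
  expect_error(sim_config(loop_fold = 0.5), "loop_fold")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
})

test_that("panels are deterministic and match the target LD", {
  cfg <- sim_config(seed = 1, n_snps_per_locus = 1000, n_individuals = 300,
                    adjacent_corr = 0)
  p1 <- sim_panel(cfg, seed = 1)
  p2 <- sim_panel(cfg, seed = 1)
  expect_identical(p1$dosage, p2$dosage)
  expect_true(all(p1$dosage %in% 0:2))

  # no copying: neighbors essentially uncorrelated
  adj <- vapply(seq_len(999), function(j)
    stats::cor(p1$dosage[, j], p1$dosage[, j + 1]), 0)
  expect_lt(mean(abs(adj)), 0.1)

  # moderate copying: mean neighbor correlation near the target
  cfg6 <- sim_config(seed = 1, n_snps_per_locus = 300, n_individuals = 400,
                     adjacent_corr = 0.6)
  p6 <- sim_panel(cfg6, seed = 2)
  adj6 <- vapply(seq_len(299), function(j)
    stats::cor(p6$dosage[, j], p6$dosage[, j + 1]), 0)
  expect_lt(abs(mean(adj6) - 0.6), 0.15)

  # single-SNP edge case keeps MAF inside the configured range
  cfg1 <- sim_config(seed = 1, n_snps_per_locus = 1, n_individuals = 500,
                     maf_range = c(0.2, 0.4))
  pp <- sim_panel(cfg1, seed = 3)
  expect_equal(ncol(pp$dosage), 1L)
  expect_true(pp$maf >= 0.1 && pp$maf <= 0.5)
})

test_that("null GWAS z-statistics are calibrated", {
  cfg <- sim_config(seed = 1, n_snps_per_locus = 1000, n_individuals = 400,
                    adjacent_corr = 0)
  panel <- sim_panel(cfg, seed = 1)
  gw <- sim_gwas_locus(panel, panel$variant_id[1], effect = 0, seed = 1)
  z <- gw$records$beta / gw$records$se
  expect_true(all(gw$records$se > 0))
  frac <- mean(abs(z) > 1.96)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("a strong causal signal attains the top ABF in nearly all reps", {
  cfg <- sim_config(seed = 1, n_snps_per_locus = 100, n_individuals = 2000,
                    adjacent_corr = 0.6)
  panel <- sim_panel(cfg, seed = 5)
  ci <- 50L
  effect <- 8 / sqrt(2000 * stats::var(panel$dosage[, ci]))  # |z| ~ 8
  top <- vapply(1:200, function(r) {
    gw <- sim_gwas_locus(panel, panel$variant_id[ci], effect, seed = r)
    abf <- compute_abf(gw$records$beta, gw$records$se)
    which.max(abf) == ci
  }, TRUE)
  expect_gte(mean(top), 0.95)
  expect_error(sim_gwas_locus(panel, "not_a_snp", 0.1), "not in the panel")
})

test_that("contact counts decay with distance and honor depth and bias", {
  cfg <- sim_config(seed = 1, loop_fold = 1, n_planted_loops = 0,
                    bias_sd = 0)
  sc <- sim_contacts(cfg, seed = 1)
  expect_true(all(sc$binpairs$count >= 1))
  # mean count per pair decreases over distance deciles
  cand <- candidate_bin_pairs(sc$chrom_sizes, 5000, d_min = 5000,
                              d_max = 995000)
  cand$count <- 0L
  m <- match(paste(sc$binpairs$bin_i, sc$binpairs$bin_j),
             paste(cand$bin_i, cand$bin_j))
  cand$count[m[!is.na(m)]] <- sc$binpairs$count[!is.na(m)]
  dec <- cut(cand$distance, quantile(cand$distance, 0:10 / 10),
             include.lowest = TRUE)
  mean_by_decile <- tapply(cand$count, dec, mean)
  expect_true(all(diff(mean_by_decile) < 0))

  # bias_sd = 0: per-bin coverage close to uniform
  bias <- estimate_bias(sc$binpairs, sc$chrom_sizes)
  cv <- stats::sd(bias$coverage) / mean(bias$coverage)
  expect_lt(cv, 0.2)

  # zero depth gives zero counts
  sc0 <- sim_contacts(sim_config(seed = 1, sequencing_depth = 0,
                                 n_planted_loops = 0), seed = 1)
  expect_equal(nrow(sc0$binpairs), 0L)
})

test_that("planted loops respect the distance bounds and appear in truth", {
  cfg <- sim_config(seed = 4)
  sc <- sim_contacts(cfg, seed = 4)
  sep <- sc$truth$start2 - sc$truth$start1
  expect_true(all(sep >= 20000 & sep <= 2e6))
  expect_error(
    sim_contacts(cfg, seed = 1,
                 planted_loops = data.frame(bin_i = 0L, bin_j = 10000L)),
    "chromosome end")
  expect_error(
    sim_contacts(cfg, seed = 1,
                 planted_loops = data.frame(bin_i = 0L, bin_j = 1L)),
    "range")
})

test_that("valid-pair composition is recovered by QC", {
  vp <- sim_valid_pairs(10000, frac_dup = 0.2, frac_trans = 0.1,
                        frac_cis_short = 0.2, seed = 1)
  qc <- qc_valid_pairs(vp)
  expect_lt(abs(qc$pct_duplicates / 100 - 0.2), 0.02)
  expect_lt(abs(qc$pct_trans / 100 - 0.1), 0.02)
  expect_lt(abs(qc$pct_cis_short / 100 - 0.2), 0.02)
  # no duplicates at all
  vp0 <- sim_valid_pairs(1000, frac_dup = 0, seed = 2)
  expect_equal(qc_valid_pairs(vp0)$pct_unique, 100)
  expect_error(sim_valid_pairs(100, frac_dup = -0.1), ">= 0")
  expect_error(sim_valid_pairs(100, frac_dup = 0.6, frac_trans = 0.5),
               "exceed")
})

test_that("simulated genes are disjoint with strand-consistent TSS", {
  cfg <- sim_config(seed = 9)
  ann <- sim_genome_annotation(cfg, seed = 9)
  g <- ann$genes[order(ann$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  minus <- g[g$strand == "-", ]
  expect_equal(minus$tss, minus$end - 1)
  plus <- g[g$strand == "+", ]
  expect_equal(plus$tss, plus$start)
  # every gene has at least one exon inside its body
  expect_true(all(g$gene_id %in% ann$exons$gene_id))
  expect_error(sim_genome_annotation(
    sim_config(seed = 1, n_genes = 500, chrom_length = 1e5)), "packing")
})

test_that("expression matrices have the right shape and planted signal", {
  cfg <- sim_config(seed = 2, n_genes = 200, de_fraction = 0.2, de_lfc = 2)
  ann <- sim_genome_annotation(sim_config(seed = 2, n_genes = 200,
                                          chrom_length = 5e6), seed = 2)
  ex <- sim_expression(ann, cfg, seed = 2)
  expect_equal(dim(ex$expr), c(200L, 40L))
  de <- diff_expression(ex$expr, ex$labels)
  found <- de$gene_id[de$significant]
  expect_gte(mean(ex$truth$de_gene_ids %in% found), 0.9)

  # null: about 5% of genes nominally significant
  ex0 <- sim_expression(ann, sim_config(seed = 3, n_genes = 200,
                                        de_lfc = 0), seed = 3)
  de0 <- diff_expression(ex0$expr, ex0$labels)
  expect_lt(mean(de0$p_value < 0.05, na.rm = TRUE), 0.1)
  expect_error(sim_expression(ann, sim_config(seed = 1, n_tumor = 1)),
               "2 samples")
})

test_that("the assembled study carries complete, consistent truth", {
  st <- sim_study(sim_config(seed = 6))
  expect_true(st$truth$causal_variant_per_locus %in% st$gwas$variant_id)
  sep <- st$truth$planted_loop_coords$start2 -
    st$truth$planted_loop_coords$start1
  expect_true(all(sep >= 20000 & sep <= 2e6))
  expect_true(all(st$truth$de_gene_ids %in% st$annotation$genes$gene_id))
  # causal variant really sits inside one planted anchor
  cp <- st$truth$causal_pos - 1
  tl <- st$truth$planted_loop_coords
  expect_true(any((tl$start1 <= cp & cp < tl$end1) |
                    (tl$start2 <= cp & cp < tl$end2)))
})
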