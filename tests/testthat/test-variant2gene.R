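# annotation with one gene whose TSS is 302000, promoter window
# [299500, 304500)
v2g_ann <- function() {
  gene_annotation(
    data.frame(gene_id = "GENE1", symbol = "GENE1", chrom = "chr1",
               strand = "+", start = 302000, end = 330000,
               stringsAsFactors = FALSE),
    data.frame(gene_id = "GENE1", chrom = "chr1", start = 302000,
               end = 330000, stringsAsFactors = FALSE))
}

test_that("a CV in one anchor links to genes at the other, with TSS distance", {
  loops <- make_loops(100000, 300000)  # anchors [1e5,105e3) and [3e5,305e3)
  cvs <- data.frame(variant_id = "rs1", chrom = "chr1", pos = 102500,
                    locus_id = "L1", pp = 0.5)
  links <- map_cvs_to_targets(cvs, loops, v2g_ann())
  expect_equal(nrow(links), 1L)
  expect_equal(links$gene_id, "GENE1")
  expect_equal(links$distance, 199500)

  # orientation symmetry: CV in anchor2 maps to genes at anchor1
  ann2 <- gene_annotation(
    data.frame(gene_id = "GENE2", symbol = "GENE2", chrom = "chr1",
               strand = "+", start = 101000, end = 120000,
               stringsAsFactors = FALSE),
    data.frame(gene_id = "GENE2", chrom = "chr1", start = 101000,
               end = 120000, stringsAsFactors = FALSE))
  cvs2 <- data.frame(variant_id = "rs2", chrom = "chr1", pos = 301000,
                     locus_id = "L1", pp = 0.5)
  links2 <- map_cvs_to_targets(cvs2, loops, ann2)
  expect_equal(links2$gene_id, "GENE2")
  expect_equal(links2$distance, abs(301000 - 101000))

  # CV outside any anchor yields nothing
  cvs3 <- data.frame(variant_id = "rs3", chrom = "chr1", pos = 550000,
                     locus_id = "L1", pp = 0.5)
  expect_equal(nrow(map_cvs_to_targets(cvs3, loops, v2g_ann())), 0L)
})

test_that("links deduplicate on variant-gene-loop", {
  loops <- make_loops(c(100000, 100000), c(300000, 300000),
                      source = c("cellA", "cellB"))
  # bin-identical loops from two cell lines produce one link each (distinct
  # loop ids collapse after merging)
  merged <- merge_loops(list(loops[1, ], loops[2, ]))
  cvs <- data.frame(variant_id = "rs1", chrom = "chr1", pos = 102500,
                    locus_id = "L1", pp = 1)
  links <- map_cvs_to_targets(cvs, merged, v2g_ann())
  expect_equal(nrow(links), 1L)
  expect_equal(links$source, "cellA,cellB")
})

test_that("open-chromatin filtering intersects peak sets", {
  peaks_a <- data.frame(chrom = "chr1", start = c(100, 5000),
                        end = c(300, 5600))
  peaks_b <- data.frame(chrom = "chr1", start = 150, end = 250)
  x <- data.frame(variant_id = c("v1", "v2"), chrom = "chr1",
                  pos = c(200, 5100))
  both <- filter_by_open_chromatin(x, list(peaks_a, peaks_b))
  expect_equal(both$variant_id, "v1")        # v2 only covered in set A
  any_set <- filter_by_open_chromatin(x, list(peaks_a, peaks_b),
                                      require_all = FALSE)
  expect_equal(any_set$variant_id, c("v1", "v2"))
  # a covering single set keeps everything
  ident <- filter_by_open_chromatin(
    x, list(data.frame(chrom = "chr1", start = 0, end = 10000)),
    require_all = FALSE)
  expect_equal(ident, x)
  expect_warning(out <- filter_by_open_chromatin(
    x, list(peaks_a[0, ])), "empty peak set")
  expect_equal(nrow(out), 0L)
})

test_that("peak filtering is contractive and monotone in peaks", {
  set.seed(5)
  for (r in 1:10) {
    x <- data.frame(variant_id = paste0("v", 1:50), chrom = "chr1",
                    pos = sample.int(100000, 50))
    p1 <- data.frame(chrom = "chr1",
                     start = sort(sample.int(100000, 20)))
    p1$end <- p1$start + 500
    extra <- data.frame(chrom = "chr1",
                        start = sort(sample.int(100000, 10)))
    extra$end <- extra$start + 500
    f1 <- filter_by_open_chromatin(x, list(p1))
    f2 <- filter_by_open_chromatin(x, list(rbind(p1, extra)))
    expect_true(all(f1$variant_id %in% x$variant_id))
    # adding peaks never removes variants
    expect_true(all(f1$variant_id %in% f2$variant_id))
  }
})

test_that("proximal assignment prefers the containing body, then nearest TSS", {
  ann <- gene_annotation(
    data.frame(gene_id = c("L", "R"), symbol = c("L", "R"), chrom = "chr1",
               strand = "+", start = c(1000, 9000), end = c(3000, 12000),
               stringsAsFactors = FALSE),
    data.frame(gene_id = c("L", "R"), chrom = "chr1",
               start = c(1000, 9000), end = c(3000, 12000),
               stringsAsFactors = FALSE))
  inside <- proximal_targets(
    data.frame(variant_id = "v", chrom = "chr1", pos = 2000), ann)
  expect_equal(inside$gene_id, "L")
  expect_equal(inside$distance, 0)
  # equidistant between TSS 1000 and TSS 9000: pos 5000 -> smaller
  # coordinate wins
  tie <- proximal_targets(
    data.frame(variant_id = "v", chrom = "chr1", pos = 5000), ann)
  expect_equal(tie$gene_id, "L")
  # gene-free chromosome stays unassigned
  expect_message(off <- proximal_targets(
    data.frame(variant_id = "v", chrom = "chr9", pos = 100), ann),
    "unassigned")
  expect_true(is.na(off$gene_id))
})

test_that("target-set comparison does exact set algebra", {
  cmp <- compare_target_sets(c("A", "B", "C"), "B", c("B", "C"))
  expect_equal(cmp$overlap_hichip_eqtl, 1L)
  expect_equal(cmp$overlap_hichip_proximal, 2L)
  expect_equal(cmp$triple_overlap, 1L)
  expect_equal(cmp$fold_vs_eqtl, 3.0)
  expect_equal(cmp$fold_vs_proximal, 1.5)
  same <- compare_target_sets(c("a", "b"), c("A", "B"), c("a", "B"))
  expect_equal(same$triple_overlap, 2L)      # case-normalized
  expect_equal(same$fold_vs_eqtl, 1.0)
  disj <- compare_target_sets("A", "B", "C")
  expect_equal(disj$triple_overlap, 0L)
  empty <- compare_target_sets(character(0), "B", "C")
  expect_true(is.na(empty$fold_vs_eqtl))
})

test_that("set comparison satisfies inclusion-exclusion on random sets", {
  set.seed(13)
  for (r in 1:20) {
    u <- paste0("g", 1:30)
    h <- sample(u, sample.int(20, 1))
    e <- sample(u, sample.int(20, 1))
    p <- sample(u, sample.int(20, 1))
    cmp <- compare_target_sets(h, e, p)
    expect_equal(length(union(toupper(h), toupper(e))),
                 cmp$n_hichip + cmp$n_eqtl - cmp$overlap_hichip_eqtl)
    expect_lte(cmp$triple_overlap,
               min(cmp$overlap_hichip_eqtl, cmp$overlap_hichip_proximal,
                   cmp$overlap_eqtl_proximal))
  }
})

test_that("locus summaries count distinct CVs and genes", {
  links <- data.frame(
    variant_id = c("v1", "v1", "v2", "v3", "v3"),
    locus_id = c("L1", "L1", "L1", "L2", "L2"),
    gene_id = c("GA", "GB", "GA", "GA", "GC"),
    source = "cellA",
    distance = c(10, 20, 30, 40, 50))
  s <- summarize_loci(links)
  expect_equal(s$per_locus$cv_count, c(2L, 1L))
  expect_equal(s$total_cvs, 3L)
  # GA appears in both loci but counts once in the grand total
  expect_equal(s$total_genes, 3L)
  expect_equal(s$per_locus$genes, c("GA,GB", "GA,GC"))
  expect_equal(s$distance_by_source$median_bp, 30)
  empty <- summarize_loci(links[0, ])
  expect_equal(empty$total_cvs, 0L)
  expect_equal(nrow(empty$per_locus), 0L)
})
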