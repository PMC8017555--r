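#' Simulate a complete synthetic study
#'
#' Generates every input of the pipeline with coherent planted truth: a
#' gene annotation; planted loops whose gene-side anchor contains a
#' promoter; a GWAS locus whose causal variant sits inside the distal
#' anchor of the first planted loop; contact counts carrying those loops;
#' two accessibility peak sets covering the causal variant; and a
#' tumor/normal expression matrix with shifted genes. The truth record
#' names the causal variant, the planted loop coordinates, the expected
#' variant-target gene pair, and the shifted genes.
#'
#' @param config \code{sim_config}.
#' @param seed master RNG seed (default \code{config$seed}); component
#'   seeds are derived deterministically from it.
#' @return list with \code{annotation}, \code{gwas} (association records),
#'   \code{binpairs}, \code{chrom_sizes}, \code{peaks} (list of two peak
#'   tables), \code{expression}, \code{config}, and \code{truth}.
#' @export
sim_study <- function(config = sim_config(), seed = config$seed) {
  res <- config$bin_resolution
  n_bins <- as.integer(ceiling(config$chrom_length / res))
  g_min <- as.integer(ceiling(20000 / res))
  g_max <- min(n_bins - 1L, as.integer(floor(2e6 / res)))

  annotation <- sim_genome_annotation(config, seed = seed + 1L)
  genes <- annotation$genes

  # plant loops anchored at gene TSS bins, distal partner within range
  set.seed(seed + 2L)
  n_pl <- max(config$n_planted_loops, 1L)
  pick <- sample(seq_len(nrow(genes)), n_pl, replace = n_pl > nrow(genes))
  tss_bin <- as.integer(genes$tss[pick] %/% res)
  pick1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length 1
  distal_bin <- vapply(tss_bin, function(tb) {
    hi <- max(tb, n_bins - 1L - tb)  # largest feasible gap for this gene
    # log-uniform separation, as for randomly planted loops
    gap <- min(round(exp(stats::runif(1, log(g_min),
                                      log(min(g_max, hi))))),
               min(g_max, hi))
    gap <- as.integer(max(gap, g_min))
    sides <- c(-1L, 1L)[c(tb - gap >= 0, tb + gap <= n_bins - 1L)]
    tb + pick1(sides) * gap
  }, 0L)
  planted <- data.frame(bin_i = pmin(tss_bin, distal_bin),
                        bin_j = pmax(tss_bin, distal_bin))
  planted <- planted[!duplicated(planted), , drop = FALSE]

  # GWAS panel centered on the distal anchor of the first planted loop
  anchor_start <- distal_bin[1] * res
  m <- config$n_snps_per_locus
  span <- (m - 1L) * config$snp_spacing
  first_pos <- max(1, anchor_start + res %/% 2 - span %/% 2)
  panel <- sim_panel(config, seed = seed + 3L, pos_offset = first_pos)
  in_anchor <- which(panel$pos - 1 >= anchor_start &
                       panel$pos - 1 < anchor_start + res)
  stop_if(length(in_anchor) == 0L,
          "no panel SNP falls inside the planted loop anchor; widen the panel")
  mid <- anchor_start + res / 2
  causal_idx <- in_anchor[which.min(abs(panel$pos[in_anchor] - mid))]
  causal_id <- panel$variant_id[causal_idx]
  gwas <- sim_gwas_locus(panel, causal_id, config$causal_effect,
                         seed = seed + 4L, locus_id = "locus1",
                         chrom = "chr1")

  contacts <- sim_contacts(config, seed = seed + 5L,
                           planted_loops = planted)
  peaks <- list(
    cellA = sim_peaks(config$chrom_length, cover = panel$pos[causal_idx],
                      seed = seed + 6L),
    cellB = sim_peaks(config$chrom_length, cover = panel$pos[causal_idx],
                      seed = seed + 7L)
  )
  expression <- sim_expression(annotation, config, seed = seed + 8L)

  target_gene <- genes$gene_id[pick[1]]
  list(
    annotation = annotation,
    panel = panel,
    gwas = gwas$records,
    binpairs = contacts$binpairs,
    chrom_sizes = contacts$chrom_sizes,
    peaks = peaks,
    expression = expression,
    config = config,
    truth = list(
      causal_variant_per_locus = stats::setNames(causal_id, "locus1"),
      causal_pos = panel$pos[causal_idx],
      planted_loop_coords = contacts$truth,
      expected_link = c(variant_id = causal_id, gene_id = target_gene),
      de_gene_ids = expression$truth$de_gene_ids
    )
  )
}

#' Write a synthetic study to a directory of standard-format files
#'
#' Emits every pipeline input: summary stats TSV, allValidPairs-style
#' contact records are not regenerated (binned counts are written as a
#' bins BED plus sparse triplet matrix), GTF annotation, BED peak files,
#' expression TSV with labels, and a truth JSON.
#'
#' @param study output of \code{\link{sim_study}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    sumstats = file.path(dir, "sumstats.tsv"),
    bins = file.path(dir, "bins.bed"),
    matrix = file.path(dir, "matrix.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    peaks_a = file.path(dir, "peaks_cellA.bed"),
    peaks_b = file.path(dir, "peaks_cellB.bed"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_sumstats(study$gwas, paths["sumstats"])
  write_contact_matrix(study$binpairs, study$chrom_sizes,
                       paths["bins"], paths["matrix"])
  write_gtf(study$annotation, paths["gtf"])
  write_peaks(study$peaks[[1]], paths["peaks_a"])
  write_peaks(study$peaks[[2]], paths["peaks_b"])
  write_expression(study$expression$expr, study$expression$labels,
                   paths["expression"], paths["labels"])
  truth <- study$truth
  truth$causal_variant_per_locus <- as.list(truth$causal_variant_per_locus)
  truth$expected_link <- as.list(truth$expected_link)
  truth$planted_loop_coords <- as.list(truth$planted_loop_coords)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Empirical coverage of credible sets on simulated loci
#'
#' Simulates independent single-causal GWAS loci (LD-structured panel, one
#' causal SNP with effect sized for a target marginal |z|), fine-maps each
#' locus, and reports the fraction of replicates whose credible set
#' contains the causal variant — the calibration check for the credible
#' level.
#'
#' @param n_loci number of simulated loci.
#' @param config \code{sim_config} describing the panel and sample size.
#' @param target_z expected |z| of the causal variant (default 6).
#' @param level credible level (default 0.99).
#' @param W fine-mapping prior variance (default 0.04).
#' @param seed master seed; per-locus seeds are derived from it.
#' @return list with \code{coverage} (fraction in [0, 1]), \code{n_loci},
#'   and \code{set_sizes} (credible-set cardinalities).
#' @export
estimate_credible_coverage <- function(n_loci, config = sim_config(),
                                       target_z = 6, level = 0.99,
                                       W = 0.04, seed = 1) {
  hit <- logical(n_loci)
  sizes <- integer(n_loci)
  for (i in seq_len(n_loci)) {
    panel <- sim_panel(config, seed = seed + 2L * i)
    set.seed(seed + 2L * i + 1L)
    ci <- sample.int(length(panel$variant_id), 1L)
    causal <- panel$variant_id[ci]
    effect <- target_z / sqrt(config$n_individuals *
                                stats::var(panel$dosage[, ci]))
    gw <- sim_gwas_locus(panel, causal, effect, seed = seed + 2L * i + 1L)
    cs <- fine_map_locus(gw$records, W = W, level = level)
    members <- cs$table$variant_id[cs$table$in_credible_set]
    hit[i] <- causal %in% members
    sizes[i] <- length(members)
  }
  list(coverage = mean(hit), n_loci = n_loci, set_sizes = sizes)
}

#' Run the variant-to-gene pipeline on in-memory study inputs
#'
#' Convenience wrapper chaining decay fitting, bias estimation, loop
#' calling, fine-mapping and variant-to-gene mapping at the package
#' defaults — the path exercised by the end-to-end recovery tests.
#'
#' @param study output of \code{\link{sim_study}}.
#' @param fdr loop-calling FDR (default 0.01).
#' @param level credible level (default 0.99).
#' @param W fine-mapping prior variance (default 0.04).
#' @param mode gene-at-anchor mode (default "promoter").
#' @return list with \code{loops}, \code{credible_set}, \code{cvs},
#'   \code{links}.
#' @export
run_pipeline <- function(study, fdr = 0.01, level = 0.99, W = 0.04,
                         mode = "promoter") {
  decay <- fit_distance_decay(study$binpairs, study$chrom_sizes)
  bias <- estimate_bias(study$binpairs, study$chrom_sizes, decay = decay)
  loops <- call_loops(study$binpairs, decay, bias, study$chrom_sizes,
                      fdr = fdr)
  cs <- fine_map_locus(study$gwas, W = W, level = level)
  cvs <- credible_variants(cs)
  links <- map_cvs_to_targets(cvs, loops, study$annotation, mode = mode)
  list(loops = loops, credible_set = cs, cvs = cvs, links = links)
}
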