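#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates a complete synthetic study at the package defaults: one 1 Mb
# chromosome of 5 kb bins with a million cis contacts and ten planted
# loops, a 100-SNP GWAS locus whose causal variant sits in a planted loop
# anchor, forty genes, two accessibility peak sets covering the causal
# variant, and a 20 vs 20 tumor/normal expression matrix. Everything is
# written to results/sim/ in the pipeline's standard text formats, with
# the planted truth as JSON.

suppressMessages(library(hichipTargets))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
cfg <- sim_config(seed = seed)
study <- sim_study(cfg)

paths <- write_study_files(study, "results/sim")

# raw valid pairs for the QC stage (stage 3 classifies them)
vp <- sim_valid_pairs(50000, frac_dup = 0.16, frac_trans = 0.11,
                      frac_cis_short = 0.18,
                      chrom_length = cfg$chrom_length, seed = seed)
write_valid_pairs(vp, "results/sim/valid_pairs.txt")

jsonlite::write_json(provenance_block(cfg[names(cfg) != "seed"], seed),
                     "results/sim/provenance.json", auto_unbox = TRUE)

cat(sprintf("wrote %d files to results/sim (seed %d)\n",
            length(paths) + 1L, seed))
cat(sprintf("planted: %d loops, causal variant %s -> target gene %s\n",
            nrow(study$truth$planted_loop_coords),
            study$truth$expected_link[["variant_id"]],
            study$truth$expected_link[["gene_id"]]))
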