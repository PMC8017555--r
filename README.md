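# hichipTargets

Nominating target genes for GWAS risk loci by intersecting Bayesian
credible variant sets with significant H3K27ac-HiChIP chromatin loops.

Most disease-associated variants are non-coding and act on distal genes
through chromatin looping, so the nearest gene is often the wrong target.
This package implements, as a tested R pipeline over fully synthetic
inputs, the analysis chain used in epithelial-ovarian-cancer regulatory
genomics:

- **Fine-mapping** — per-variant approximate Bayes factors
  `ABF = sqrt(V/(V+W)) * exp(z^2 W / (2(V+W)))` (V = se², prior variance
  W = 0.04) and 99% credible sets under the single-causal-variant model.
- **Loop calling** — HiC-Pro-style valid-pair QC, 5 kb binning,
  equal-occupancy isotonic distance decay, coverage bias, and a
  bias-corrected binomial test `P(X >= k | N, π_ij)` with
  `π_ij ∝ p(d_ij) b_i b_j`, BH-controlled at FDR 0.01 over all candidate
  bin pairs in 20 kb–2 Mb.
- **Annotation & mapping** — strand-aware ±2.5 kb promoter windows,
  precedence-based anchor categories, and variant→gene links whenever a
  credible variant occupies one anchor of a loop whose other anchor holds
  a promoter; open-chromatin filtering, proximal-gene baselines, and
  per-locus summaries.
- **Enrichment** — a stratified LD-score-regression core
  (`enrichment_C = (h²_C/h²)/(M_C/M)` with block-jackknife SEs) and the
  ssGSEA per-sample statistic with a Welch/BH differential-expression
  stage.
- **Synthetic data** — generators for LD-structured genotype panels,
  GWAS summary statistics, power-law contact matrices with planted
  loops, gene annotations, peak sets and tumor/normal expression, each
  with a planted-truth record for parameter-recovery testing.

## Worked example

The `analysis/` scripts run the whole study in order; each stage reads
the previous stage's outputs from `results/`:

```sh
Rscript analysis/01_simulate_study.R   # inputs + planted truth
Rscript analysis/02_finemap.R          # credible sets
Rscript analysis/03_call_loops.R       # QC + significant loops
Rscript analysis/04_annotate_loops.R   # anchor/loop categories
Rscript analysis/05_map_targets.R      # variant -> gene links
Rscript analysis/06_enrichment.R       # SLDSC + ssGSEA/DE
```

At the default seed this prints, among other things:

```
Valid pairs: 50000 (unique 84.0%, duplicates 16.0%)
  cis long-range (>20000 bp): 55.0%
  cis short-range: 18.0%
  trans: 11.0%
11 significant loops (FDR 0.01), median distance 75000 bp
1 credible variants, 1 in loops (2 links), 1 in open chromatin
SLDSC: planted 5x enrichment estimated at 5.31 (SD 1.29 over 20 reps)
ssGSEA: tumor mean 0.298 vs normal -0.280 (one-sided p = 5.4e-22)
```

Reading: the QC categories partition the unique fraction (55 + 18 + 11 =
84); the caller finds the planted loops at the nominal FDR; the planted
causal variant lands in a loop anchor and is linked to the gene at the
opposite anchor (including the planted target); the heritability
enrichment of the annotated SNP category is recovered near its planted
5-fold value; and the planted tumor-shifted gene set scores higher in
tumor samples.

The same machinery is available programmatically:

```r
library(hichipTargets)
study <- sim_study(sim_config(seed = 1))
res <- run_pipeline(study)        # loops, credible set, links
summarize_loci(res$links)
```

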