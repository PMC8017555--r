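---
title: "Mapping GWAS credible variants to target genes through HiChIP loops: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping GWAS credible variants to target genes through HiChIP loops: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most GWAS risk variants for epithelial ovarian cancer (and other common
diseases) are non-coding. Assigning each variant its nearest gene is known
to be unreliable: enhancers regulate promoters over tens to hundreds of
kilobases through chromatin looping. H3K27ac-HiChIP measures exactly those
enhancer-associated contacts. This package implements the analysis chain
that connects the two data types: Bayesian fine-mapping of GWAS loci into
credible variant sets, loop calling from binned HiChIP contacts,
promoter-centric annotation of loop anchors, and the intersection that
nominates a target gene whenever a credible variant occupies one anchor of
a significant loop whose other anchor holds a gene promoter. Two
enrichment statistics contextualize the result: a stratified LD-score
regression core for heritability enrichment of loop annotations, and a
single-sample GSEA statistic for tumor/normal expression contrasts of the
target-gene set.

Everything runs on synthetic data generated inside the package; no
downloads are required, and every generator plants known truth so the
pipeline's operating characteristics (credible-set coverage, loop-caller
FDR and power, end-to-end link recovery, enrichment recovery) are
measurable.

## Fine-mapping

Per-variant marginal effects $\hat\beta$ and standard errors $se$ yield
the approximate Bayes factor under a normal effect prior $N(0, W)$:

$$\mathrm{ABF} = \sqrt{\frac{V}{V+W}}\,
  \exp\!\left(\frac{z^2 W}{2(V+W)}\right), \qquad V = se^2,\; z = \hat\beta/se.$$

Under the single-causal-variant assumption the posterior probability of
variant $i$ is $pp_i = \mathrm{ABF}_i / \sum_j \mathrm{ABF}_j$; the
99% credible set accumulates variants in decreasing $pp$ until the
cumulative mass first reaches the level (inclusive). Ties are broken by
chromosome, position, then variant id, so output is deterministic.
Records with missing $\hat\beta$ or $se$ are dropped with a warning, never
imputed.

$W = 0.04$ (prior SD 0.2 per allele on a standardized trait) is the
field-standard default and is exposed as a parameter; the greedy set is
provably the smallest set achieving the level when posteriors are
distinct, and the test suite checks this against subset enumeration.

## Loop calling

Valid pairs are deduplicated on the exact coordinate/strand tuple and
classified as trans, cis long-range (> 20 kb) or cis short-range;
percentages are reported against total pairs, so the three category
percentages sum to the unique percentage — the partition identity familiar
from Hi-C QC tables. Cis pairs are binned at 5 kb
(`floor((pos - 1)/resolution)`).

The caller is a deliberately simple, fully testable member of the
FitHiC/FitHiChIP family:

1. **Distance decay.** All candidate bin pairs in 20 kb–2 Mb (zero-count
   pairs included) are split into 200 equal-occupancy distance strata; the
   per-pair contact probability in each stratum is
   $(\sum k)/(N \cdot \#\text{pairs})$ with $N$ the total in-range count.
   Weighted pool-adjacent-violators enforces monotone non-increase, and
   queries interpolate linearly between stratum mean distances (clamped at
   the ends). Isotonic smoothing rather than a parametric power law keeps
   the background assumption-free.
2. **Coverage bias.** The marginal coverage of each bin, normalized to
   mean 1 over covered bins, gives the multiplicative bias $b_i$;
   zero-coverage bins are excluded from testing. When a decay model is
   supplied, coverage is first divided by the position-expected coverage
   $e_i = \sum_j p(d_{ij})$. This correction matters on short chromosomes:
   an end-proximal bin sees partners on one side only, so its raw marginal
   coverage understates its true bias and end-proximal pairs would be
   systematically over-called. The pipeline default uses the corrected
   form; the plain ratio remains available and is what the simple
   worked examples in the documentation show.
3. **Testing.** Expected probabilities
   $\pi_{ij} = p(d_{ij})\,b_i b_j / Z$ are renormalized over the candidate
   universe; the observed count is tested against
   $\mathrm{Binomial}(N, \pi_{ij})$ (upper tail), BH-adjusted across *all*
   candidates with nonzero expected probability — including observed-zero
   pairs, for honest multiplicity — and pairs with $q \le 0.01$ become
   loops. A binomial rather than negative-binomial test keeps the null
   exact under the Poisson generator default; overdispersion is available
   behind a single generator knob for sensitivity analysis.

Loop sets from different libraries merge by anchor identity, keeping the
minimum-q statistics and the union of source labels.

## Anchor annotation and variant-to-gene mapping

Promoter windows are ±2.5 kb around the strand-aware TSS — half a 5 kb
bin on each side, so a promoter marks at most its own bin and neighbors;
the window is configurable. Anchors take the category of the
highest-precedence feature they overlap (promoter > 5' UTR > 3' UTR >
exon > intron > downstream-within-3 kb > distal intergenic; the 3 kb
downstream window follows common annotation practice). Loops are grouped
by their non-promoter anchor into promoter–promoter, promoter–distal
intergenic, promoter–intron, promoter–other, or non-promoter.

A credible variant (a 1 bp point; indels are out of scope) lying in one
anchor links to every gene at the other anchor — by promoter-window
overlap by default, with any-body overlap as an alternative mode that is a
strict superset. Link distance is |variant position − target TSS|, the
most direct reading of a variant-to-target distance; anchor-midpoint
distance could be derived from the loop coordinates if wanted. Open-
chromatin filtering keeps variants covered by a peak in every supplied
peak set (or any, by flag), and is contractive and monotone by
construction. Proximal (nearest-gene) assignment prefers the containing
gene body, then the nearest TSS, with deterministic coordinate-then-id
tie-breaks. The per-locus summary stage reports distinct credible
variants and sorted gene lists per locus with grand totals, and the
bundled published per-locus table can be pushed through the same stage.

## Enrichment statistics

**Stratified LD-score regression.** Annotation-stratified LD scores use
the small-sample-adjusted squared correlation
$r^2_{adj} = r^2 - (1-r^2)/(n-2)$ within a 1 Mb window (a base-pair
window replaces the usual genetic-map window because synthetic panels
have no map). The regression
$\chi^2_j \approx N \sum_c \tau_c \ell_j(c) + 1$ is fit by weighted least
squares with an intercept. Weights follow the standard two-step scheme:
a first pass weighted by $1/\max(\ell_j, 1)$ (LD overcounting) gives a
method-of-moments estimate of the mean per-SNP signal $\bar h^2$, and the
final fit uses $w_j = 1/[\max(\ell_j,1)(1 + N \bar h^2 \ell_j)^2]$, which
also absorbs the heteroskedasticity of chi-square statistics. Per-category
heritability follows from the coefficients, and

$$\mathrm{enrichment}_C = \frac{h^2_C / h^2}{M_C / M},$$

with block-jackknife standard errors (20 contiguous blocks). With all
$\chi^2$ exactly 1 the fit returns $\tau = 0$ and intercept 1 exactly; a
base-only model returns enrichment 1 identically. The synthetic
enrichment study deliberately gives the panel LD blocks of varying
strength (copy probability 0.2–0.95 across 40 blocks): with uniform LD
the base score is nearly constant and the intercept and polygenic term
are not separable — as in real data, identifiability comes from LD
heterogeneity.

**ssGSEA.** For one sample, genes are ranked by expression (ties broken
by gene order), and the enrichment score is the summed difference between
the weighted cumulative hit fraction (weights $|r_i|^\alpha$ on the rank
statistic, $\alpha = 0.25$ by convention) and the uniform cumulative miss
fraction. Only ranks enter, so the score is invariant under any strictly
increasing transform of the sample's values; scores are normalized across
samples by the score range. The differential-expression stage is a Welch
t-test with BH adjustment at q < 0.05 — the least-assumption default,
isolated in one function so another test can be swapped in.

## The synthetic study

The generator defaults encode the study conditions:

| parameter | default | rationale |
|---|---|---|
| locus size | 100 SNPs, 500 bp spacing | a 50 kb fine-mapping window |
| neighbor LD | 0.6 | moderately strong local LD |
| GWAS sample | n = 5000, effect for \|z\| ≈ 6 | a well-powered, genome-wide-significant locus |
| chromosome | 1 Mb, 5 kb bins | one locus-scale region per study |
| contacts | 10^6 cis pairs, decay exponent 1 | the per-Mb contact density of a deeply sequenced library |
| bin bias | log-normal, SD 0.3 | realistic coverage spread |
| planted loops | 10 at 5-fold, log-uniform separations | median separation ≈ 130 kb, matching observed loop-distance scales |
| genes | 40 disjoint, spans 5–20 kb | gene density of a gene-rich locus |
| expression | 20 tumor / 20 normal, 25% of genes shifted 2 log2-fold | a typical microarray contrast |

Haplotypes follow first-order Markov copying (copy probability =
target neighbor correlation, fresh Bernoulli(MAF) otherwise) — the
simplest process with tunable LD. Counts are Poisson around
depth × decay × bias (negative binomial behind the `overdispersion`
knob). Phenotypes are quantitative with marginal OLS summary statistics;
the ABF is identical in form for log-odds, so nothing depends on the
trait type. Loop separations are drawn log-uniformly over 20 kb–2 Mb
(clipped to the chromosome), reflecting the short-range skew of real
loop-distance distributions. The assembled study plants the causal
variant inside the distal anchor of a loop whose other anchor holds a
gene TSS, so exactly one variant–gene link is expected.

What the generator does *not* emulate: restriction-fragment structure,
trans contacts, TADs and A/B compartments, multi-causal loci, population
stratification, isoform-level TSS choice, and batch effects in
expression. Passing tests therefore demonstrate internal correctness and
calibration under the stated model, not robustness to those real-data
complications.

## Numerical choices and degenerate inputs

- Internal coordinates are half-open 0-based; GTF and allValidPairs are
  1-based at the file boundary, BED/BEDPE half-open 0-based. Variant
  positions are 1-based points; the variant-to-TSS distance subtracts the
  stored TSS field directly, so it is exact at the file convention and at
  most 1 bp off the zero-based internal convention — immaterial at loop
  resolution.
- All-zero contact matrices produce a flat decay model with a warning;
  zero-count pairs get p = 1 and can never become loops.
- The WashU longrange score is −log10(q) capped at 300 to keep finite
  text output for q values at the double-precision floor.
- Equal-posterior ties in fine-mapping, equidistant proximal genes, and
  gene ordering in annotation are all resolved by fixed deterministic
  rules, so every stage is reproducible bit-for-bit from (inputs, seed).
- Problem sizes in the test suite (1,000 fine-mapping loci; 50 null and 5
  signal contact simulations; 20 end-to-end seeds; a 2,000 × 2,000
  enrichment panel with 50 phenotype replicates) were chosen as the
  smallest sizes at which the binomial/credible-set/regression
  calibrations are statistically informative.

## Known limitations

- The loop caller is peak-to-all over one resolution; no spline
  regression, no negative-binomial background, no ICE balancing, no
  trans loops, no TAD context.
- Fine-mapping assumes a single causal variant per locus and ignores LD
  in the posterior (standard for ABF credible sets); multi-causal loci
  need stochastic-search or SuSiE-style methods.
- The LD-score core carries user-supplied annotations only; it does not
  replicate the full baseline-annotation model, and its enrichment
  estimates on small panels are noisy (the jackknife SE is reported for
  exactly that reason).
- eQTL target lists are taken as given; computing eQTLs is out of scope.
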