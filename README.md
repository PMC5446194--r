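# methocc

Links DNA methylation context to MeCP2 chromatin occupancy and to the
direction of transcriptional change when MeCP2 is lost or over-expressed.

MeCP2 is an abundant neuronal methyl-CpG–binding protein whose loss causes
Rett syndrome. Two observations complicate naive ChIP-seq analyses of its
binding: the Input (no-immunoprecipitation) coverage alone predicts most of
the ChIP signal, so occupancy must be read from the Input-corrected ratio;
and total RNA per cell drops ~15% in the knockout, so standard
count-normalised differential expression silently erases a genuine global
down-regulation. `methocc` implements the full inference chain around these
two ideas, for researchers in regulatory genomics who want to study the
methylation–occupancy–expression coupling or to stress-test the statistical
steps on simulated data with known ground truth.

## What it computes

* **Methylation context statistics.** Every cytosine is classified by
  strand-aware di-/tri-nucleotide context (CG, CA, …, CAC, …). For a region
  of length *L* with *N*<sub>CX</sub> covered sites of context CX, the mean
  methylation is *m′*<sub>CX</sub> = Σᵢ *m*ᵢ / *N*<sub>CX</sub> (per-site
  level *m*ᵢ = mC / C basecalls) and the **methylation density** is
  *N*<sub>CX</sub>·*m′*<sub>CX</sub>/*L*, reported per kb. Paired
  bisulfite/TAB measurements resolve 5mC from 5hmC (BS reads mC+hmC, TAB
  reads hmC), and unmethylated spike-in DNA yields the non-conversion rate.
* **Input-corrected occupancy.** Fragments are shifted and binned into
  fixed windows (RPKM-normalised); occupancy is
  log2((ChIP+ψ)/(Input+ψ)) per window. A linear model ChIP ~ Input
  quantifies how much of the ChIP signal is sequence/composition bias
  (R²), and an outlier partition labels relatively depleted/enriched
  windows (default tail fractions 4.1% / 1.7%) before refitting on the
  neutral rest.
* **Summits and meta-profiles.** A simplified Poisson-background summit
  caller, uniform random-position controls, and anchored profile matrices
  (summits ±4 kb at 20 bp; TSS ±100 kb at 1 kb; CGIs).
* **Multiscale domains.** A geometric smoothing ladder segments the
  occupancy signal into enriched/depleted domains at each scale (binomial
  test per segment, p < 1e-6), with per-segment mCG/mCAC density and GC
  annotations, scale-by-score summaries, and a shuffle test for CGI
  overlap of short depleted segments.
* **Globally-rescaled differential expression.** Median-of-ratios size
  factors, the ×1.15 KO size-factor correction for the measured global RNA
  reduction, a self-contained moderated negative-binomial Wald test,
  TPM-based gene classification (up / down / unchanged / other /
  filtered), gene-level occupancy aggregation (body ± 100 kb), rolling-mean
  and grouped density curves, domain-overlap proportions, and
  occupancy–fold-change rank correlations.
* **Synthetic data with ground truth.** `sim_config()` +
  `simulate_experiment()` generate a CG-depleted genome with realistic CpG
  islands, a domain-structured CAC methylome, biased Input and
  density-coupled ChIP fragments, and NB counts whose KO fold changes
  couple to occupancy under a global 0.85 scale — with every planted
  parameter recorded for recovery tests.

All user-facing functions take and return tibbles (fitted objects support
`tidy()`/`glance()`, result types have `autoplot()` methods), so the whole
pipeline composes with the pipe.

## Worked example

```r
library(methocc)

cfg <- sim_config(seed = 42, n_chroms = 1, chrom_length = 2e6,
                  domain_length_range = c(5e4, 1e5), cgi_count = 20,
                  coverage_depth = 100, n_genes = 1000)
sim <- simulate_experiment(cfg)

chip  <- bin_coverage(sim$chip,  sim$genome, w = 1000, shift = 67)
input <- bin_coverage(sim$input, sim$genome, w = 1000, shift = 67)
occ   <- log2_ratio(chip, input)

fit <- partition_outliers(fit_input_model(chip, input))
glance(fit)
#>    r.squared neutral.r.squared n.windows frac.depleted frac.enriched
#> 1 0.00000129         0.0000148      2000         0.041         0.017

segs <- multiscale_segments(chip, input, scales = 3:8) |>
  annotate_segments(sim$sites, sim$genome)
dplyr::count(tibble::as_tibble(segs), label)
#>   label        n
#> 1 depleted    92
#> 2 enriched   124

ex <- sim$expression
factors <- size_factors(ex$counts) |>
  apply_global_scale(ex$samples, "KO", 1.15)
de <- nb_test(ex$counts, ex$samples, factors, contrast = c("KO", "WT")) |>
  classify_genes(compute_tpm(ex$counts))
glance(de)
#>   test reference n.genes n.tested n.signif n.up n.down
#> 1 KO   WT           1000     1000      135   34    101

st <- occupancy_expression_stats(gene_occupancy(sim$genes, occ, flank = 1e5), de)
st$rho_ko
#> [1] 0.214
```

The R² near zero says the synthetic Input carries no long-range
compositional structure beyond Poisson noise (real genomes differ; see the
vignette), while the outlier partition reproduces its configured 4.1%/1.7%
tail fractions exactly. The segment table shows the multiscale caller
finding both enriched (high-mCAC) and depleted domains. In the expression
block, the ×1.15 correction applied after median-of-ratios reveals the
planted global reduction as an excess of down-regulated genes (101 down vs
34 up), and the positive Spearman ρ says genes under high MeCP2 occupancy
are preferentially **up**-regulated when the protein is removed — the
repression signature.

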