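# admixscan

Admixture-aware scans for post-admixture adaptive evolution in recently
admixed populations.

## The problem

A recently admixed population (for example a highland population whose
ancestry mixes West-Eurasian-like, South-Asian-like and minor
East-Asian/Siberian-like sources) inherits, at every site, an allele
frequency that is — under neutrality — the average of the source
frequencies weighted by the genome-wide ancestry proportions:

```
p_exp,i = Σ_k w_k · p_k,i
```

Loci where the observed frequency departs from this expectation faster
than sampling and drift allow are candidates for post-admixture selection.
`admixscan` implements that reasoning as a reusable pipeline for
population geneticists working with phased genotype panels:

* **AFd_e scan** — the allele-frequency deviation from the admixture
  expectation, `AFd_e = |p_obs − p_exp|`, with a z-test whose variance
  combines target sampling `p(1−p)/2n_t`, source sampling
  `Σ w_k² p_k(1−p_k)/2n_k`, and an optional drift term
  `p(1−p)·G/2Ne`; gene-level ranking by the proportion of significant
  sites.
* **Haplotype scans** — EHH/iHH, iHS (frequency-bin standardized) and
  XP-EHH (pooled-allele, genome-standardized), with the walks in C++.
* **Weir–Cockerham FST** (1984 variance components, per site and
  ratio-of-sums over windows) and pairwise LD (r², D′).
* **CMS** — a rank-based composite of AFd_e, |iHS|, XP-EHH and FST:
  `CMS_i = (4/S_i) Σ_s −ln(1 − r_is)` over the available statistics, with
  gene-level `MaxCMS` and empirical p-values drawn from SNP-count-matched
  gene bins (significant at p < 0.05).
* **mGSEA** — weighted running-sum enrichment of gene sets in a
  score-ranked gene list, with gene-sampling permutation p-values and BH
  adjustment.
* **Diversity** — windowed θ_π, θ_W, Tajima's D, haplotype diversity,
  rare-variant proportion (50 kb / 25 kb sliding windows by default),
  per-sample heterozygosity and F̂, and PLINK-style ROH detection with
  short / intermediate (2–10 Mb) / long (>10 Mb) classes.
* **Archaic introgression** — segment enrichment against the
  admixture-expected archaic-haplotype frequency, and windowed U / Q95
  statistics with joint-outlier calls.
* **Admixture-LD dating** — single-pulse admixture time from the decay
  of the weighted LD statistic `ŵ(d) = mean(u_i u_j D_ij)` fit as
  `a·exp(−T·d) + c` (d in Morgans), with bootstrap confidence intervals.
* **Synthetic data with truth** — a seeded generator (Balding–Nichols
  sources, Poisson ancestry-tract mosaics copied from finite template
  pools, injected hard sweeps) so every stage is testable end to end
  without restricted cohort data.

Input formats are the field's: phased VCF 4.2 (with the `AA` ancestral
allele tag), TSV sample maps, plink-style genetic maps, BED gene models,
GMT gene sets.

## Worked example

Simulate a three-way admixed population (ancestry 0.483/0.373/0.144, one
pulse 40 generations ago) with one injected sweep, then run the composite
scan:

```r
library(admixscan)

cfg <- simConfig(n_sites = 5000, chrom_length_bp = 1e7, seed = 42,
                 n_genes = 100, gene_length = 20000)
cfg$selected <- data.frame(site = chooseSweepSite(cfg), s = NA, G = NA,
                           target_freq = 0.85, span_bp = 5e5)
sim <- simulateDataset(cfg)
sim$panel
#> HaplotypePanel: 5000 variants x 800 haplotypes ( 400 samples )
#>   populations: ADM (n=100), EAS (n=100), EUR (n=100), SAS (n=100)
#>   phased: TRUE
sim$truth$selected[, c("site", "pos", "target_freq", "realized_freq")]
#>   site     pos target_freq realized_freq
#> 1 2499 5014003        0.85          0.85

af  <- afdeScan(sim$panel, "ADM", sim$spec,
                drift_opts = matchedDriftOpts(cfg))
ih  <- ihsScan(sim$panel, "ADM", sim$map)
xp  <- xpehhScan(sim$panel, "ADM", "EUR", sim$map)
fs  <- fstScan(sim$panel, "ADM", "EUR")
cms <- cmsScan(buildSiteStats(af, ih, xp, fs))
genes <- geneCmsPvalues(cms, sim$genes, "chr1")
head(genes[order(genes$p_value, -genes$max_cms), ], 5)
#>     gene_id n_snps   max_cms bin    p_value significant
#> 49 gene0049     14 21.464237   2 0.01587302        TRUE
#> 66 gene0066      6  8.494786   1 0.02702703        TRUE
#> 52 gene0052     14 21.112381   2 0.03174603        TRUE
#> 51 gene0051      9 19.836815   2 0.04761905        TRUE
#> 12 gene0012      7  7.906776   1 0.05405405       FALSE
```

The sweep was injected at 5.01 Mb; the genes tiled across 4.85–5.15 Mb
(`gene0049`–`gene0052`) carry the largest gene-level composite scores
(`max_cms` ≈ 20–21 against a neutral background of ≈ 8) and are called
significant against their SNP-count-matched empirical nulls.

The same analysis runs as one orchestrated call —
`runPipeline(config, out_dir)` with a config list or YAML file — writing
per-stage TSVs, a manifest (config hash, seed, row counts) and a summary;
reruns with the same config and seed are bit-identical, and existing
stage outputs are reused.

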