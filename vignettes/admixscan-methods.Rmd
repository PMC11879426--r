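---
title: "Methods: admixture-aware selection scans in admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture-aware selection scans in admixscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`admixscan` detects post-admixture adaptive evolution in recently admixed
populations from phased genotypes. This vignette documents the models and
procedures, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the method itself is underdetermined.

## 1. The admixture expectation and the AFd_e test

For an admixed target with global ancestry proportions $w_k$ from source
populations $k$, the neutral expectation of the allele frequency at site
$i$ is the weighted source average $p_{\exp,i} = \sum_k w_k\,p_{k,i}$
("rules of admixture"). The deviation statistic is
$\mathrm{AFd_e} = |p_{\mathrm{obs}} - p_{\exp}|$.

The literature leaves "significant AFd_e" undefined, so the package
defines a calibratable test: $z = (p_{\mathrm{obs}} -
p_{\exp})/\sqrt{V}$ with

$$V = \frac{p_{\exp}(1-p_{\exp})}{2n_t}
    + \sum_k \frac{w_k^2\, \hat p_k(1-\hat p_k)}{2n_k}
    + \frac{p_{\exp}(1-p_{\exp})\,G}{2N_e},$$

a two-sided normal p-value and a default $\alpha = 0.001$. The first two
terms are sampling variance of the target and source panels ($n$ in
diploids); the third, off by default, absorbs genuine drift since
admixture ($G$ generations, effective size $N_e$) or any analogous extra
variance. On simulated data `matchedDriftOpts()` returns the $(G, N_e)$
pair whose drift term equals the generator's template-pool variance
$\sum_k w_k^2 p_k(1-p_k)/M_k$, making the null exactly matched; this is
how the z-scores come out $\mathcal N(0,1)$ in the calibration tests.
Sites where every panel is monomorphic are flagged invalid; if $V = 0$
with no deviation, $z = 0$; if $V = 0$ with a deviation (degenerate
source panels), the observed-frequency binomial term is used instead so
the site is not silently dropped.

Gene-level ranking counts, per gene interval (gene body by default,
`flank` configurable), the proportion of contained valid SNVs whose
AFd_e is significant; genes are ranked descending by proportion with
ties broken by significant count, then gene id (dense ranks). The
observed-vs-expected site-frequency-spectrum comparison histograms
derived-allele frequencies over shared bin edges and reports the
total-variation distance.

## 2. Haplotype statistics

**EHH.** From a core SNP and a carrier set, EHH at marker $x$ is the
fraction of carrier pairs identical at every SNP from the core through
$x$; the walk stops when EHH drops below `cutoff` (default 0.05), at the
chromosome end (flagged truncated), or at an inter-SNP gap above
`max_gap_bp` (default 200 kb). Integration (iHH) is trapezoidal over
genetic distance from the supplied map. These defaults mirror the common
scanning software's; all are arguments.

**iHS.** Per derived-polarized site, $\ln(\mathrm{iHH_{anc}} /
\mathrm{iHH_{der}})$, standardized to mean 0 / sd 1 within
derived-frequency bins (50 equal-width bins, bins under 20 SNPs merged
left-to-right). Sites with unknown ancestral allele are skipped rather
than polarity-guessed by frequency — a wrong guess silently flips the
sign — and end-truncated sites are invalid. Polarity comes from the `AA`
VCF tag only.

**XP-EHH.** Pooled-allele EHH (the partition starts from the core
alleles; EHH at the core is the pooled homozygosity) computed jointly in
target and reference with a shared walk that stops when EHH is below the
cutoff in *both* populations, so the two integrals cover the same
interval. $\ln(\mathrm{iHH_t}/\mathrm{iHH_r})$ is standardized
genome-wide; positive values mean longer homozygosity in the target.
The pooled-allele definition is one of the two conventions in use; it
needs no polarization and behaves well when the core allele is near
fixation in one population.

**FST and LD.** Per-site Weir–Cockerham (1984) two-population components
$a, b, c$ with sample-size correction (heterozygosity from the sample
genotypes), $\hat\theta = a/(a+b+c)$ reported as computed (negative
values included); multi-SNP FST is the ratio of summed components.
Pairwise LD returns $r^2$ and $|D'|$ from phased haplotype counts.

## 3. The composite score (CMS) and its gene-level null

The composite is rank-based. For statistic $s$ with $N_s$ valid sites,
the rank fraction of site $i$ is $r_{is} = \mathrm{rank}_i/(N_s+1)$
(average ranks on ties; each statistic oriented so larger = more
selection-like: AFd_e, $|$iHS$|$, signed XP-EHH, FST), and

$$\mathrm{CMS}_i = \frac{4}{S_i} \sum_{s\ \mathrm{available}}
  -\ln(1 - r_{is}),$$

with $S_i \ge$ `min_stats` (default 3) required. The published
composite-of-signals idea prescribes rank consensus but not a formula;
this sum of exponential tail transforms was chosen because it is
invariant to monotone transforms of each input, unbounded above (so a
maximum is informative), exactly testable against an independent rank
implementation, and reduces to $4\ln 2 \approx 2.77$ at all-median
ranks.

Gene-level `MaxCMS` is the maximum CMS over a gene's valid SNPs. Because
a maximum grows with the number of SNPs, empirical p-values are computed
within SNP-count-matched bins: deciles of the per-gene SNP count, merged
left-to-right so every bin holds at least 30 genes (both configurable; a
single-bin fallback applies below 30 genes, with a warning). The p-value
is $(1 + \#\{\text{bin genes with } \mathrm{MaxCMS} \ge
\mathrm{MaxCMS}_g,\ g \text{ excluded}\})/B$ — the $+1$ convention keeps
$p > 0$ and makes ties conservative — and genes are significant at
$p < 0.05$. Under neutrality this construction yields uniform p-values
by exchangeability, which the test suite checks by KS test.

## 4. mGSEA

Enrichment of a gene set in a score-ranked gene list uses the weighted
running sum: member genes add $s_i^p/\sum_{\mathrm{members}} s^p$
(weight $p = 1$ default), non-members subtract $1/(N-m)$, and the score
is the signed maximum deviation. Significance comes from $B$ random
same-size gene draws from the universe ($p = (1 + \#\{ES_\mathrm{null}
\ge ES_\mathrm{obs}\})/(B+1)$, one-sided for enrichment, two-sided
behind a flag), BH adjustment across sets, and a normalized score
$ES/\overline{ES^+_\mathrm{null}}$. The "modification" in the modified
GSEA the field applies to ranked selection scores is not publicly
specified; gene-sampling nulls on a caller-supplied ranking metric
(significant-AFd_e proportion or MaxCMS — both supported) are this
package's concrete choice, and runs are bit-reproducible given the seed.

## 5. Archaic introgression summaries

Segment detection is out of scope: the enrichment test consumes a
segment table with target and per-source archaic-haplotype frequencies.
Expected frequency is again $\sum_k w_k f_k$; the z-test is the same
code path as the AFd_e scan (asserted by test), with a one-sided upper
p-value because only excess frequency counts as enrichment — under a
binomial null the enriched fraction then matches $\alpha$.

The windowed U/Q95 scan counts sites whose derived allele is rare in an
outgroup (AF < $w$, default 0.01), common in the target (AF > $x$,
default 0.20) and carried by the archaic genome at dosage fraction $y$
(default 1.0, i.e. homozygous derived; $y = 0.5$ matches heterozygous
carriers); Q95 is the 95th percentile (linear interpolation) of target
derived AF over sites passing the outgroup and archaic conditions.
Windows at or above the genome-wide 0.999 quantile of both statistics
are joint outliers. The thresholds follow the conventions of the
statistic's originating literature and are all exposed.

## 6. Admixture-LD dating

With per-SNP weights $u_i = \hat p_{1,i} - \hat p_{2,i}$ from two source
panels and $\hat D_{ij}$ the haplotype covariance between SNPs in the
target, the binned statistic $\hat w(d) = \mathrm{mean}_{|i,j|\in d}\,
u_i u_j \hat D_{ij}$ decays, under a single admixture pulse $T$
generations ago, as $\exp(-T d)$ in Morgans. The package fits
$a\,e^{-T d/100} + c$ (distances in cM) by Levenberg–Marquardt least
squares over bins with at least 100 pairs in a 0.5–30 cM default range;
the affine $c$ absorbs background LD. Bins pool across replicate
chromosomes when several panels are given; confidence intervals are
bootstrap over chromosomes, or over contiguous site blocks (pairs
assigned to the block of their first member, computed on the full
matrix so long-range pairs are kept) for a single chromosome. A fit is
flagged unidentifiable when it fails, the amplitude is non-positive, or
the amplitude is below twice the residual sd — an unadmixed target
triggers this. Sites are thinned evenly to `max_sites` (default 3000)
before the $O(\text{sites}^2)$ pair computation.

## 7. The synthetic-data generator

The generator produces the study conditions every calibration and
recovery experiment runs under; its defaults are fixed once:

* **Sources.** Balding–Nichols frequencies: ancestral $p \sim
  U(0.05, 0.95)$, source $k$ frequency $\sim \mathrm{Beta}(p(1-F_k)/F_k,
  (1-p)(1-F_k)/F_k)$. Default three sources (West-Eurasian-like,
  South-Asian-like, East-Asian-like) with $F = (0.08, 0.08, 0.10)$ —
  continental-scale divergence — and ancestry weights
  $0.483/0.373/0.144$, the three-way collapse of the admixture profile
  of the motivating highland population with the two minor eastern
  components merged.
* **Admixture.** A single pulse $T = 40$ generations ago by default
  (the age of the most recent major admixture wave reported for such
  populations); two-wave histories compose sequentially, older wave
  first, each wave a Poisson switch-point process at rate $T$ per Morgan
  along a uniform map (default 1.2 cM/Mb, the human genome-wide
  average), with the newest wave overwriting a configured fraction of
  segments. Tract mosaics are Markov approximations of pedigree
  reality.
* **Haplotypes.** Each source backs a finite pool of $M_k$ template
  haplotypes (default 500) with alleles independent across sites; each
  admixed haplotype copies every tract from one uniformly chosen
  template of the tract's source. Finite pools induce within-source
  haplotype sharing — enough EHH structure to test iHS/XP-EHH sign and
  ranking at desk scale — while coalescent-exact LD is deliberately out
  of scope. Source *samples* are drawn i.i.d. from the source
  frequencies, independent of the pools: this keeps the AFd_e variance
  formula exact, with the pool's own fluctuation accounted for by the
  matched drift term (Section 1). Default panel sizes: 100 admixed and
  100 per-source diploids.
* **Selection.** A sweep at a chosen site is realized by replacing the
  local span (default interpretation: `span_bp` centered on the site) of
  random non-carrier haplotypes with copies of one random carrier until
  the site frequency first reaches its target — either given directly or
  from the deterministic genic recursion $p' = p(1+s)/(1+sp)$ iterated
  $G$ generations. This hard-sweep injection produces the two signals
  the scans consume (frequency shift and local haplotype homozygosity)
  with a known truth, unlike forward resampling whose endpoint is
  random. `chooseSweepSite()` picks a usefully polymorphic site from the
  seed-deterministic frequency draw.
* **Reproducibility.** One mandatory seed; the three generation stages
  use fixed offsets of it, truth files serialize it, and regeneration is
  bit-identical.

What passing tests on this generator do *not* show: robustness to real
LD structure in the sources, to ascertainment or genotyping error (the
loader rejects missing data; imputation and phasing are upstream,
out-of-scope steps), to mis-specified ancestry proportions from proxy
sources, or to multi-wave histories when a single-pulse model is fit.

## 8. Experiment sizes and numerical choices

The packaged experiments use: neutral calibration on 5 Mb / 20 000 SNVs
/ 200 admixed haplotypes with 200 tiled genes; sweep recovery on a
50 Mb chromosome (so one 1 Mb sweep leaves the SNP-count-matched gene
null essentially uncontaminated) and a 150 Mb chromosome for the
top-1% |iHS| check (the swept interval must be well under 1% of scanned
sites for that rank to be attainable at all); dating on ten replicate
5 Mb chromosomes at 2 cM/Mb per true age; tract statistics on a
4-Morgan map, where the short-bias of boundary-censored interior tracts
(≈ mean/length) falls to about 1%. These sizes are the package's chosen
desk-scale study conditions and are stated in the tests that use them.

Other numerical conventions: internal coordinates are GRanges (1-based,
closed); BED I/O converts through rtracklayer; genetic-map queries
interpolate linearly with constant extrapolation; windows are
`size`/`step` sliding (50 kb / 25 kb defaults, non-overlapping for the
archaic scan); Tajima's D is undefined (NA) below 3 segregating sites
and at $n = 2$ haplotypes, where its variance constants vanish; ROH
defaults (500 kb minimum, 1 heterozygote allowed per 50-SNP block) are
PLINK-like conventions, since no standard exists for the underlying
analysis; empirical p-values everywhere use $+1$ numerators; ties take
average ranks.

## 9. Known limitations

Proxy-source bias (the source panels are modern proxies of the true
ancestral populations) is acknowledged, not corrected. The AFd_e test
treats sites independently; no LD-aware multiple-testing correction is
applied beyond the empirical gene-level nulls. The dating model is
single-pulse with a free intercept; multi-wave model selection is out of
scope. Archaic segment calls are inputs, not inferences. The simulator's
within-source LD is template-sharing, not coalescent, so absolute iHH
magnitudes are not comparable to real data — only ranks and signs are
used downstream.
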