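Package: admixscan
Title: Admixture-Aware Scans for Post-Admixture Adaptive Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting post-admixture adaptive evolution in
    recently admixed populations from phased genotypes. Computes allele
    frequencies expected under the admixture proportions of the source
    populations and the deviation from that expectation (AFd_e) with a
    calibrated significance test, extended-haplotype statistics (EHH, iHS,
    XP-EHH), Weir-Cockerham FST, and a rank-based
    composite-of-multiple-signals (CMS) score with gene-level empirical
    p-values from SNP-count-matched nulls. Also provides windowed diversity
    statistics (nucleotide and haplotype diversity, Tajima's D, rare-variant
    proportion), runs of homozygosity, modified gene-set enrichment over
    score-ranked genes, archaic-introgression enrichment and U/Q95 window
    statistics, and single-pulse admixture dating from weighted
    linkage-disequilibrium decay. A seeded synthetic admixed-genome
    generator with known truth (source frequencies, ancestry tracts,
    injected sweeps) supports end-to-end testing without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
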