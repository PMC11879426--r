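# Small in-code fixtures: panels built directly from allele matrices.

library(GenomicRanges)

makePanel <- function(alleles, pops, pos = NULL, chrom = "chr1",
                      anc = "A", ref = "A", alt = "C") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  ns <- ncol(alleles) / 2
  if (is.null(pos)) pos <- seq_len(nrow(alleles)) * 1000L
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                id = sprintf("v%04d", seq_len(nrow(alleles))),
                ref = ref, alt = alt,
                anc = rep(anc, length.out = nrow(alleles)))
  samples <- sprintf("s%03d", seq_len(ns))
  HaplotypePanel(gr, alleles, samples,
                 setNames(rep(pops, length.out = ns), samples))
}

# Uniform 1 cM/Mb map over the span of a panel (plus margin).
flatMap <- function(panel, rate = 1) {
  v <- variantInfo(panel)
  uniformGeneticMap(as.character(seqnames(v))[1], max(end(v)) + 1000, rate)
}

# A small random two-population panel.
randomPanel <- function(n_sites = 40, n_per_pop = c(A = 6, B = 6),
                        seed = 1, p = 0.4) {
  set.seed(seed)
  nh <- 2 * sum(n_per_pop)
  al <- matrix(rbinom(n_sites * nh, 1L, p), n_sites, nh)
  makePanel(al, rep(names(n_per_pop), n_per_pop))
}

# Tiny reference simulation configs reused across tests.
tinySimConfig <- function(seed, n_sites = 2000, chrom_length_bp = 1e6,
                          ...) {
  simConfig(n_sites = n_sites, chrom_length_bp = chrom_length_bp,
            sources = data.frame(label = c("EUR", "SAS", "EAS"),
                                 F = c(0.08, 0.08, 0.10),
                                 pool_size = c(100, 100, 100),
                                 sample_n = c(50, 50, 50)),
            admixed_sample_n = 50, n_genes = 40, gene_length = 10000,
            seed = seed, ...)
}
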