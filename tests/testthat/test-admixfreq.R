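test_that("expected frequency is the weight-averaged source frequency", {
  spec2 <- AdmixtureSpec(c("a", "b"), c(0.5, 0.5))
  m <- cbind(a = 0.2, b = 0.6)
  expect_equal(expectedAF(m, spec2), 0.4)
  spec1 <- AdmixtureSpec("a", 1)
  expect_equal(expectedAF(cbind(a = c(0.1, 0.9)), spec1), c(0.1, 0.9))
  # four-way weights renormalized, checked against an independent dot product
  w4 <- c(0.465, 0.359, 0.056, 0.082)
  spec4 <- AdmixtureSpec(letters[1:4], w4 / sum(w4))
  set.seed(3)
  m4 <- matrix(runif(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  hand <- sapply(seq_len(10), function(i) sum(m4[i, ] * w4 / sum(w4)))
  expect_equal(expectedAF(m4, spec4), hand)
  # linearity in the weights
  specA <- AdmixtureSpec(c("a", "b"), c(0.3, 0.7))
  specB <- AdmixtureSpec(c("a", "b"), c(0.6, 0.4))
  mid <- AdmixtureSpec(c("a", "b"), c(0.45, 0.55))
  expect_equal((expectedAF(m, specA) + expectedAF(m, specB)) / 2,
               expectedAF(m, mid))
  expect_error(expectedAF(cbind(a = 0.1), spec2), "no AF vector")
})

test_that("AFd_e is the absolute deviation from expectation", {
  # target 434/1000 alt haplotypes, single source at 301/1000:
  # observed 0.434, expected 0.301, AFd_e = 0.133
  al_t <- c(rep(1L, 434), rep(0L, 566))
  al_s <- c(rep(1L, 301), rep(0L, 699))
  al <- rbind(c(al_t, al_s), c(al_t, al_s))
  p <- makePanel(al, rep(c("T", "S"), each = 500))
  sp <- AdmixtureSpec("S", 1)
  sc <- afdeScan(p, "T", sp, alpha = 0.001)
  expect_equal(sc$p_obs, c(0.434, 0.434))
  expect_equal(sc$p_exp, c(0.301, 0.301))
  expect_equal(sc$afde, c(0.133, 0.133))
})

test_that("a target equal to its expectation shows no deviation", {
  set.seed(5)
  half <- matrix(rbinom(20 * 40, 1, 0.5), 20, 40)
  al <- cbind(half, half)     # target haplotypes identical to source
  p <- makePanel(al, rep(c("T", "S"), each = 20))
  sc <- afdeScan(p, "T", AdmixtureSpec("S", 1))
  expect_equal(sc$afde, rep(0, 20))
  expect_false(any(sc$significant))
  expect_equal(sc$z, rep(0, 20))
  expect_error(afdeScan(p, "T", AdmixtureSpec("S", 1), alpha = 1.5),
               "alpha")
})

test_that("AFd_e is invariant to flipping the allele coding", {
  sim <- simulateDataset(tinySimConfig(33, n_sites = 500))
  sc1 <- afdeScan(sim$panel, "ADM", sim$spec)
  flipped <- sim$panel
  flipped@alleles <- 1L - flipped@alleles
  sc2 <- afdeScan(flipped, "ADM", sim$spec)
  expect_equal(sc2$afde, sc1$afde)
  expect_equal(sc2$z, -sc1$z)
})

test_that("injected frequency shifts are recovered as significant", {
  base <- tinySimConfig(37, n_sites = 4000, chrom_length_bp = 8e6)
  sites <- sapply(c(0.2, 0.5, 0.8), function(f)
    chooseSweepSite(base, c(0.3, 0.55), f))
  base$selected <- data.frame(site = sites, s = NA, G = NA,
                              target_freq = 0.85, span_bp = 2e5)
  sim <- simulateDataset(base)
  sc <- afdeScan(sim$panel, "ADM", sim$spec, alpha = 0.001,
                 drift_opts = matchedDriftOpts(base))
  shift <- sim$truth$selected$realized_freq -
    sc$p_exp[sim$truth$selected$site]
  expect_true(all(shift >= 0.15))
  expect_gte(mean(sc$significant[sites]), 0.8)
})

test_that("gene ranking aggregates significant proportions", {
  af <- data.frame(site = 1:10, chrom = "chr1",
                   pos = c(1:10) * 100,
                   p_obs = 0.5, p_exp = 0.4, afde = 0.1, z = 1,
                   p_value = 0.3,
                   significant = c(rep(TRUE, 3), rep(FALSE, 7)),
                   valid = TRUE)
  g <- GRanges("chr1", IRanges(c(50, 2000), width = 1000),
               gene_id = c("g1", "g2"))
  r <- geneAfdeRanking(af, g)
  expect_equal(r$n_snvs[r$gene_id == "g1"], 10L)
  expect_equal(r$proportion[r$gene_id == "g1"], 0.3)
  expect_equal(nrow(r), 1L)         # g2 holds no SNV -> excluded
  # no significant SNVs: rank falls back to the tie-break order
  af0 <- af
  af0$significant <- FALSE
  g2 <- GRanges("chr1", IRanges(c(50, 450), width = 400),
                gene_id = c("gB", "gA"))
  r0 <- geneAfdeRanking(af0, g2)
  expect_equal(r0$proportion, c(0, 0))
  expect_equal(r0$rank, c(1L, 1L))  # dense ranks tie at the top
  expect_equal(r0$gene_id, c("gA", "gB"))
})

test_that("gene assignment equals brute-force interval containment", {
  set.seed(7)
  pos <- sort(sample.int(50000, 50))
  af <- data.frame(site = 1:50, chrom = "chr1", pos = pos,
                   p_obs = 0.5, p_exp = 0.4, afde = 0.1, z = 1,
                   p_value = 0.3,
                   significant = rbinom(50, 1, 0.3) == 1,
                   valid = rbinom(50, 1, 0.9) == 1)
  starts <- c(1, 9000, 21000, 30000, 42000)
  g <- GRanges("chr1", IRanges(starts, width = 8000),
               gene_id = paste0("g", 1:5))
  flank <- 500
  r <- geneAfdeRanking(af, g, flank = flank)
  for (i in seq_along(starts)) {
    lo <- starts[i] - flank
    hi <- starts[i] + 8000 - 1 + flank
    inside <- af$valid & af$pos >= lo & af$pos <= hi
    gid <- paste0("g", i)
    if (any(inside)) {
      expect_equal(r$n_snvs[r$gene_id == gid], sum(inside))
      expect_equal(r$n_significant[r$gene_id == gid],
                   sum(af$significant[inside]))
    } else {
      expect_false(gid %in% r$gene_id)
    }
  }
})

test_that("observed and expected spectra are binned identically", {
  sim <- simulateDataset(tinySimConfig(43, n_sites = 2000))
  p_obs <- alleleFrequency(sim$panel, "ADM")
  s_id <- observedVsExpectedSFS(sim$panel, "ADM", p_obs, n_bins = 10)
  expect_equal(s_id$observed, s_id$expected)     # identical inputs
  expect_equal(sum(s_id$observed), s_id$n_sites)
  expect_equal(s_id$tv_distance, 0)
  # all mass at 0.5 occupies a single bin
  s_half <- observedVsExpectedSFS(sim$panel, "ADM",
                                  rep(0.5, 2000), n_bins = 10)
  expect_equal(sum(s_half$expected > 0), 1L)
  expect_error(observedVsExpectedSFS(sim$panel, "ADM", p_obs, n_bins = 1))
})

test_that("the weighted LD curve is scale-equivariant in the weights", {
  sim <- simulateDataset(simConfig(
    n_sites = 800, chrom_length_bp = 4e6, recomb_rate = 2,
    sources = data.frame(label = c("P1", "P2"), F = c(0.2, 0.2),
                         pool_size = c(100, 100), sample_n = c(40, 40)),
    weights = c(0.5, 0.5), T_gen = 30, admixed_sample_n = 60,
    n_genes = 5, seed = 47))
  X <- haploMatrix(sim$panel)[, hapColumns(sim$panel, "ADM")]
  u <- alleleFrequency(sim$panel, "P1") - alleleFrequency(sim$panel, "P2")
  cm <- mapDistance(sim$map, "chr1", start(variantInfo(sim$panel)))
  c1 <- weightedLdCurve(X, u, cm, d_range = c(0.5, 7))
  c2 <- weightedLdCurve(X, 2 * u, cm, d_range = c(0.5, 7))
  expect_equal(c2$w, 4 * c1$w)
  expect_equal(c2$n_pairs, c1$n_pairs)
})

test_that("an unadmixed target yields no dateable admixture LD", {
  sim <- simulateDataset(simConfig(
    n_sites = 1200, chrom_length_bp = 5e6, recomb_rate = 2,
    sources = data.frame(label = c("P1", "P2"), F = c(0.2, 0.2),
                         pool_size = c(100, 100), sample_n = c(60, 60)),
    weights = c(0.5, 0.5), T_gen = 30, admixed_sample_n = 60,
    n_genes = 5, seed = 53))
  d <- dateAdmixtureLD(sim$panel, "P1", "P1", "P2", sim$map,
                       d_range = c(0.5, 9), n_boot = 0)
  expect_true(d$flagged)
})

test_that("single-pulse dating recovers the admixture time", {
  sims <- lapply(1:4, function(i) simulateDataset(simConfig(
    n_sites = 2500, chrom_length_bp = 5e6, recomb_rate = 2,
    sources = data.frame(label = c("P1", "P2"), F = c(0.2, 0.2),
                         pool_size = c(300, 300), sample_n = c(100, 100)),
    weights = c(0.5, 0.5), T_gen = 30, admixed_sample_n = 100,
    n_genes = 5, seed = 590 + i)))
  d <- dateAdmixtureLD(lapply(sims, `[[`, "panel"), "ADM", "P1", "P2",
                       lapply(sims, `[[`, "map"), d_range = c(0.5, 9),
                       n_boot = 20, seed = 1)
  expect_false(d$flagged)
  expect_lt(abs(d$T - 30) / 30, 0.3)
})
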