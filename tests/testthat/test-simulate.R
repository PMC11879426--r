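test_that("source frequency draws follow the Balding-Nichols structure", {
  cfg <- tinySimConfig(11, n_sites = 10000)
  a1 <- drawSourceAFs(cfg)
  a2 <- drawSourceAFs(cfg)
  expect_identical(a1, a2)                    # determinism contract
  # E[source AF] = ancestral p, checked as a regression through the origin
  for (k in 1:3) {
    expect_lt(mean(a1$sources[, k] - a1$anc), 0.01)
    expect_gt(cor(a1$sources[, k], a1$anc), 0.8)
  }
  # F -> 0 limit: source AFs collapse onto the ancestral draw
  cfg0 <- tinySimConfig(11, n_sites = 500)
  cfg0$sources$F <- rep(1e-6, 3)
  a0 <- drawSourceAFs(cfg0)
  expect_lt(max(abs(a0$sources[, 1] - a0$anc)), 0.02)
  cfgbad <- tinySimConfig(12)
  cfgbad$sources$F <- c(0, 0.1, 0.1)
  expect_error(drawSourceAFs(cfgbad))
})

test_that("a single-source mixture reproduces that source", {
  cfg <- simConfig(n_sites = 1500, chrom_length_bp = 1e6,
                   sources = data.frame(label = "SRC", F = 0.1,
                                        pool_size = 200, sample_n = 50),
                   weights = 1, T_gen = 30, admixed_sample_n = 50,
                   n_genes = 10, seed = 21)
  afs <- drawSourceAFs(cfg)
  sim <- simulateAdmixedHaplotypes(cfg, afs)
  expect_true(all(sim$truth$tracts$source == "SRC"))
  p_adm <- alleleFrequency(sim$panel, "ADM")
  expect_lt(mean(abs(p_adm - afs$sources[, 1])), 0.05)
})

test_that("ancestry tracts partition the chromosome and match weights", {
  cfg <- tinySimConfig(31, n_sites = 1000, chrom_length_bp = 5e6)
  sim <- simulateAdmixedHaplotypes(cfg, drawSourceAFs(cfg))
  tr <- sim$truth$tracts
  for (h in unique(tr$hap)[1:10]) {
    t1 <- tr[tr$hap == h, ]
    expect_equal(t1$start_bp[1], 1)
    expect_equal(t1$end_bp[nrow(t1)], cfg$chrom_length_bp)
    if (nrow(t1) > 1) {
      expect_true(all(t1$start_bp[-1] == t1$end_bp[-nrow(t1)] + 1))
      # merged: no two adjacent tracts share a source
      expect_true(all(t1$source[-1] != t1$source[-nrow(t1)]))
    }
  }
  # genome-wide ancestry fractions close to the admixture weights
  len <- tr$end_M - tr$start_M
  frac <- tapply(len, tr$source, sum) / sum(len)
  expect_lt(max(abs(frac[names(cfg$weights)] - cfg$weights)), 0.05)
})

test_that("tract lengths are exponential at rate T(1-w)", {
  # 4 Morgans of map: boundary-censoring bias on interior tracts is ~1%
  cfg <- simConfig(n_sites = 600, chrom_length_bp = 4e7, recomb_rate = 10,
                   sources = data.frame(label = c("P1", "P2"),
                                        F = c(0.1, 0.1),
                                        pool_size = c(60, 60),
                                        sample_n = c(10, 10)),
                   weights = c(0.5, 0.5), T_gen = 50,
                   admixed_sample_n = 30, n_genes = 5, seed = 41)
  sim <- simulateAdmixedHaplotypes(cfg, drawSourceAFs(cfg))
  tr <- sim$truth$tracts
  # drop boundary-censored first/last tracts of every haplotype
  interior <- do.call(rbind, lapply(split(tr, tr$hap), function(t1)
    if (nrow(t1) > 2) t1[2:(nrow(t1) - 1), ] else NULL))
  len <- interior$end_M - interior$start_M
  expect_gt(length(len), 2000)
  rate <- cfg$T_gen * (1 - 0.5)
  expect_lt(abs(mean(len) - 1 / rate) / (1 / rate), 0.10)
  ks <- suppressWarnings(ks.test(len, "pexp", rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("the genic-selection recursion has its fixed points and values", {
  expect_equal(selectionRecursion(0.3, 0, 100), 0.3)
  expect_equal(selectionRecursion(0.5, 0.05, 1), 0.5 * 1.05 / 1.025)
  # independent 170-step loop
  p <- 0.2
  for (i in 1:170) p <- p * 1.05 / (1 + 0.05 * p)
  expect_equal(selectionRecursion(0.2, 0.05, 170), p)
  expect_true(selectionRecursion(0.2, 0.05, 170) > 0.9)
})

test_that("sweep injection reaches the target frequency and records truth", {
  base <- tinySimConfig(51, n_sites = 2000, chrom_length_bp = 2e6)
  site <- chooseSweepSite(base, c(0.35, 0.6), 0.5)
  base$selected <- data.frame(site = site, s = NA, G = NA,
                              target_freq = 0.85, span_bp = 4e5)
  sim <- simulateDataset(base)
  sel <- sim$truth$selected
  expect_equal(nrow(sel), 1L)
  expect_gte(sel$realized_freq, 0.85)
  expect_equal(alleleFrequency(sim$panel, "ADM")[site], sel$realized_freq)
  # s = 0 with recursion target: panel unchanged
  neutral <- tinySimConfig(51, n_sites = 2000, chrom_length_bp = 2e6)
  neutral$selected <- data.frame(site = site, s = 0, G = 100,
                                 target_freq = NA, span_bp = 4e5)
  sim0 <- simulateDataset(neutral)
  plain <- tinySimConfig(51, n_sites = 2000, chrom_length_bp = 2e6)
  expect_identical(haploMatrix(sim0$panel),
                   haploMatrix(simulateDataset(plain)$panel))
})

test_that("a sweep with no carrier is an error", {
  cfg <- tinySimConfig(61, n_sites = 500)
  afs <- drawSourceAFs(cfg)
  sim <- simulateAdmixedHaplotypes(cfg, afs)
  cols <- hapColumns(sim$panel, "ADM")
  sim$panel@alleles[10, cols] <- 0L
  cfg$selected <- data.frame(site = 10, s = NA, G = NA,
                             target_freq = 0.5, span_bp = 1e5)
  expect_error(applyPostAdmixtureSelection(sim$panel, sim$truth, cfg),
               "no carrier")
})

test_that("neutral admixed frequencies obey the rules of admixture", {
  cfg <- tinySimConfig(71, n_sites = 5000)
  afs <- drawSourceAFs(cfg)
  sim <- simulateAdmixedHaplotypes(cfg, afs)
  p_exp <- as.vector(afs$sources %*% cfg$weights)
  p_obs <- alleleFrequency(sim$panel, "ADM")
  expect_lt(mean(abs(p_obs - p_exp)), 0.05)
  expect_lt(abs(mean(p_obs - p_exp)), 0.005)
})

test_that("two-wave histories compose sequentially", {
  cfg <- simConfig(n_sites = 800, chrom_length_bp = 2e7, recomb_rate = 1,
                   sources = data.frame(label = c("P1", "P2", "P3"),
                                        F = c(0.1, 0.1, 0.1),
                                        pool_size = c(60, 60, 60),
                                        sample_n = c(10, 10, 10)),
                   weights = c(0.4, 0.4, 0.2),
                   waves = list(
                     list(time = 150, weights = c(P1 = 0.5, P2 = 0.5),
                          fraction = 1),
                     list(time = 30, weights = c(P3 = 1), fraction = 0.2)),
                   admixed_sample_n = 60, n_genes = 5, seed = 81)
  sim <- simulateAdmixedHaplotypes(cfg, drawSourceAFs(cfg))
  tr <- sim$truth$tracts
  len <- tr$end_M - tr$start_M
  frac <- tapply(len, tr$source, sum) / sum(len)
  expect_equal(unname(frac["P3"]), 0.2, tolerance = 0.25)
  expect_equal(unname(frac["P1"]), 0.4, tolerance = 0.2)
  # wave ordering is validated
  expect_error(AdmixtureSpec(c("a", "b"), c(0.5, 0.5), waves = list(
    list(time = 10, weights = c(a = 1), fraction = 1),
    list(time = 50, weights = c(b = 1), fraction = 0.5))),
    "oldest")
})

test_that("the full reference-scale dataset generates quickly", {
  cfg <- simConfig(n_sites = 20000, chrom_length_bp = 5e6,
                   sources = data.frame(label = c("EUR", "SAS", "EAS"),
                                        F = c(0.08, 0.08, 0.10),
                                        pool_size = c(300, 300, 300),
                                        sample_n = c(50, 50, 50)),
                   admixed_sample_n = 100, seed = 91)
  el <- system.time(sim <- simulateDataset(cfg))[["elapsed"]]
  expect_lt(el, 120)
  expect_equal(nVariants(sim$panel), 20000L)
  expect_equal(nHaplotypes(sim$panel), 2L * (100 + 3 * 50))
})
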