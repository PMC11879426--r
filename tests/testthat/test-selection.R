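test_that("EHH is 1 for identical carriers and 0 once all differ", {
  # the four carriers of allele 1 at the core share one haplotype
  al2 <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0),
               c(0, 0, 0, 0, 1, 0, 1, 0),
               c(1, 1, 1, 1, 0, 0, 1, 0))
  p2 <- makePanel(al2, rep("P", 4))
  d2 <- ehhDecay(p2, "P", 2, 0, flatMap(p2))  # allele-0 carriers: cols 1-4,6,8
  d2 <- ehhDecay(p2[, ], "P", 1, 1, flatMap(p2))
  expect_true(all(d2$ehh == 1))
  # haplotypes: site1 all carry the core allele, then they split apart
  hap4 <- cbind(c(1, 1, 0), c(1, 1, 1), c(1, 0, 0), c(1, 0, 1))
  p3 <- makePanel(hap4, rep("P", 2))
  d3 <- ehhDecay(p3, "P", 1, 1, flatMap(p3))
  expect_equal(d3$ehh[d3$direction == "right"],
               c(2 / 6, 0))   # groups (2,2) then all four distinct -> 0
  expect_error(ehhDecay(p3, "P", 1, 0, flatMap(p3)),
               "carriers")
})

test_that("EHH decay equals all-pairs brute force on a toy panel", {
  set.seed(101)
  al <- matrix(rbinom(15 * 16, 1, 0.5), 15, 16)
  al[8, ] <- rep(c(1, 0), each = 8)
  p <- makePanel(al, rep("P", 8))
  m <- flatMap(p)
  d <- ehhDecay(p, "P", 8, 1, m, cutoff = 0)
  carriers <- which(al[8, ] == 1)
  for (r in seq_len(nrow(d)))
    expect_equal(d$ehh[r], ehhBrute(al, 8, carriers, d$site[r]))
  # non-increasing away from the core in each direction
  for (dir in c("left", "right")) {
    e <- d$ehh[d$direction == dir]
    if (length(e) > 1) expect_true(all(diff(e) <= 0))
  }
})

test_that("iHH integrates the trapezoid over genetic distance", {
  # core first site (no left side), EHH 1 -> 0.5 over 0.1 cM
  al <- rbind(c(1, 1, 1, 1, 0, 0),
              c(0, 0, 1, 1, 1, 0))
  p <- makePanel(al, rep("P", 3), pos = c(1000, 101000))
  m <- uniformGeneticMap("chr1", 2e5, 1)   # 0.1 cM between the sites
  d <- ehhDecay(p, "P", 1, 1, m)
  # carriers 1-4; at site 2 groups (2,2) -> EHH = 2/6
  expect_equal(attr(d, "ihh"), 0.5 * (1 + 2 / 6) * 0.1)
  # the printed arithmetic case: EHH (1, 0.5) over 0.1 cM -> 0.075
  # (a (3,1) split of the 4 carriers leaves 3 of 6 pairs identical)
  al2 <- rbind(c(1, 1, 1, 1, 0, 0),
               c(1, 1, 1, 0, 0, 0))
  p2 <- makePanel(al2, rep("P", 3), pos = c(1000, 101000))
  d2 <- ehhDecay(p2, "P", 1, 1, m)
  expect_equal(d2$ehh, 0.5)                 # groups (2,2) of 4 carriers
  expect_equal(attr(d2, "ihh"), 0.075)
})

test_that("a mirror-symmetric panel has zero unstandardized iHS", {
  blockD <- rbind(c(1, 1, 0, 0),
                  c(1, 0, 1, 0),
                  c(1, 1, 1, 1))
  blockA <- blockD                       # identical internal structure
  al <- cbind(blockD, blockA)
  al[2, ] <- c(1, 1, 1, 1, 0, 0, 0, 0)   # core: derived = cols 1-4
  p <- makePanel(al, rep("P", 4), pos = c(1000, 2000, 3000))
  ih <- ihsScan(p, "P", flatMap(p), maf_min = 0, min_bin = 1)
  expect_equal(ih$uihs[2], 0)
})

test_that("standardized iHS has mean 0 and sd 1 within every bin", {
  sim <- simulateDataset(tinySimConfig(107, n_sites = 4000,
                                       chrom_length_bp = 4e6))
  ih <- ihsScan(sim$panel, "ADM", sim$map)
  ok <- ih[ih$valid, ]
  for (b in unique(ok$std_bin)) {
    expect_lt(abs(mean(ok$ihs[ok$std_bin == b])), 1e-9)
    expect_lt(abs(sd(ok$ihs[ok$std_bin == b]) - 1), 1e-9)
    expect_gte(sum(ok$std_bin == b), 20)
  }
  # iHH is invariant under haplotype relabeling
  cols <- hapColumns(sim$panel, "ADM")
  perm <- sim$panel
  set.seed(1)
  shuffled_samples <- sample(which(unname(popOf(sim$panel)) == "ADM"))
  reord <- c(rbind(2 * shuffled_samples - 1, 2 * shuffled_samples))
  perm@alleles[, cols] <- perm@alleles[, reord]
  ih2 <- ihsScan(perm, "ADM", sim$map)
  expect_equal(ih2$ihh_der, ih$ihh_der)
  expect_equal(ih2$ihh_anc, ih$ihh_anc)
})

test_that("XP-EHH is zero for identical populations, standardized overall", {
  set.seed(11)
  half <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12)
  p <- makePanel(cbind(half, half), rep(c("T", "R"), each = 6))
  x <- xpehhScan(p, "T", "R", flatMap(p))
  expect_equal(x$uxpehh[x$valid], rep(0, sum(x$valid)))
  expect_error(xpehhScan(p, "T", "T", flatMap(p)), "differ")
  sim <- simulateDataset(tinySimConfig(109, n_sites = 1500))
  xs <- xpehhScan(sim$panel, "ADM", "EUR", sim$map)
  expect_lt(abs(mean(xs$xpehh[xs$valid])), 1e-9)
  expect_lt(abs(sd(xs$xpehh[xs$valid]) - 1), 1e-9)
})

test_that("a homogenized target shows positive XP-EHH", {
  set.seed(13)
  n <- 41
  ref <- matrix(rbinom(n * 20, 1, 0.5), n, 20)
  tgt <- matrix(rep(rbinom(n, 1, 0.5), 20), n, 20)   # one fixed haplotype
  p <- makePanel(cbind(tgt, ref), rep(c("T", "R"), each = 10))
  x <- xpehhScan(p, "T", "R", flatMap(p))
  mid <- 15:25
  expect_true(all(x$uxpehh[mid] > 0))
})

test_that("Weir-Cockerham components match the ANOVA oracle", {
  set.seed(19)
  for (rep in 1:8) {
    g1 <- sample(0:2, 3, replace = TRUE)
    g2 <- sample(0:2, 3, replace = TRUE)
    if (all(c(g1, g2) == 0) || all(c(g1, g2) == 2)) next
    hap <- function(g) do.call(cbind, lapply(g, function(x)
      if (x == 0) c(0L, 0L) else if (x == 2) c(1L, 1L) else c(1L, 0L)))
    al <- matrix(c(hap(g1), hap(g2)), nrow = 1)
    p <- makePanel(al, rep(c("A", "B"), each = 3))
    f <- fstScan(p, "A", "B")
    o <- wcAnovaOracle(g1, g2)
    expect_equal(f$a, o$a)
    expect_equal(f$b, o$b)
    expect_equal(f$c, o$c)
    if (o$a + o$b + o$c != 0) expect_equal(f$fst, o$fst)
  }
})

test_that("FST hits its boundary cases", {
  # fixed difference -> theta = 1
  al <- rbind(c(rep(1L, 6), rep(0L, 6)))
  p <- makePanel(al, rep(c("A", "B"), each = 3))
  f <- fstScan(p, "A", "B")
  expect_equal(f$fst, 1)
  # equal frequencies, equal sizes -> theta <= 0, reported as computed
  al2 <- rbind(rep(c(1L, 0L), 6))
  f2 <- fstScan(makePanel(al2, rep(c("A", "B"), each = 3)), "A", "B")
  expect_lte(f2$fst, 0)
  # monomorphic-everywhere sites flagged invalid
  al3 <- rbind(rep(0L, 12), c(rep(1L, 6), rep(0L, 6)))
  f3 <- fstScan(makePanel(al3, rep(c("A", "B"), each = 3)), "A", "B")
  expect_false(f3$valid[1])
  expect_true(f3$valid[2])
  expect_error(fstScan(p, "A", "A"), "overlap")
})

test_that("windowed FST is the ratio of summed components", {
  sim <- simulateDataset(tinySimConfig(113, n_sites = 400))
  f <- fstScan(sim$panel, "ADM", "EUR")
  w <- genomeWindows("chr1", 1e6, 250000, 250000)
  fw <- fstWindows(f, w, "chr1")
  pos <- f$pos
  for (i in seq_along(w)) {
    idx <- which(pos >= start(w)[i] & pos <= end(w)[i] & f$valid)
    if (length(idx))
      expect_equal(fw$fst[i],
                   sum(f$a[idx]) / sum(f$a[idx] + f$b[idx] + f$c[idx]))
  }
  # a fixed difference attains the window maximum per-site FST
  al <- matrix(rbinom(20 * 12, 1, 0.5), 20, 12)
  al[10, ] <- c(rep(1L, 6), rep(0L, 6))
  pf <- fstScan(makePanel(al, rep(c("A", "B"), each = 3)), "A", "B")
  expect_equal(which.max(pf$fst), 10L)
})

test_that("pairwise LD follows the haplotype-count definitions", {
  # two complementary haplotypes: complete LD
  al <- rbind(c(1, 1, 0, 0, 1, 0),
              c(0, 0, 1, 1, 0, 1))
  p <- makePanel(al, rep("P", 3))
  ld <- pairwiseLD(p, "P", 1, 2)
  expect_equal(ld$r2, 1)
  expect_equal(ld$d_prime, 1)
  # D = 0 -> r2 = 0 and D' = 0
  al2 <- rbind(c(1, 1, 0, 0),
               c(1, 0, 1, 0))
  ld2 <- pairwiseLD(makePanel(al2, rep("P", 2)), "P", 1, 2)
  expect_equal(ld2$d, 0)
  expect_equal(ld2$r2, 0)
  expect_equal(ld2$d_prime, 0)
  # independently shuffled alleles: r2 near zero
  set.seed(23)
  alr <- rbind(sample(rep(0:1, 100)), sample(rep(0:1, 100)))
  ldr <- pairwiseLD(makePanel(alr, rep("P", 100)), "P", 1, 2)
  expect_lt(ldr$r2, 0.05)
  al3 <- rbind(c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_error(pairwiseLD(makePanel(al3, rep("P", 2)), "P", 1, 2),
               "monomorphic")
})
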