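#' Extended haplotype homozygosity decay from a core allele
#'
#' EHH at a marker x is the fraction of carrier pairs identical at every
#' SNP from the core through x (EHH at the core itself is 1). The walk in
#' each direction stops when EHH falls below `cutoff`, at the chromosome
#' end, or when the gap between adjacent SNPs exceeds `max_gap_bp`.
#'
#' @param panel a [HaplotypePanel-class]
#' @param population population label
#' @param core_site variant index of the core SNP
#' @param core_allele 0 or 1; carriers are haplotypes with this allele
#' @param map a [GeneticMap-class]
#' @param cutoff EHH stopping threshold (default 0.05)
#' @param max_gap_bp maximum tolerated inter-SNP gap (default 200 kb)
#' @return data.frame: `direction` ("left"/"right"), `site`, `pos`, `cm`,
#'   `ehh`; attribute `ihh` carries the two-sided integral
#' @export
ehhDecay <- function(panel, population, core_site, core_allele, map,
                     cutoff = 0.05, max_gap_bp = 2e5) {
  cols <- hapColumns(panel, population)
  X <- haploMatrix(panel)
  carriers <- cols[X[core_site, cols] == core_allele]
  if (length(carriers) < 2) stop("< 2 carriers of the core allele")
  v <- variantInfo(panel)
  pos <- start(v)
  cm <- mapDistance(map, as.character(seqnames(v))[core_site], pos)
  r <- cpp_ehh_decay(X, core_site, carriers - 1L, cm, pos, cutoff,
                     max_gap_bp)
  ls <- r$left_sites + 1L
  rs <- r$right_sites + 1L
  out <- data.frame(
    direction = c(rep("left", length(ls)), rep("right", length(rs))),
    site = c(ls, rs), pos = pos[c(ls, rs)], cm = cm[c(ls, rs)],
    ehh = c(r$left_ehh, r$right_ehh))
  attr(out, "ihh") <- r$ihh
  attr(out, "truncated") <- r$truncated
  out
}

# Standardize x within bins of freq (equal-width on [0,1]); bins with fewer
# than min_bin members are merged with their left neighbour (the first bin
# merges right).  Returns the standardized values.
standardizeByBin <- function(x, freq, n_bins = 50, min_bin = 20) {
  z <- rep(NA_real_, length(x))
  grp0 <- rep(NA_integer_, length(x))
  ok <- which(!is.na(x))
  if (!length(ok)) return(list(z = z, group = grp0))
  b <- pmin(n_bins, pmax(1L, ceiling(freq[ok] * n_bins)))
  occupied <- sort(unique(b))
  cnt <- table(factor(b, levels = occupied))
  groups <- list()
  cur <- integer()
  cur_n <- 0
  for (bb in occupied) {
    cur <- c(cur, bb)
    cur_n <- cur_n + cnt[[as.character(bb)]]
    if (cur_n >= min_bin) {
      groups[[length(groups) + 1L]] <- cur
      cur <- integer(); cur_n <- 0
    }
  }
  if (cur_n > 0) {
    if (length(groups))
      groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
    else groups[[1L]] <- cur
  }
  grp <- rep(NA_integer_, length(x))
  for (gi in seq_along(groups)) {
    s <- ok[b %in% groups[[gi]]]
    grp[s] <- gi
    mu <- mean(x[s])
    sdv <- sd(x[s])
    z[s] <- if (length(s) > 1L && !is.na(sdv) && sdv > 0)
      (x[s] - mu) / sdv else 0
  }
  list(z = z, group = grp)
}

#' Integrated haplotype score (iHS) scan
#'
#' Per derived-polarized site, integrates EHH over genetic distance in both
#' directions separately for ancestral- and derived-allele carriers
#' (trapezoidal rule), forms ln(iHH_anc / iHH_der), and standardizes the
#' ratio within derived-allele-frequency bins so the score has mean 0 and
#' sd 1 in each retained bin. Sites with unknown ancestral allele, minor
#' allele frequency below `maf_min`, fewer than two carriers of either
#' allele, or a walk truncated by the chromosome end are flagged invalid.
#'
#' @param panel a [HaplotypePanel-class]
#' @param population population label
#' @param map a [GeneticMap-class]
#' @param maf_min minor-AF threshold (default 0.05)
#' @param cutoff,max_gap_bp walk controls, as in [ehhDecay()]
#' @param n_bins,min_bin standardization bins (defaults 50 equal-width bins,
#'   bins under 20 SNPs merged with a neighbour)
#' @return data.frame: `site`, `pos`, `daf`, `ihh_anc`, `ihh_der`,
#'   `uihs` (unstandardized ln-ratio), `ihs`, `valid`
#' @export
ihsScan <- function(panel, population, map, maf_min = 0.05, cutoff = 0.05,
                    max_gap_bp = 2e5, n_bins = 50, min_bin = 20) {
  cols <- hapColumns(panel, population)
  X <- haploMatrix(panel)[, cols, drop = FALSE]
  v <- variantInfo(panel)
  anc <- mcols(v)$anc
  der <- ifelse(is.na(anc), NA_integer_,
                ifelse(anc == mcols(v)$ref, 1L, 0L))
  pos <- start(v)
  cm <- mapDistance(map, as.character(seqnames(v))[1], pos)
  p_alt <- rowMeans(X)
  daf <- ifelse(der == 1L, p_alt, 1 - p_alt)
  maf <- pmin(p_alt, 1 - p_alt)
  use <- der
  use[is.na(der) | maf < maf_min] <- NA_integer_
  r <- cpp_ihs_all(X, use, cm, pos, cutoff, max_gap_bp)
  uihs <- log(r$ihh_anc / r$ihh_der)
  valid <- !is.na(uihs) & is.finite(uihs) & !r$truncated
  std <- standardizeByBin(ifelse(valid, uihs, NA_real_), daf,
                          n_bins, min_bin)
  data.frame(site = seq_len(nVariants(panel)), pos = pos, daf = daf,
             ihh_anc = r$ihh_anc, ihh_der = r$ihh_der, uihs = uihs,
             ihs = std$z, std_bin = std$group,
             valid = valid & !is.na(std$z))
}

#' Cross-population EHH (XP-EHH) scan
#'
#' Per site, integrates the pooled-allele EHH (homozygosity over all
#' haplotypes of a population, anchored at the core site) in target and
#' reference; the walk is truncated where EHH has fallen below `cutoff` in
#' both populations, so both integrals cover the same interval. The
#' unstandardized score ln(iHH_target / iHH_ref) is standardized
#' genome-wide over valid sites; positive values indicate longer
#' homozygosity (more recent sweep) in the target.
#'
#' @param panel a [HaplotypePanel-class]
#' @param target_pop,ref_pop distinct population labels
#' @param map a [GeneticMap-class]
#' @param cutoff,max_gap_bp walk controls
#' @return data.frame: `site`, `pos`, `ihh_target`, `ihh_ref`, `uxpehh`,
#'   `xpehh`, `valid`
#' @export
xpehhScan <- function(panel, target_pop, ref_pop, map, cutoff = 0.05,
                      max_gap_bp = 2e5) {
  if (identical(target_pop, ref_pop))
    stop("target and reference populations must differ")
  Xt <- haploMatrix(panel)[, hapColumns(panel, target_pop), drop = FALSE]
  Xr <- haploMatrix(panel)[, hapColumns(panel, ref_pop), drop = FALSE]
  v <- variantInfo(panel)
  pos <- start(v)
  cm <- mapDistance(map, as.character(seqnames(v))[1], pos)
  r <- cpp_xpehh_all(Xt, Xr, cm, pos, cutoff, max_gap_bp)
  u <- log(r$ihh_target / r$ihh_ref)
  valid <- is.finite(u)
  z <- rep(NA_real_, length(u))
  if (sum(valid) > 1) {
    mu <- mean(u[valid])
    sdv <- sd(u[valid])
    z[valid] <- (u[valid] - mu) / sdv
  }
  data.frame(site = seq_len(nVariants(panel)), pos = pos,
             ihh_target = r$ihh_target, ihh_ref = r$ihh_ref,
             uxpehh = u, xpehh = z, valid = valid & !is.na(z))
}

# Weir-Cockerham (1984) two-population variance components per site.
# Returns a list of vectors a, b, c.
wcComponents <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Per-site Weir-Cockerham FST between two populations
#'
#' The 1984 two-population estimator theta-hat = a/(a+b+c) from the
#' variance components with sample-size correction; heterozygote
#' frequencies come from the sample genotypes (pairs of phased haplotypes).
#' Sites monomorphic across both populations are flagged invalid; negative
#' estimates are reported as computed.
#'
#' @param panel a [HaplotypePanel-class]
#' @param popA,popB distinct population labels (>= 2 samples each)
#' @return data.frame: `site`, `pos`, `a`, `b`, `c`, `fst`, `valid`
#' @export
fstScan <- function(panel, popA, popB) {
  ia <- which(unname(popOf(panel)) == popA)
  ib <- which(unname(popOf(panel)) == popB)
  if (length(intersect(ia, ib))) stop("populations overlap")
  if (length(ia) < 2 || length(ib) < 2) stop("need >= 2 samples per pop")
  X <- haploMatrix(panel)
  gA1 <- X[, 2L * ia - 1L, drop = FALSE]; gA2 <- X[, 2L * ia, drop = FALSE]
  gB1 <- X[, 2L * ib - 1L, drop = FALSE]; gB2 <- X[, 2L * ib, drop = FALSE]
  p1 <- rowMeans(cbind(gA1, gA2))
  p2 <- rowMeans(cbind(gB1, gB2))
  h1 <- rowMeans(gA1 != gA2)
  h2 <- rowMeans(gB1 != gB2)
  comp <- wcComponents(p1, p2, h1, h2, length(ia), length(ib))
  denom <- comp$a + comp$b + comp$c
  valid <- !(p1 %in% c(0, 1) & p2 == p1)
  fst <- ifelse(denom != 0, comp$a / denom, NA_real_)
  data.frame(site = seq_len(nVariants(panel)),
             pos = start(variantInfo(panel)),
             a = comp$a, b = comp$b, c = comp$c, fst = fst,
             valid = valid & !is.na(fst))
}

#' Multi-SNP FST as a ratio of summed variance components
#'
#' @param fst output of [fstScan()]
#' @param windows GRanges of windows
#' @param chrom chromosome of the scanned sites
#' @return data.frame per window: `start`, `end`, `n_sites`, `fst`
#' @export
fstWindows <- function(fst, windows, chrom) {
  sites <- GRanges(chrom, IRanges(fst$pos, width = 1L))
  ov <- findOverlaps(sites, windows)
  out <- data.frame(start = start(windows), end = end(windows),
                    n_sites = 0L, fst = NA_real_)
  for (w in unique(subjectHits(ov))) {
    idx <- queryHits(ov)[subjectHits(ov) == w]
    idx <- idx[fst$valid[idx]]
    out$n_sites[w] <- length(idx)
    if (length(idx))
      out$fst[w] <- sum(fst$a[idx]) /
        sum(fst$a[idx] + fst$b[idx] + fst$c[idx])
  }
  out
}

#' Pairwise linkage disequilibrium between two sites
#'
#' From phased haplotype counts: D = p_AB - p_A p_B,
#' r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B)), D' = D / D_max with the standard
#' sign-dependent D_max.
#'
#' @param panel a [HaplotypePanel-class]
#' @param population population label
#' @param site_i,site_j variant indices (both polymorphic in the
#'   population)
#' @return list(r2, d_prime, d)
#' @export
pairwiseLD <- function(panel, population, site_i, site_j) {
  cols <- hapColumns(panel, population)
  X <- haploMatrix(panel)
  x <- X[site_i, cols]
  y <- X[site_j, cols]
  pA <- mean(x)
  pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic site in population")
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (D == 0) 0 else D / dmax
  list(r2 = r2, d_prime = abs(dp), d = D)
}
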