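#' Allele frequency expected under the admixture proportions
#'
#' Under neutrality the allele frequency of an admixed population is the
#' average of the source frequencies weighted by the global ancestry
#' proportions: p_exp = sum_k w_k p_k.
#'
#' @param source_afs matrix (sites x sources) of source allele frequencies,
#'   columns named by source label, or a list of vectors named by label
#' @param spec an [AdmixtureSpec-class]
#' @return numeric vector of expected frequencies
#' @export
expectedAF <- function(source_afs, spec) {
  if (is.list(source_afs) && !is.matrix(source_afs))
    source_afs <- do.call(cbind, source_afs)
  miss <- setdiff(specSources(spec), colnames(source_afs))
  if (length(miss))
    stop("no AF vector for source(s): ", paste(miss, collapse = ", "))
  w <- specWeights(spec)
  as.vector(source_afs[, specSources(spec), drop = FALSE] %*% w)
}

# Shared deviation z-test: observed frequency vs admixture expectation.
# V = p_exp(1-p_exp)/(2 n_t) + sum_k w_k^2 p_k(1-p_k)/(2 n_k) [+ drift]
# The archaic segment enrichment test reuses this code path.
deviationZ <- function(p_obs, p_exp, n_t, w, p_k, n_k, drift_opts = NULL) {
  V <- p_exp * (1 - p_exp) / (2 * n_t)
  if (!is.null(p_k)) {
    for (k in seq_along(w)) {
      if (is.finite(n_k[k]))
        V <- V + w[k]^2 * p_k[, k] * (1 - p_k[, k]) / (2 * n_k[k])
    }
  }
  if (!is.null(drift_opts))
    V <- V + p_exp * (1 - p_exp) * drift_opts$G / (2 * drift_opts$Ne)
  z <- ifelse(V > 0, (p_obs - p_exp) / sqrt(V), 0)
  # boundary convention: no variance and no deviation -> z = 0 (handled
  # above); no variance but a deviation -> fall back on the observed-
  # frequency binomial term so the site is not silently dropped
  bad <- V == 0 & p_obs != p_exp
  if (any(bad)) {
    Vb <- p_obs[bad] * (1 - p_obs[bad]) / (2 * n_t)
    z[bad] <- ifelse(Vb > 0, (p_obs[bad] - p_exp[bad]) / sqrt(Vb), Inf)
  }
  z
}

#' Scan for allele frequencies deviating from the admixture expectation
#'
#' Per site computes AFd_e = |p_obs - p_exp| for the target population
#' against the weighted source expectation, with a z-test whose variance
#' combines the binomial sampling of the target and source panels and an
#' optional drift-style term p_exp(1-p_exp) G/(2 Ne) (`drift_opts =
#' list(G=, Ne=)`). Sites monomorphic in every panel are flagged invalid.
#'
#' @param panel a [HaplotypePanel-class] containing target and sources
#' @param target_pop target population label
#' @param spec an [AdmixtureSpec-class]; source labels must be populations
#'   of the panel
#' @param alpha significance level in (0,1) (default 0.001)
#' @param drift_opts optional list(G, Ne); see [matchedDriftOpts()]
#' @param basis `"alt"` or `"derived"` frequency basis
#' @return data.frame: `site`, `chrom`, `pos`, `p_obs`, `p_exp`, `afde`,
#'   `z`, `p_value`, `significant`, `valid`
#' @export
afdeScan <- function(panel, target_pop, spec, alpha = 0.001,
                     drift_opts = NULL, basis = "alt") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  srcs <- specSources(spec)
  w <- specWeights(spec)
  p_obs <- alleleFrequency(panel, target_pop, basis)
  p_k <- do.call(cbind, lapply(srcs, function(s)
    alleleFrequency(panel, s, basis)))
  colnames(p_k) <- srcs
  n_k <- vapply(srcs, function(s) sum(unname(popOf(panel)) == s),
                numeric(1))
  n_t <- sum(unname(popOf(panel)) == target_pop)
  if (n_t < 2 || any(n_k < 2)) stop("target and sources need >= 2 samples")
  p_exp <- as.vector(p_k %*% w)
  valid <- !(p_obs %in% c(0, 1) & apply(p_k, 1L, function(r)
    all(r %in% c(0, 1))) & p_exp == p_obs)
  valid[is.na(p_obs)] <- FALSE
  z <- deviationZ(p_obs, p_exp, n_t, w, p_k, n_k, drift_opts)
  pv <- 2 * pnorm(-abs(z))
  v <- variantInfo(panel)
  data.frame(site = seq_len(nVariants(panel)),
             chrom = as.character(seqnames(v)), pos = start(v),
             p_obs = p_obs, p_exp = p_exp, afde = abs(p_obs - p_exp),
             z = z, p_value = pv,
             significant = valid & pv < alpha, valid = valid)
}

#' Rank genes by their proportion of significant-AFd_e SNVs
#'
#' Each valid SNV is assigned to the genes whose (flank-extended) interval
#' contains it; genes are ranked descending by the proportion of contained
#' SNVs with a significant AFd_e, ties broken by the significant count and
#' then by gene id. Genes containing no SNV are excluded.
#'
#' @param afde output of [afdeScan()]
#' @param genes GRanges with mcols `gene_id`
#' @param flank bp added to both gene ends (default 0: gene body only)
#' @return data.frame: `gene_id`, `n_snvs`, `n_significant`, `proportion`,
#'   `rank` (dense)
#' @export
geneAfdeRanking <- function(afde, genes, flank = 0) {
  ok <- afde$valid
  sites <- GRanges(afde$chrom[ok], IRanges(afde$pos[ok], width = 1L))
  g <- genes
  if (flank > 0) {
    g <- GRanges(seqnames(genes),
                 IRanges(pmax(1, start(genes) - flank), end(genes) + flank))
    mcols(g)$gene_id <- mcols(genes)$gene_id
  }
  ov <- findOverlaps(sites, g)
  sig <- afde$significant[ok][queryHits(ov)]
  gi <- subjectHits(ov)
  n_snvs <- tabulate(gi, nbins = length(g))
  n_sig <- vapply(seq_along(g), function(i) 0, numeric(1))
  if (length(gi)) {
    agg <- tapply(sig, gi, sum)
    n_sig[as.integer(names(agg))] <- as.numeric(agg)
  }
  keep <- n_snvs > 0
  out <- data.frame(gene_id = mcols(g)$gene_id[keep],
                    n_snvs = n_snvs[keep], n_significant = n_sig[keep],
                    proportion = n_sig[keep] / n_snvs[keep])
  ord <- order(-out$proportion, -out$n_significant, out$gene_id)
  out <- out[ord, ]
  key <- paste(out$proportion, out$n_significant)
  out$rank <- cumsum(!duplicated(key))
  rownames(out) <- NULL
  out
}

#' Observed vs expected site frequency spectra
#'
#' Histograms the observed derived allele frequencies of the target and the
#' admixture-expected frequencies over identical bin edges on \[0,1\].
#' Only derived-polarized sites (known ancestral allele) enter; both counts
#' sum to the number of valid sites.
#'
#' @param panel a [HaplotypePanel-class]
#' @param target_pop target population label
#' @param expected_af expected frequencies on the *alt* basis, as from
#'   [expectedAF()] on alt-basis source frequencies
#' @param n_bins number of equal-width bins (>= 2)
#' @return list: `breaks`, `observed`, `expected` (counts), `n_sites`,
#'   `tv_distance` (total-variation distance between the two normalized
#'   spectra)
#' @export
observedVsExpectedSFS <- function(panel, target_pop, expected_af,
                                  n_bins = 20) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  p_obs <- alleleFrequency(panel, target_pop, basis = "derived")
  anc <- mcols(variantInfo(panel))$anc
  alt <- mcols(variantInfo(panel))$alt
  p_exp <- ifelse(is.na(anc), NA_real_,
                  ifelse(anc == alt, 1 - expected_af, expected_af))
  ok <- !is.na(p_obs) & !is.na(p_exp)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- function(x) tabulate(pmin(n_bins, findInterval(x, breaks,
                                                        rightmost.closed = TRUE,
                                                        all.inside = TRUE)),
                              nbins = n_bins)
  obs <- bin(p_obs[ok])
  exp_ <- bin(p_exp[ok])
  n <- sum(ok)
  list(breaks = breaks, observed = obs, expected = exp_,
       n_sites = n,
       tv_distance = if (n) 0.5 * sum(abs(obs / n - exp_ / n)) else NA_real_)
}

#' Weighted admixture-LD decay curve
#'
#' For SNP pairs binned by genetic distance, the statistic
#' w(d) = mean over pairs of u_i u_j D_ij, where u_i is the source allele
#' frequency difference at SNP i and D_ij the haplotype covariance between
#' the two SNPs in the target. Under a single admixture pulse T generations
#' ago the curve decays as exp(-T d) with d in Morgans.
#'
#' @param X haplotype matrix (sites x haplotypes) of the target
#' @param u per-site source frequency difference
#' @param cm genetic position (cM) per site
#' @param bin_cm distance bin width in cM
#' @param d_range genetic distance range (cM) considered
#' @param max_sites cap on sites used (evenly thinned beyond it)
#' @return data.frame per populated bin: `d` (bin midpoint, cM), `w`
#'   (mean u_i u_j D_ij), `n_pairs`
#' @export
weightedLdCurve <- function(X, u, cm, bin_cm = 0.5, d_range = c(0.5, 30),
                            max_sites = 3000) {
  n_sites <- nrow(X)
  sel <- seq_len(n_sites)
  if (n_sites > max_sites)
    sel <- unique(round(seq(1, n_sites, length.out = max_sites)))
  Xs <- X[sel, , drop = FALSE]
  us <- u[sel]
  cms <- cm[sel]
  n <- ncol(Xs)
  P <- rowMeans(Xs)
  D <- tcrossprod(Xs) / n - tcrossprod(P)
  W <- tcrossprod(us)
  dd <- abs(outer(cms, cms, "-"))
  ut <- upper.tri(dd)
  d <- dd[ut]
  keep <- d >= d_range[1] & d <= d_range[2]
  d <- d[keep]
  val <- (W * D)[ut][keep]
  br <- seq(d_range[1], d_range[2] + bin_cm, by = bin_cm)
  bi <- findInterval(d, br)
  agg_w <- tapply(val, bi, mean)
  agg_n <- tapply(val, bi, length)
  mids <- br[as.integer(names(agg_w))] + bin_cm / 2
  data.frame(d = mids, w = as.numeric(agg_w), n_pairs = as.numeric(agg_n))
}

# Per-unit LD curves for one chromosome: all pairs are computed, each pair
# assigned to the contiguous site block of its first member, giving
# resampling units that keep the full distance range.
ldUnitsOneChrom <- function(X, u, cm, bin_cm, d_range, max_sites, nb = 10L) {
  n_sites <- nrow(X)
  sel <- seq_len(n_sites)
  if (n_sites > max_sites)
    sel <- unique(round(seq(1, n_sites, length.out = max_sites)))
  Xs <- X[sel, , drop = FALSE]
  us <- u[sel]
  cms <- cm[sel]
  n <- ncol(Xs)
  P <- rowMeans(Xs)
  D <- tcrossprod(Xs) / n - tcrossprod(P)
  val_m <- tcrossprod(us) * D
  dd <- abs(outer(cms, cms, "-"))
  ut <- upper.tri(dd)
  blk <- cut(seq_along(sel), min(nb, max(2L, length(sel) %/% 50L)),
             labels = FALSE)
  blk_i <- matrix(blk, length(sel), length(sel))[ut]
  d <- dd[ut]
  val <- val_m[ut]
  keep <- d >= d_range[1] & d <= d_range[2]
  d <- d[keep]; val <- val[keep]; blk_i <- blk_i[keep]
  br <- seq(d_range[1], d_range[2] + bin_cm, by = bin_cm)
  bi <- findInterval(d, br)
  lapply(sort(unique(blk_i)), function(b) {
    s <- blk_i == b
    agg_w <- tapply(val[s], bi[s], mean)
    agg_n <- tapply(val[s], bi[s], length)
    data.frame(d = br[as.integer(names(agg_w))] + bin_cm / 2,
               w = as.numeric(agg_w), n_pairs = as.numeric(agg_n))
  })
}

# Fit a exp(-T d / 100) + c to a binned curve (d in cM).
fitLdDecay <- function(bins, min_pairs = 100) {
  bins <- bins[bins$n_pairs >= min_pairs, ]
  if (nrow(bins) < 5) stop("< 5 populated distance bins")
  c0 <- mean(tail(bins$w, max(2, nrow(bins) %/% 5)))
  pos <- bins$w - c0 > 0
  T0 <- 30
  if (sum(pos) >= 3) {
    fit0 <- lm(log(bins$w[pos] - c0) ~ bins$d[pos])
    sl <- -coef(fit0)[2] * 100
    if (is.finite(sl) && sl > 0) T0 <- min(max(sl, 1), 500)
  }
  a0 <- max(bins$w[1] - c0, 1e-8)
  fit <- try(minpack.lm::nlsLM(
    w ~ a * exp(-T * d / 100) + c, data = bins,
    start = list(a = a0, T = T0, c = c0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(T = NA_real_, amplitude = NA_real_, c = NA_real_,
                flagged = TRUE))
  cf <- coef(fit)
  flag <- cf[["a"]] <= 0 || cf[["T"]] <= 0 ||
    cf[["a"]] < 2 * sd(resid(fit))
  list(T = cf[["T"]], amplitude = cf[["a"]], c = cf[["c"]], flagged = flag)
}

#' Date a single admixture pulse from weighted LD decay
#'
#' Computes the weighted admixture-LD curve (see [weightedLdCurve()]) with
#' SNP weights u_i = p_src1,i - p_src2,i estimated from the two source
#' panels, pools bins across replicate chromosomes/panels, and fits
#' a exp(-T d/100) + c by nonlinear least squares (the affine term absorbs
#' background LD). The returned confidence interval is a bootstrap over
#' chromosomes (or over contiguous site blocks when only one chromosome is
#' supplied).
#'
#' @param panels a [HaplotypePanel-class] or list of panels (replicate
#'   chromosomes), each containing the three populations
#' @param target_pop admixed target label
#' @param src1,src2 the two source population labels
#' @param maps a [GeneticMap-class] or list matching `panels`
#' @param bin_cm distance bin width (cM)
#' @param d_range fitted genetic distance range (cM)
#' @param max_sites per-panel cap on sites used
#' @param min_pairs minimum pairs per bin entering the fit
#' @param n_boot bootstrap replicates for the CI
#' @param seed RNG seed for the bootstrap
#' @return list: `T` (generations), `amplitude`, `c`, `ci` (2.5/97.5
#'   percentiles for T), `flagged` (TRUE when no admixture-LD signal is
#'   identifiable), `bins`
#' @export
dateAdmixtureLD <- function(panels, target_pop, src1, src2, maps,
                            bin_cm = 0.5, d_range = c(0.5, 30),
                            max_sites = 3000, min_pairs = 100,
                            n_boot = 100, seed = 1) {
  if (is(panels, "HaplotypePanel")) panels <- list(panels)
  if (is(maps, "GeneticMap")) maps <- list(maps)
  units <- list()
  for (i in seq_along(panels)) {
    pn <- panels[[i]]
    u <- alleleFrequency(pn, src1) - alleleFrequency(pn, src2)
    X <- haploMatrix(pn)[, hapColumns(pn, target_pop), drop = FALSE]
    ch <- as.character(seqnames(variantInfo(pn)))[1]
    cm <- mapDistance(maps[[min(i, length(maps))]], ch,
                      start(variantInfo(pn)))
    if (length(panels) > 1L) {
      units[[length(units) + 1L]] <-
        weightedLdCurve(X, u, cm, bin_cm, d_range, max_sites)
    } else {
      units <- c(units,
                 ldUnitsOneChrom(X, u, cm, bin_cm, d_range, max_sites))
    }
  }
  pool <- function(idx) {
    all <- do.call(rbind, units[idx])
    agg_w <- tapply(all$w * all$n_pairs, all$d, sum)
    agg_n <- tapply(all$n_pairs, all$d, sum)
    data.frame(d = as.numeric(names(agg_w)),
               w = as.numeric(agg_w) / as.numeric(agg_n),
               n_pairs = as.numeric(agg_n))
  }
  fit <- fitLdDecay(pool(seq_along(units)), min_pairs)
  ci <- c(NA_real_, NA_real_)
  if (!fit$flagged && n_boot > 0 && length(units) > 1L) {
    set.seed(seed)
    Tb <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample(seq_along(units), length(units), replace = TRUE)
      fb <- try(fitLdDecay(pool(idx), min_pairs), silent = TRUE)
      if (!inherits(fb, "try-error") && !fb$flagged) Tb[b] <- fb$T
    }
    ci <- unname(quantile(Tb, c(0.025, 0.975), na.rm = TRUE))
  }
  c(fit, list(ci = ci, bins = pool(seq_along(units))))
}
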