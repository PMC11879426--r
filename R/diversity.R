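tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed diversity statistics for one population
#'
#' Per sliding window, over sites segregating in the population: nucleotide
#' diversity theta_pi = sum 2p(1-p) n/(n-1) (per kb of window span),
#' Watterson's theta_W = S / a_{n-1} (per kb), Tajima's D from the standard
#' constants, whole-window haplotype diversity
#' H = n/(n-1) (1 - sum f_h^2) over exact haplotype-string identity, and
#' the proportion of segregating sites with minor allele frequency < 0.05.
#' Tajima's D is `NA` (undefined) when fewer than 3 sites segregate.
#'
#' @param panel a [HaplotypePanel-class]
#' @param population population label (>= 2 haplotypes)
#' @param windows GRanges of windows (see [genomeWindows()])
#' @param rare_af minor-AF threshold defining "rare" (default 0.05)
#' @return data.frame, one row per window: `chrom`, `start`, `end`,
#'   `n_sites`, `theta_pi_kb`, `theta_w_kb`, `tajima_d`, `hap_diversity`,
#'   `rare_prop`
#' @export
windowDiversity <- function(panel, population, windows, rare_af = 0.05) {
  cols <- hapColumns(panel, population)
  if (length(cols) < 2L) stop("need >= 2 haplotypes")
  X <- haploMatrix(panel)[, cols, drop = FALSE]
  n <- ncol(X)
  p <- rowMeans(X)
  seg <- p > 0 & p < 1
  cons <- tajimaConstants(n)
  ov <- findOverlaps(variantInfo(panel), windows)
  by_win <- split(queryHits(ov), subjectHits(ov))
  out <- data.frame(
    chrom = as.character(seqnames(windows)),
    start = start(windows), end = end(windows),
    n_sites = 0L, theta_pi_kb = NA_real_, theta_w_kb = NA_real_,
    tajima_d = NA_real_, hap_diversity = NA_real_, rare_prop = NA_real_)
  for (wi in names(by_win)) {
    w <- as.integer(wi)
    idx <- by_win[[wi]]
    sidx <- idx[seg[idx]]
    S <- length(sidx)
    kb <- (end(windows)[w] - start(windows)[w] + 1) / 1000
    out$n_sites[w] <- length(idx)
    pi_raw <- if (S) sum(2 * p[sidx] * (1 - p[sidx])) * n / (n - 1) else 0
    out$theta_pi_kb[w] <- pi_raw / kb
    out$theta_w_kb[w] <- (S / cons$a1) / kb
    if (S >= 3) {
      denom <- sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
      # n = 2 degenerates the variance constants to 0: D stays undefined
      out$tajima_d[w] <- if (is.finite(denom) && denom > 0)
        (pi_raw - S / cons$a1) / denom else NA_real_
    }
    hap_str <- apply(X[idx, , drop = FALSE], 2L, paste, collapse = "")
    f <- table(hap_str) / n
    out$hap_diversity[w] <- n / (n - 1) * (1 - sum(f^2))
    out$rare_prop[w] <- if (S) mean(pmin(p[sidx], 1 - p[sidx]) < rare_af)
                        else NA_real_
  }
  out
}

#' Per-sample heterozygosity and inbreeding coefficient
#'
#' Over the sites polymorphic in the population: observed heterozygosity is
#' the fraction at which the sample's two haplotypes differ; expected
#' heterozygosity is the mean of 2p(1-p) over the same sites; F-hat is
#' 1 - observed/expected.
#'
#' @param panel a [HaplotypePanel-class]
#' @param population population label
#' @return data.frame: `sample`, `obs_het`, `exp_het`, `f_hat`
#' @export
sampleHeterozygosity <- function(panel, population) {
  cols <- hapColumns(panel, population)
  X <- haploMatrix(panel)[, cols, drop = FALSE]
  p <- rowMeans(X)
  poly <- which(p > 0 & p < 1)
  sidx <- which(unname(popOf(panel)) == population)
  out <- data.frame(sample = sampleIds(panel)[sidx],
                    obs_het = NA_real_, exp_het = NA_real_, f_hat = NA_real_)
  if (!length(poly)) return(out)
  eh <- mean(2 * p[poly] * (1 - p[poly]))
  for (i in seq_along(sidx)) {
    h1 <- X[poly, 2L * i - 1L]
    h2 <- X[poly, 2L * i]
    out$obs_het[i] <- mean(h1 != h2)
    out$exp_het[i] <- eh
    out$f_hat[i] <- 1 - out$obs_het[i] / eh
  }
  out
}

#' Runs of homozygosity
#'
#' Per sample and chromosome, finds maximal runs of consecutive SNPs such
#' that every sliding block of `window_snps` SNPs inside the run contains at
#' most `het_allowance` heterozygous sites. Runs spanning less than
#' `min_length_bp` are discarded; retained segments are classed `short`
#' (< 2 Mb), `intermediate` (2-10 Mb) or `long` (> 10 Mb). Defaults are
#' PLINK-like conventions.
#'
#' @param panel a [HaplotypePanel-class]
#' @param min_length_bp minimum segment span (default 500 kb)
#' @param het_allowance heterozygote allowance per block (default 1)
#' @param window_snps block size in SNPs (default 50, must be >= 2)
#' @return data.frame: `sample`, `chrom`, `start`, `end`, `length_bp`,
#'   `class`
#' @export
detectROH <- function(panel, min_length_bp = 5e5, het_allowance = 1,
                      window_snps = 50) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  v <- variantInfo(panel)
  X <- haploMatrix(panel)
  res <- list()
  for (ch in unique(as.character(seqnames(v)))) {
    vi <- which(as.character(seqnames(v)) == ch)
    pos <- start(v)[vi]
    for (i in seq_len(nSamples(panel))) {
      het <- X[vi, 2L * i - 1L] != X[vi, 2L * i]
      m <- length(het)
      if (m < window_snps) next
      # rolling het count for block starts 1..(m-window_snps+1)
      cs <- c(0, cumsum(het))
      nblk <- m - window_snps + 1L
      blk <- cs[window_snps + seq_len(nblk)] - cs[seq_len(nblk)]
      good <- blk <= het_allowance
      r <- rle(good)
      ends_rle <- cumsum(r$lengths)
      starts_rle <- ends_rle - r$lengths + 1L
      for (j in which(r$values)) {
        a <- starts_rle[j]
        b <- ends_rle[j] + window_snps - 1L
        len <- pos[b] - pos[a] + 1
        if (len < min_length_bp) next
        res[[length(res) + 1L]] <- data.frame(
          sample = sampleIds(panel)[i], chrom = ch,
          start = pos[a], end = pos[b], length_bp = len)
      }
    }
  }
  if (!length(res))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      length_bp = numeric(), class = character()))
  out <- do.call(rbind, res)
  out$class <- cut(out$length_bp, c(-Inf, 2e6 - 1e-9, 10e6, Inf),
                   labels = c("short", "intermediate", "long"))
  out$class <- as.character(out$class)
  rownames(out) <- NULL
  out
}
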