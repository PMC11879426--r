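#' Assemble the per-site statistic table feeding the composite score
#'
#' Merges the outputs of [afdeScan()], [ihsScan()], [xpehhScan()] and
#' [fstScan()] on the shared site index, orienting every statistic so that
#' larger values are more selection-like in the target: AFd_e itself, |iHS|,
#' signed XP-EHH (target-polarized) and FST. Invalid sites contribute `NA`.
#'
#' @param afde,ihs,xpehh,fst the four scan tables (any may be `NULL`)
#' @return data.frame: `site`, `pos`, plus one column per statistic
#' @export
buildSiteStats <- function(afde = NULL, ihs = NULL, xpehh = NULL,
                           fst = NULL) {
  tabs <- list(afde = afde, ihs = ihs, xpehh = xpehh, fst = fst)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (!length(tabs)) stop("no statistic tables supplied")
  n <- vapply(tabs, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop("statistic tables do not share the site index")
  base <- tabs[[1]]
  for (tb in tabs)
    if (!identical(tb$site, base$site))
      stop("statistic tables do not share the site index")
  out <- data.frame(site = base$site, pos = base$pos)
  if (!is.null(afde))
    out$afde <- ifelse(afde$valid, afde$afde, NA_real_)
  if (!is.null(ihs))
    out$abs_ihs <- ifelse(ihs$valid, abs(ihs$ihs), NA_real_)
  if (!is.null(xpehh))
    out$xpehh <- ifelse(xpehh$valid, xpehh$xpehh, NA_real_)
  if (!is.null(fst))
    out$fst <- ifelse(fst$valid, fst$fst, NA_real_)
  out
}

#' Composite-of-multiple-signals (CMS) score per SNP
#'
#' For each statistic s, the empirical rank fraction of site i is
#' r_is = rank_i / (N_s + 1) over the N_s valid sites (average ranks for
#' ties, ascending so that the most selection-like site has the largest
#' fraction). The composite is CMS_i = (4 / S_i) sum_s -ln(1 - r_is) over
#' the S_i statistics available at the site; sites with fewer than
#' `min_stats` available statistics are flagged invalid. Being rank-based,
#' the score is invariant under monotone transforms of the inputs.
#'
#' @param site_stats output of [buildSiteStats()]
#' @param min_stats minimum statistics required per site (default 3)
#' @return data.frame: `site`, `pos`, per-statistic rank fractions
#'   (`r_<name>`), `n_stats`, `cms`, `valid`
#' @export
cmsScan <- function(site_stats, min_stats = 3) {
  stat_cols <- setdiff(names(site_stats), c("site", "pos"))
  out <- data.frame(site = site_stats$site, pos = site_stats$pos)
  contrib <- matrix(NA_real_, nrow(site_stats), length(stat_cols),
                    dimnames = list(NULL, stat_cols))
  for (sc in stat_cols) {
    x <- site_stats[[sc]]
    okv <- !is.na(x)
    N <- sum(okv)
    r <- rep(NA_real_, length(x))
    if (N) r[okv] <- rank(x[okv], ties.method = "average") / (N + 1)
    out[[paste0("r_", sc)]] <- r
    contrib[, sc] <- -log(1 - r)
  }
  S <- rowSums(!is.na(contrib))
  cms <- ifelse(S > 0, 4 / S * rowSums(contrib, na.rm = TRUE), NA_real_)
  out$n_stats <- S
  out$cms <- cms
  out$valid <- S >= min_stats
  out
}

# Quantile bins of n_snps merged (left to right) so every bin holds at
# least min_bin_genes genes. Returns an integer bin id per gene.
snpCountBins <- function(n_snps, n_bins = 10, min_bin_genes = 30) {
  qs <- unique(quantile(n_snps, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 1))
  breaks <- unique(c(-Inf, qs[-1]))
  if (length(breaks) < 2) return(rep(1L, length(n_snps)))
  raw <- cut(n_snps, breaks = breaks, labels = FALSE)
  occupied <- sort(unique(raw))
  cnt <- table(factor(raw, levels = occupied))
  groups <- list()
  cur <- integer(); cur_n <- 0
  for (bb in occupied) {
    cur <- c(cur, bb)
    cur_n <- cur_n + cnt[[as.character(bb)]]
    if (cur_n >= min_bin_genes) {
      groups[[length(groups) + 1L]] <- cur
      cur <- integer(); cur_n <- 0
    }
  }
  if (cur_n > 0) {
    if (length(groups))
      groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
    else groups[[1L]] <- cur
  }
  g <- integer(length(raw))
  for (gi in seq_along(groups)) g[raw %in% groups[[gi]]] <- gi
  g
}

#' Gene-level MaxCMS with empirical p-values from SNP-count-matched nulls
#'
#' MaxCMS of a gene is the maximum CMS over its contained valid SNPs.
#' Genes are grouped into SNP-count bins (deciles of the n_snps
#' distribution by default, merged so each bin holds at least
#' `min_bin_genes` genes); the empirical p-value of gene g is
#' (1 + #\{genes in its bin with MaxCMS >= MaxCMS_g, excluding g\}) / bin
#' size, so the top gene of a 100-gene bin gets p = 1/100 and ties push p
#' towards 1. Genes are called significant at p < 0.05.
#'
#' @param cms output of [cmsScan()]
#' @param genes GRanges with mcols `gene_id`
#' @param chrom chromosome of the scanned sites
#' @param flank bp added to both gene ends (default 0)
#' @param n_bins target number of SNP-count bins (default 10: deciles)
#' @param min_bin_genes minimum genes per bin after merging (default 30)
#' @return data.frame: `gene_id`, `n_snps`, `max_cms`, `bin`, `p_value`,
#'   `significant`
#' @export
geneCmsPvalues <- function(cms, genes, chrom, flank = 0, n_bins = 10,
                           min_bin_genes = 30) {
  ok <- cms$valid & !is.na(cms$cms)
  sites <- GRanges(chrom, IRanges(cms$pos[ok], width = 1L))
  g <- genes
  if (flank > 0) {
    g <- GRanges(seqnames(genes),
                 IRanges(pmax(1, start(genes) - flank), end(genes) + flank))
    mcols(g)$gene_id <- mcols(genes)$gene_id
  }
  ov <- findOverlaps(sites, g)
  vals <- cms$cms[ok][queryHits(ov)]
  gi <- subjectHits(ov)
  n_snps <- tabulate(gi, nbins = length(g))
  mx <- rep(NA_real_, length(g))
  agg <- tapply(vals, gi, max)
  mx[as.integer(names(agg))] <- as.numeric(agg)
  keep <- n_snps > 0
  out <- data.frame(gene_id = mcols(g)$gene_id[keep],
                    n_snps = n_snps[keep], max_cms = mx[keep])
  if (nrow(out) < min_bin_genes) {
    warning("fewer genes than the minimum bin size; single-bin fallback")
    out$bin <- 1L
  } else {
    out$bin <- snpCountBins(out$n_snps, n_bins, min_bin_genes)
  }
  out$p_value <- NA_real_
  for (b in unique(out$bin)) {
    idx <- which(out$bin == b)
    B <- length(idx)
    m <- out$max_cms[idx]
    ge <- vapply(seq_along(idx), function(i) sum(m >= m[i]) - 1L, numeric(1))
    out$p_value[idx] <- (1 + ge) / B
  }
  out$significant <- out$p_value < 0.05
  rownames(out) <- NULL
  out
}
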