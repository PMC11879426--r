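#' Archaic-segment enrichment relative to the admixture expectation
#'
#' For each introgressed segment the expected archaic-haplotype frequency
#' in the admixed target is the admixture-weighted average of the source
#' frequencies, f_exp = sum_k w_k f_k; the deviation is tested with the
#' same z-test as [afdeScan()] (shared code path), using the target sample
#' size and, when `n_source` is given, the source panel sizes. A segment
#' is called enriched when f_obs > f_exp and p < alpha.
#'
#' @param segments data.frame with columns `segment_id`, `chrom`, `start`,
#'   `end`, `f_obs` (target archaic-haplotype frequency), one column per
#'   source label (source frequencies) and optionally `lineage`
#' @param spec an [AdmixtureSpec-class]
#' @param n_target diploid sample size behind `f_obs`
#' @param alpha significance level (default 0.05)
#' @param n_source optional named diploid sizes behind the source
#'   frequencies; omitted sources contribute no sampling variance
#' @return the input with `f_exp`, `deviation`, `z`, `p_value`, `enriched`
#'   appended
#' @export
archaicEnrichment <- function(segments, spec, n_target, alpha = 0.05,
                              n_source = NULL) {
  srcs <- specSources(spec)
  miss <- setdiff(srcs, names(segments))
  if (length(miss))
    stop("missing source frequency column(s): ",
         paste(miss, collapse = ", "))
  w <- specWeights(spec)
  f_k <- as.matrix(segments[, srcs, drop = FALSE])
  f_exp <- as.vector(f_k %*% w)
  n_k <- rep(Inf, length(srcs))
  names(n_k) <- srcs
  if (!is.null(n_source)) n_k[names(n_source)] <- unlist(n_source)
  z <- deviationZ(segments$f_obs, f_exp, n_target, w, f_k, n_k)
  # one-sided (upper) p: the question is enrichment above expectation
  pv <- pnorm(-z)
  segments$f_exp <- f_exp
  segments$deviation <- segments$f_obs - f_exp
  segments$z <- z
  segments$p_value <- pv
  segments$enriched <- segments$f_obs > f_exp & pv < alpha
  segments
}

#' Windowed U and Q95 adaptive-introgression statistics
#'
#' Per window over derived-polarized sites: U counts the sites whose
#' derived allele is rare in the outgroup (AF < `w`), common in the target
#' (AF > `x`) and carried by the archaic genome at dosage fraction `y`
#' (1.0 = homozygous derived; 0.5 matches heterozygous carriers). Q95 is
#' the 95th percentile (linear interpolation) of the target derived AF over
#' the window's sites passing the outgroup and archaic conditions alone.
#' Windows at or above the genome-wide `outlier_quantile` of both
#' statistics are flagged joint outliers.
#'
#' @param target,outgroup [HaplotypePanel-class]s over identical variants
#' @param target_pop,outgroup_pop population labels within each panel
#' @param archaic_dosage integer vector (0/1/2) of archaic derived-allele
#'   dosage per site
#' @param windows GRanges of (typically non-overlapping) windows
#' @param w,x,y thresholds (defaults 0.01, 0.20, 1.0)
#' @param outlier_quantile joint-outlier quantile (default 0.999)
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `u`, `q95`,
#'   `joint_outlier`
#' @export
uQ95Scan <- function(target, target_pop, outgroup, outgroup_pop,
                     archaic_dosage, windows, w = 0.01, x = 0.20, y = 1.0,
                     outlier_quantile = 0.999) {
  vt <- variantInfo(target)
  vo <- variantInfo(outgroup)
  if (!identical(start(vt), start(vo)))
    stop("target and outgroup panels must share variants")
  p_t <- alleleFrequency(target, target_pop, basis = "derived")
  p_o <- alleleFrequency(outgroup, outgroup_pop, basis = "derived")
  anc <- mcols(vt)$anc
  arc <- archaic_dosage / 2
  ok <- !is.na(p_t) & !is.na(p_o) & !is.na(arc)
  base <- ok & p_o < w & arc == y
  passU <- base & p_t > x
  ov <- findOverlaps(GRanges(seqnames(vt), IRanges(start(vt), width = 1L)),
                     windows)
  out <- data.frame(chrom = as.character(seqnames(windows)),
                    start = start(windows), end = end(windows),
                    n_sites = 0L, u = 0L, q95 = NA_real_,
                    joint_outlier = FALSE)
  for (wi in unique(subjectHits(ov))) {
    idx <- queryHits(ov)[subjectHits(ov) == wi]
    out$n_sites[wi] <- sum(ok[idx])
    out$u[wi] <- sum(passU[idx])
    qsites <- idx[base[idx]]
    if (length(qsites))
      out$q95[wi] <- unname(quantile(p_t[qsites], 0.95, type = 7))
  }
  thr_u <- quantile(out$u, outlier_quantile, type = 7)
  thr_q <- quantile(out$q95, outlier_quantile, type = 7, na.rm = TRUE)
  out$joint_outlier <- !is.na(out$q95) & out$u >= thr_u & out$u > 0 &
    out$q95 >= thr_q
  out
}
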