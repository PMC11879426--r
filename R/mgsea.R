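#' Weighted running-sum enrichment score of one gene set
#'
#' Over the gene list sorted descending by score, a member gene at position
#' i adds score_i^p / sum_{members} score^p to the running sum and a
#' non-member subtracts 1/(N - m); the enrichment score is the signed
#' maximum deviation from zero. With `weight_p = 0` this is the classic
#' Kolmogorov-Smirnov statistic; `weight_p = 1` (the default used by
#' [runMgsea()]) weights members by their scores.
#'
#' @param scores named numeric vector of non-negative gene scores (any
#'   order; sorted internally, ties kept in the order given)
#' @param members character vector of member gene ids
#' @param weight_p score weighting exponent (>= 0)
#' @return the enrichment score in \[-1, 1\]
#' @export
enrichmentScore <- function(scores, members, weight_p = 1) {
  if (any(scores < 0)) stop("scores must be >= 0")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% members
  m <- sum(hit)
  N <- length(s)
  if (!m || m == N) stop("set empty or equal to the universe after ranking")
  w <- s[hit]^weight_p
  if (sum(w) == 0) {
    if (weight_p > 0) stop("all member scores are zero")
    w <- rep(1, m)
  }
  inc <- numeric(N)
  inc[hit] <- w / sum(w)
  inc[!hit] <- -1 / (N - m)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Gene-set enrichment over a score-ranked gene list with permutation nulls
#'
#' For each gene set (intersected with the ranked universe; sets smaller
#' than `min_size` after intersection are dropped), the observed running-
#' sum enrichment score is compared with `B` null scores obtained by
#' drawing random same-size gene sets from the universe. The permutation
#' p-value is (1 + #\{ES_null >= ES_obs\}) / (B + 1) (one-sided for
#' enrichment; a two-sided variant on |ES| is available), with
#' Benjamini-Hochberg adjustment across sets and a normalized score
#' NES = ES / mean(positive null ES). Deterministic given `seed`.
#'
#' @param scores named numeric vector of non-negative gene scores (e.g.
#'   significant-AFd_e proportion or MaxCMS)
#' @param gene_sets named list of character vectors
#' @param B permutations (>= 100)
#' @param seed RNG seed (mandatory)
#' @param weight_p score weighting exponent
#' @param min_size minimum effective set size (default 5)
#' @param two_sided use |ES| for the permutation comparison
#' @return data.frame: `set`, `size`, `es`, `nes`, `p_value`, `q_value`
#' @export
runMgsea <- function(scores, gene_sets, B = 1000, seed, weight_p = 1,
                     min_size = 5, two_sided = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  if (B < 100) stop("B must be >= 100")
  if (!length(gene_sets)) stop("empty gene set collection")
  universe <- names(scores)
  eff <- lapply(gene_sets, function(s) intersect(s, universe))
  keep <- vapply(eff, length, integer(1)) >= min_size
  eff <- eff[keep]
  if (!length(eff)) stop("no gene set of size >= min_size in the universe")
  set.seed(seed)
  sizes <- vapply(eff, length, integer(1))
  out <- data.frame(set = names(eff), size = sizes, es = NA_real_,
                    nes = NA_real_, p_value = NA_real_)
  for (i in seq_along(eff)) {
    es <- enrichmentScore(scores, eff[[i]], weight_p)
    null <- vapply(seq_len(B), function(b)
      enrichmentScore(scores, sample(universe, sizes[i]), weight_p),
      numeric(1))
    if (two_sided) {
      p <- (1 + sum(abs(null) >= abs(es))) / (B + 1)
    } else {
      p <- (1 + sum(null >= es)) / (B + 1)
    }
    pos <- null[null > 0]
    out$es[i] <- es
    out$nes[i] <- if (length(pos)) es / mean(pos) else NA_real_
    out$p_value[i] <- p
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
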