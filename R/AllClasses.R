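#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits metadata
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx rbinom rbeta runif rpois rnorm pnorm quantile
#'   ks.test p.adjust sd var setNames complete.cases coef nls resid lm
#'   rmultinom
#' @importFrom utils read.table write.table head tail
#' @useDynLib admixscan, .registration = TRUE
NULL

#' HaplotypePanel: phased haplotypes with variant metadata
#'
#' The central container of the package: a matrix of phased 0/1 alleles
#' (rows = biallelic SNVs, columns = haplotypes, two consecutive columns per
#' sample) together with variant metadata held as a \code{GRanges} (mcols
#' \code{id}, \code{ref}, \code{alt}, \code{anc}; \code{anc} is
#' \code{NA_character_} when the ancestral allele is unknown) and a
#' sample-to-population assignment. Missing genotypes are not representable:
#' input with missing or unphased genotypes is rejected at load.
#'
#' @slot variants \code{GRanges}, one range of width 1 per SNV, sorted, no
#'   duplicated positions within a chromosome.
#' @slot alleles integer matrix in \{0,1\}; 1 codes the alternate allele.
#' @slot samples character vector of sample identifiers; haplotype columns
#'   \code{2i-1, 2i} belong to sample \code{i}.
#' @slot popOf named character vector, population label per sample.
#' @slot phased logical flag (always TRUE for panels built by this package).
#' @slot metadata list for provenance (load reports, simulation seeds).
#'
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(
    variants = "GRanges",
    alleles = "matrix",
    samples = "character",
    popOf = "character",
    phased = "logical",
    metadata = "list"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  al <- object@alleles
  if (nrow(al) != length(object@variants))
    msg <- c(msg, "nrow(alleles) must equal length(variants)")
  if (ncol(al) != 2L * length(object@samples))
    msg <- c(msg, "alleles must have two columns per sample")
  if (length(al) && !all(al %in% c(0L, 1L)))
    msg <- c(msg, "alleles must contain only 0/1 (missing data not permitted)")
  if (!identical(names(object@popOf), object@samples))
    msg <- c(msg, "popOf must be named by (and ordered as) samples")
  if (any(is.na(object@popOf)) || any(!nzchar(object@popOf)))
    msg <- c(msg, "every population label must be non-empty")
  mc <- mcols(object@variants)
  need <- c("id", "ref", "alt", "anc")
  if (!all(need %in% names(mc)))
    msg <- c(msg, "variants must carry mcols id, ref, alt, anc")
  v <- object@variants
  if (length(v) > 1L) {
    ord <- order(as.character(seqnames(v)), start(v))
    if (!identical(ord, seq_along(v)))
      msg <- c(msg, "variants must be sorted by (chrom, pos)")
    key <- paste(as.character(seqnames(v)), start(v))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos) not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param variants `GRanges` of width-1 SNV positions with mcols
#'   `id`, `ref`, `alt`, `anc` (use `NA` for unknown ancestral allele).
#' @param alleles 0/1 matrix, variants x haplotypes.
#' @param samples sample ids, one per pair of haplotype columns.
#' @param popOf population label per sample (recycled if length 1); may be
#'   a named vector in `samples` order or an unnamed vector.
#' @param phased logical; only phased panels are supported.
#' @param metadata optional provenance list.
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(variants, alleles, samples, popOf,
                           phased = TRUE, metadata = list()) {
  storage.mode(alleles) <- "integer"
  if (length(popOf) == 1L) popOf <- rep(popOf, length(samples))
  if (is.null(names(popOf))) names(popOf) <- samples
  popOf <- popOf[samples]
  new("HaplotypePanel", variants = variants, alleles = alleles,
      samples = samples, popOf = popOf, phased = phased, metadata = metadata)
}

#' @describeIn HaplotypePanel number of variants
#' @param x,object a `HaplotypePanel`
#' @export
nVariants <- function(x) length(x@variants)

#' @describeIn HaplotypePanel number of samples
#' @export
nSamples <- function(x) length(x@samples)

#' @describeIn HaplotypePanel number of haplotypes (2 per sample)
#' @export
nHaplotypes <- function(x) ncol(x@alleles)

#' @describeIn HaplotypePanel sample identifiers
#' @export
sampleIds <- function(x) x@samples

#' @describeIn HaplotypePanel named vector sample -> population
#' @export
popOf <- function(x) x@popOf

#' @describeIn HaplotypePanel unique population labels
#' @export
populations <- function(x) unique(unname(x@popOf))

#' @describeIn HaplotypePanel the 0/1 allele matrix
#' @export
haploMatrix <- function(x) x@alleles

#' @describeIn HaplotypePanel variant metadata as GRanges
#' @export
variantInfo <- function(x) x@variants

#' Haplotype column indices of a population
#'
#' @param x a `HaplotypePanel`
#' @param population a population label present in the panel
#' @return integer vector of columns of `haploMatrix(x)`
#' @export
hapColumns <- function(x, population) {
  if (!population %in% x@popOf)
    stop("unknown population label: ", population)
  idx <- which(unname(x@popOf) == population)
  sort(c(2L * idx - 1L, 2L * idx))
}

#' @describeIn HaplotypePanel provenance list (load report, seed)
#' @param ... ignored
#' @exportMethod metadata
setMethod("metadata", "HaplotypePanel", function(x, ...) x@metadata)

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nVariants(object), "variants x",
      nHaplotypes(object), "haplotypes (", nSamples(object), "samples )\n")
  tab <- table(object@popOf)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat("  phased:", object@phased, "\n")
})

setMethod("[", signature("HaplotypePanel", "ANY", "ANY"),
  function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nVariants(x))
    if (missing(j)) j <- seq_len(nSamples(x))
    if (is.character(j)) j <- match(j, x@samples)
    cols <- as.vector(rbind(2L * j - 1L, 2L * j))
    HaplotypePanel(x@variants[i], x@alleles[i, cols, drop = FALSE],
                   x@samples[j], x@popOf[j], x@phased, x@metadata)
  })

#' GeneticMap: physical-to-genetic coordinate interpolation
#'
#' Per-chromosome lookup table of physical position (bp, 1-based) against
#' cumulative genetic distance (cM). Queries interpolate linearly and
#' extrapolate with the boundary value beyond the table ends.
#'
#' @slot table data.frame with columns `chrom`, `pos`, `cm`.
#' @exportClass GeneticMap
setClass("GeneticMap", representation(table = "data.frame"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  if (!all(c("chrom", "pos", "cm") %in% names(tb)))
    return("table needs columns chrom, pos, cm")
  for (ch in unique(tb$chrom)) {
    s <- tb[tb$chrom == ch, ]
    if (is.unsorted(s$pos, strictly = TRUE))
      return(sprintf("positions on %s must be strictly increasing", ch))
    if (is.unsorted(s$cm))
      return(sprintf("cM on %s must be non-decreasing", ch))
  }
  TRUE
})

#' Construct a GeneticMap
#' @param chrom,pos,cm vectors of equal length (chromosome, bp, cumulative cM)
#' @return a [GeneticMap-class]
#' @export
GeneticMap <- function(chrom, pos, cm) {
  tb <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   cm = as.numeric(cm), stringsAsFactors = FALSE)
  tb <- tb[order(tb$chrom, tb$pos), ]
  rownames(tb) <- NULL
  new("GeneticMap", table = tb)
}

#' Uniform-rate genetic map over one chromosome
#' @param chrom chromosome name
#' @param length_bp chromosome length in bp
#' @param rate_cm_mb recombination rate in cM/Mb
#' @return a [GeneticMap-class]
#' @export
uniformGeneticMap <- function(chrom, length_bp, rate_cm_mb) {
  GeneticMap(chrom = c(chrom, chrom), pos = c(1, length_bp),
             cm = c(0, (length_bp - 1) / 1e6 * rate_cm_mb))
}

#' Genetic position (cM) of physical positions
#' @param map a [GeneticMap-class]
#' @param chrom chromosome name (scalar)
#' @param pos physical positions (bp)
#' @return numeric vector of cM
#' @export
mapDistance <- function(map, chrom, pos) {
  tb <- map@table[map@table$chrom == chrom, ]
  if (!nrow(tb)) stop("chromosome not covered by map: ", chrom)
  if (nrow(tb) == 1L) return(rep(tb$cm, length(pos)))
  approx(tb$pos, tb$cm, xout = pos, rule = 2)$y
}

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  cat("GeneticMap:", length(unique(tb$chrom)), "chromosome(s),",
      nrow(tb), "anchor points\n")
})

#' AdmixtureSpec: source populations and admixture proportions
#'
#' Labels and global ancestry proportions of the source populations of an
#' admixed target, optionally with admixture waves (time in generations ago
#' and the per-wave source contributions) for multi-pulse histories.
#'
#' @slot sources character vector of source labels.
#' @slot weights numeric ancestry proportions, summing to 1.
#' @slot waves list of waves, oldest first; each a list with elements
#'   `time` (generations ago), `weights` (named, the mixture among sources
#'   entering at that wave) and `fraction` (total proportion of the genome
#'   replaced at that wave; 1 for the founding wave).
#' @exportClass AdmixtureSpec
setClass("AdmixtureSpec",
  representation(sources = "character", weights = "numeric", waves = "list"))

setValidity("AdmixtureSpec", function(object) {
  w <- object@weights
  if (length(w) != length(object@sources))
    return("one weight per source required")
  if (any(w < 0)) return("weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 (+/- 1e-9)")
  if (length(object@waves)) {
    tms <- vapply(object@waves, `[[`, numeric(1), "time")
    if (any(tms <= 0)) return("wave times must be positive")
    if (is.unsorted(rev(tms))) return("waves must be sorted oldest -> newest")
  }
  TRUE
})

#' Construct an AdmixtureSpec
#' @param sources source population labels
#' @param weights global ancestry proportions (normalized if slightly off 1
#'   is *not* done silently: they must sum to 1 within 1e-9)
#' @param waves optional list of admixture waves, oldest first (see
#'   [AdmixtureSpec-class])
#' @return an [AdmixtureSpec-class]
#' @export
AdmixtureSpec <- function(sources, weights, waves = list()) {
  if (!is.null(names(weights)) && is.null(sources)) sources <- names(weights)
  new("AdmixtureSpec", sources = as.character(sources),
      weights = as.numeric(weights), waves = waves)
}

#' @describeIn AdmixtureSpec source labels
#' @param x an `AdmixtureSpec`
#' @export
specSources <- function(x) x@sources

#' @describeIn AdmixtureSpec named ancestry proportions
#' @export
specWeights <- function(x) setNames(x@weights, x@sources)

#' @describeIn AdmixtureSpec admixture waves (possibly empty list)
#' @export
specWaves <- function(x) x@waves

setMethod("show", "AdmixtureSpec", function(object) {
  cat("AdmixtureSpec:",
      paste(sprintf("%s=%.3f", object@sources, object@weights),
            collapse = ", "), "\n")
  if (length(object@waves))
    cat("  waves (oldest first):",
        paste(vapply(object@waves, function(w)
          sprintf("T=%g (fraction %.2f)", w$time, w$fraction),
          character(1)), collapse = "; "), "\n")
})
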