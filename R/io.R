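#' Read a phased VCF and sample map into a HaplotypePanel
#'
#' Loads phased biallelic SNVs for the samples listed in a two-column TSV
#' (`sample`, `population`). Multiallelic records, indels and records with
#' any missing genotype among the requested samples are dropped and counted
#' in the load report (`metadata(panel)$load_report`). The ancestral allele
#' is taken from the `AA` INFO tag when present and equal to REF or ALT;
#' otherwise it is recorded as unknown.
#'
#' @param vcf_path path to a VCF (optionally gzipped) with phased GT.
#' @param samples_tsv path to a TSV with header columns `sample`,
#'   `population`; every listed sample must be present in the VCF.
#' @return a [HaplotypePanel-class]
#' @export
readPanel <- function(vcf_path, samples_tsv) {
  smap <- read.table(samples_tsv, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(smap)))
    stop("sample map needs columns 'sample' and 'population'")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    gr0 <- GRanges()
    mcols(gr0) <- S4Vectors::DataFrame(id = character(), ref = character(),
                                       alt = character(), anc = character())
    return(HaplotypePanel(gr0, matrix(0L, 0L, 2L * nrow(smap)),
                          smap$sample,
                          setNames(smap$population, smap$sample),
                          metadata = list(load_report = list(
                            n_kept = 0L, drop_multiallelic = 0L,
                            drop_indel = 0L, drop_missing = 0L,
                            drop_count = 0L))))
  }
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt_all <- v@gt
  vcf_samples <- colnames(gt_all)[-1]
  missing_samples <- setdiff(smap$sample, vcf_samples)
  if (length(missing_samples))
    stop("samples in TSV absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, smap$sample, drop = FALSE]

  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  n_indel <- sum(!snv & !multi)
  has_gt <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  complete <- rowSums(!has_gt) == 0L
  n_missing <- sum(snv & !complete)

  unph <- which(snv & complete & apply(gt, 1L, function(g)
    any(grepl("/", g, fixed = TRUE))))
  if (length(unph))
    stop(sprintf("unphased genotype at %s:%s",
                 fix$CHROM[unph[1]], fix$POS[unph[1]]))

  keep <- snv & complete
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  aa <- rep(NA_character_, nrow(fix))
  if (nrow(fix)) {
    info_aa <- sub(".*(?:^|;)AA=([^;]+).*", "\\1", fix$INFO)
    info_aa[!grepl("AA=", fix$INFO)] <- NA_character_
    aa <- ifelse(!is.na(info_aa) & (info_aa == fix$REF | info_aa == fix$ALT),
                 info_aa, NA_character_)
  }

  h1 <- substr(gt, 1L, 1L)
  h2 <- substr(gt, 3L, 3L)
  al <- matrix(0L, nrow(gt), 2L * ncol(gt))
  if (nrow(gt)) {
    al[, seq(1L, ncol(al), by = 2L)] <- as.integer(h1 != "0")
    al[, seq(2L, ncol(al), by = 2L)] <- as.integer(h2 != "0")
  }
  gr <- GRanges(fix$CHROM, IRanges(as.integer(fix$POS), width = 1L),
                id = ifelse(is.na(fix$ID), ".", fix$ID),
                ref = fix$REF, alt = fix$ALT, anc = aa)
  ord <- order(as.character(seqnames(gr)), start(gr))
  panel <- HaplotypePanel(
    gr[ord], al[ord, , drop = FALSE], smap$sample,
    setNames(smap$population, smap$sample),
    metadata = list(load_report = list(
      n_kept = sum(keep), drop_multiallelic = n_multi,
      drop_indel = n_indel, drop_missing = n_missing,
      drop_count = n_multi + n_indel + n_missing)))
  panel
}

#' Write a HaplotypePanel as a phased VCF 4.2 file
#'
#' Records are emitted sorted, with `0|1`-style phased GT and the `AA` INFO
#' tag where the ancestral allele is known. The file is plain text.
#'
#' @param panel a [HaplotypePanel-class]
#' @param vcf_path output path
#' @return `vcf_path`, invisibly
#' @export
writePanel <- function(panel, vcf_path) {
  v <- variantInfo(panel)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=admixscan",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(panel)), collapse = "\t"))
  con <- file(vcf_path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (length(v)) {
    al <- haploMatrix(panel)
    ns <- nSamples(panel)
    gts <- matrix("", nrow(al), ns)
    for (j in seq_len(ns))
      gts[, j] <- paste0(al[, 2L * j - 1L], "|", al[, 2L * j])
    info <- ifelse(is.na(mcols(v)$anc), ".", paste0("AA=", mcols(v)$anc))
    body <- paste(as.character(seqnames(v)), start(v), mcols(v)$id,
                  mcols(v)$ref, mcols(v)$alt, ".", "PASS", info, "GT",
                  apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(vcf_path)
}

#' Write the sample -> population map of a panel as TSV
#' @param panel a [HaplotypePanel-class]
#' @param path output path
#' @export
writeSampleMap <- function(panel, path) {
  write.table(data.frame(sample = sampleIds(panel),
                         population = unname(popOf(panel))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-site allele frequencies within a population
#'
#' @param panel a [HaplotypePanel-class]
#' @param population population label
#' @param basis `"alt"` (count the alternate allele) or `"derived"`
#'   (count the non-ancestral allele; sites with unknown ancestral allele
#'   return `NA`).
#' @return numeric vector in \[0,1\], one value per variant
#' @export
alleleFrequency <- function(panel, population, basis = c("alt", "derived")) {
  basis <- match.arg(basis)
  cols <- hapColumns(panel, population)
  p <- rowMeans(haploMatrix(panel)[, cols, drop = FALSE])
  if (basis == "derived") {
    anc <- mcols(variantInfo(panel))$anc
    alt <- mcols(variantInfo(panel))$alt
    p <- ifelse(is.na(anc), NA_real_, ifelse(anc == alt, 1 - p, p))
  }
  p
}

#' Built-in variant-prioritization rule sets
#'
#' `clinical_protective`: frequent in the target (`AF_target > 0.1`),
#' conserved (`gerp > 2`) and predicted deleterious (`cadd > 15`).
#' `lof_enriched`: frequent in the target (`AF_target > 0.1`) but rare in a
#' worldwide reference (`AF_reference < 0.1`).
#' @keywords internal
builtinRuleSets <- function() {
  list(
    clinical_protective = list(
      list(column = "AF_target", comparator = ">", threshold = 0.1),
      list(column = "gerp", comparator = ">", threshold = 2),
      list(column = "cadd", comparator = ">", threshold = 15)),
    lof_enriched = list(
      list(column = "AF_target", comparator = ">", threshold = 0.1),
      list(column = "AF_reference", comparator = "<", threshold = 0.1)))
}

#' Filter an annotation table by conjunctive threshold rules
#'
#' Keeps the rows satisfying every rule, preserving input order. `rules` is
#' either the name of a built-in rule set (`"clinical_protective"`,
#' `"lof_enriched"`) or a list of rules, each a list with `column`,
#' `comparator` (one of `>`, `>=`, `<`, `<=`, `==`) and `threshold`.
#'
#' @param annotation data.frame of variant annotations
#' @param rules rule-set name or list of rules
#' @return the filtered data.frame
#' @export
filterFunctionalVariants <- function(annotation, rules) {
  if (is.character(rules) && length(rules) == 1L) {
    sets <- builtinRuleSets()
    if (!rules %in% names(sets))
      stop("unknown rule set: ", rules, "; built-ins: ",
           paste(names(sets), collapse = ", "))
    rules <- sets[[rules]]
  }
  keep <- rep(TRUE, nrow(annotation))
  for (r in rules) {
    if (!r$column %in% names(annotation))
      stop(sprintf("column '%s' not in table; available: %s", r$column,
                   paste(names(annotation), collapse = ", ")))
    cmp <- match.fun(r$comparator)
    keep <- keep & cmp(annotation[[r$column]], r$threshold)
  }
  annotation[which(keep), , drop = FALSE]
}

#' Read gene models from BED
#'
#' BED (0-based half-open) is converted to GRanges by rtracklayer; the 4th
#' column becomes `gene_id`.
#' @param path BED file with at least 4 columns
#' @return GRanges with mcols `gene_id`
#' @export
readGenesBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr)$gene_id <- mcols(gr)$name
  mcols(gr) <- mcols(gr)["gene_id"]
  gr
}

#' Write gene models as BED
#' @param genes GRanges with mcols `gene_id`
#' @param path output path
#' @export
writeGenesBed <- function(genes, path) {
  gr <- genes
  mcols(gr)$name <- mcols(gr)$gene_id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a plink-style genetic map
#'
#' Accepts the 4-column plink `.map` layout (chrom, id, cM, bp) or a
#' 3-column (chrom, cM, bp) variant; columns are detected by type.
#' @param path map file (whitespace-separated, no header)
#' @return a [GeneticMap-class]
#' @export
readGeneticMap <- function(path) {
  tb <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tb) == 4L) {
    GeneticMap(tb[[1]], tb[[4]], tb[[3]])
  } else if (ncol(tb) == 3L) {
    GeneticMap(tb[[1]], tb[[3]], tb[[2]])
  } else stop("expected a 3- or 4-column plink-style map")
}

#' Write a GeneticMap in 4-column plink format
#' @param map a [GeneticMap-class]
#' @param path output path
#' @export
writeGeneticMap <- function(map, path) {
  tb <- map@table
  write.table(data.frame(tb$chrom, ".", tb$cm, as.integer(tb$pos)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file
#' @return named list of character vectors
#' @export
readGeneSets <- function(path) fgsea::gmtPathways(path)

#' Write gene sets as GMT
#' @param sets named list of character vectors
#' @param path output path
#' @export
writeGeneSets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Sliding windows over a chromosome
#'
#' @param chrom chromosome name
#' @param length_bp chromosome length
#' @param size window size in bp (> 0)
#' @param step step in bp (0 < step <= size); `step == size` gives
#'   non-overlapping windows
#' @return GRanges of windows
#' @export
genomeWindows <- function(chrom, length_bp, size = 50000, step = 25000) {
  stopifnot(size > 0, step > 0, step <= size)
  starts <- seq(1, max(1, length_bp), by = step)
  starts <- starts[starts <= length_bp]
  ends <- pmin(starts + size - 1, length_bp)
  keep <- !duplicated(ends) | (ends - starts + 1) == size
  GRanges(chrom, IRanges(starts[keep], ends[keep]))
}
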