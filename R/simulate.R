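#' Configuration for the synthetic admixed-genome generator
#'
#' The generator emulates the study design the package targets: divergent
#' source populations (Balding-Nichols allele frequencies around a shared
#' ancestral frequency), a recently admixed target population built as an
#' ancestry-tract mosaic copied from finite per-source template pools, and
#' optional post-admixture selective sweeps injected at chosen sites.
#' Defaults mirror a three-way continental-scale admixture: a West-Eurasian-
#' like major source, a South-Asian-like major source and an East-Asian-like
#' minor source with proportions 0.483/0.373/0.144, a single admixture pulse
#' 40 generations ago, 100 admixed diploids and 100 diploids per source.
#'
#' @param n_sites number of biallelic SNVs
#' @param chrom_length_bp chromosome length (bp)
#' @param recomb_rate uniform recombination rate, cM/Mb
#' @param sources data.frame with columns `label`, `F` (Balding-Nichols
#'   divergence in (0,1)), `pool_size` (template haplotypes backing the
#'   admixed mosaic), `sample_n` (diploid samples emitted per source)
#' @param weights global ancestry proportions, one per source (sum 1)
#' @param T_gen generations since the (single) admixture pulse; ignored if
#'   `waves` is given
#' @param waves optional list of waves, oldest first: each
#'   `list(time=, weights=named, fraction=)`; the first wave must have
#'   `fraction = 1`
#' @param admixed_sample_n diploid samples in the admixed target
#' @param target_label population label of the admixed target
#' @param selected data.frame of sweeps to inject, columns `site` (index),
#'   `s` (selection coefficient, > -1), `G` (generations of selection),
#'   `target_freq` (direct target frequency, `NA` to use the recursion),
#'   `span_bp` (hard-sweep haplotype-replacement span); may be empty
#' @param base_af_range range of the ancestral allele frequency draw
#' @param n_genes,gene_length gene models tiled over the chromosome
#' @param n_sets,set_size random gene sets emitted alongside one "spiked"
#'   set of genes overlapping injected sweeps
#' @param chrom chromosome name
#' @param seed mandatory RNG seed (integer)
#' @return a validated `SimConfig` list
#' @export
simConfig <- function(n_sites = 20000, chrom_length_bp = 5e6,
                      recomb_rate = 1.2,
                      sources = data.frame(
                        label = c("EUR", "SAS", "EAS"),
                        F = c(0.08, 0.08, 0.10),
                        pool_size = c(500, 500, 500),
                        sample_n = c(100, 100, 100)),
                      weights = c(0.483, 0.373, 0.144),
                      T_gen = 40, waves = NULL,
                      admixed_sample_n = 100, target_label = "ADM",
                      selected = NULL,
                      base_af_range = c(0.05, 0.95),
                      n_genes = 200, gene_length = 12000,
                      n_sets = 25, set_size = 15,
                      chrom = "chr1", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(sources$F > 0), all(sources$F < 1),
            all(sources$pool_size >= 2), all(sources$sample_n > 0),
            n_sites > 0, chrom_length_bp > n_sites, recomb_rate > 0,
            admixed_sample_n > 0)
  weights <- weights / sum(weights)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (is.null(waves))
    waves <- list(list(time = T_gen,
                       weights = setNames(weights, sources$label),
                       fraction = 1))
  if (waves[[1]]$fraction != 1)
    stop("the founding (oldest) wave must have fraction 1")
  if (is.null(selected))
    selected <- data.frame(site = integer(), s = numeric(), G = numeric(),
                           target_freq = numeric(), span_bp = numeric())
  if (nrow(selected) && any(selected$s <= -1, na.rm = TRUE))
    stop("selection coefficients must be > -1")
  structure(list(
    n_sites = as.integer(n_sites), chrom_length_bp = chrom_length_bp,
    recomb_rate = recomb_rate, sources = sources,
    weights = setNames(weights, sources$label), T_gen = T_gen,
    waves = waves, admixed_sample_n = as.integer(admixed_sample_n),
    target_label = target_label, selected = selected,
    base_af_range = base_af_range, n_genes = n_genes,
    gene_length = gene_length, n_sets = n_sets, set_size = set_size,
    chrom = chrom, seed = as.integer(seed)), class = "SimConfig")
}

#' AdmixtureSpec implied by a SimConfig
#' @param config a `SimConfig`
#' @return an [AdmixtureSpec-class]
#' @export
simAdmixtureSpec <- function(config) {
  AdmixtureSpec(config$sources$label, unname(config$weights),
                waves = if (length(config$waves) > 1L) config$waves
                        else list())
}

#' Draw ancestral and per-source allele frequencies
#'
#' Ancestral frequencies are Uniform over `base_af_range`; each source k
#' draws Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k) around the ancestral p
#' (the Balding-Nichols structure model). The ancestral allele is the REF
#' allele of the emitted panel, so frequencies refer to the derived (ALT)
#' allele throughout.
#'
#' @param config a `SimConfig`; seeds the RNG with `config$seed`
#' @return list with `anc` (numeric) and `sources`
#'   (matrix n_sites x n_sources, columns named by source label)
#' @export
drawSourceAFs <- function(config) {
  if (any(config$sources$F <= 0 | config$sources$F >= 1))
    stop("source divergence F must lie in (0, 1)")
  set.seed(config$seed)
  n <- config$n_sites
  p <- runif(n, config$base_af_range[1], config$base_af_range[2])
  K <- nrow(config$sources)
  src <- matrix(0, n, K, dimnames = list(NULL, config$sources$label))
  for (k in seq_len(K)) {
    Fk <- config$sources$F[k]
    src[, k] <- rbeta(n, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
  }
  src[src < 1e-4] <- 1e-4
  src[src > 1 - 1e-4] <- 1 - 1e-4
  list(anc = p, sources = src)
}

# Compose the per-haplotype ancestry mosaic across admixture waves.
# Returns a list(starts = Morgan positions (first 0), source = labels),
# adjacent same-source tracts merged.
composeWaves <- function(waves, L_M, labels) {
  wv <- vector("list", length(waves))
  for (j in seq_along(waves)) {
    w <- waves[[j]]
    nb <- rpois(1L, w$time * L_M)
    br <- c(0, sort(runif(nb, 0, L_M)))
    nseg <- length(br)
    pw <- w$weights[labels]
    pw[is.na(pw)] <- 0
    src <- sample(labels, nseg, replace = TRUE, prob = pw)
    repl <- if (j == 1L) rep(TRUE, nseg) else runif(nseg) < w$fraction
    wv[[j]] <- list(breaks = br, src = src, repl = repl)
  }
  u <- sort(unique(unlist(lapply(wv, `[[`, "breaks"))))
  mid <- u + c(diff(u), L_M - u[length(u)]) / 2
  src <- rep(NA_character_, length(u))
  for (j in rev(seq_along(wv))) {
    need <- is.na(src)
    if (!any(need)) break
    idx <- findInterval(mid[need], wv[[j]]$breaks)
    hit <- wv[[j]]$repl[idx]
    src[need][hit] <- wv[[j]]$src[idx][hit]
  }
  keep <- c(TRUE, src[-1] != src[-length(src)])
  list(starts = u[keep], source = src[keep])
}

#' Simulate an admixed haplotype panel with known truth
#'
#' Builds, per source, a pool of template haplotypes with alleles drawn
#' independently per site from the source frequencies; each admixed
#' haplotype is then an ancestry mosaic whose switch points follow a Poisson
#' process along the genetic map at rate T per Morgan (waves composed
#' sequentially, newest last), copying each tract from one uniformly chosen
#' template of the tract's source. Source population samples are emitted as
#' independent draws from the source frequencies. Truth records the tract
#' mosaic of every admixed haplotype.
#'
#' @param config a `SimConfig`; seeds the RNG with `config$seed + 1`
#' @param afs result of [drawSourceAFs()]
#' @return list with elements `panel` ([HaplotypePanel-class]), `truth`
#'   (class `SimTruth`: `anc_afs`, `source_afs`, `tracts`, `selected`,
#'   `config`) and `map` ([GeneticMap-class])
#' @export
simulateAdmixedHaplotypes <- function(config, afs) {
  set.seed(config$seed + 1L)
  n <- config$n_sites
  labels <- config$sources$label
  K <- length(labels)
  if (any(config$sources$pool_size < 2)) stop("pool smaller than 2")
  pos <- sort(sample.int(config$chrom_length_bp - 2L, n)) + 1L
  cm <- (pos - 1) / 1e6 * config$recomb_rate
  site_M <- cm / 100
  L_M <- config$chrom_length_bp / 1e6 * config$recomb_rate / 100

  pools <- vector("list", K)
  for (k in seq_len(K)) {
    M <- config$sources$pool_size[k]
    pools[[k]] <- matrix(rbinom(n * M, 1L, afs$sources[, k]), nrow = n)
  }

  n_adm_hap <- 2L * config$admixed_sample_n
  adm <- matrix(0L, n, n_adm_hap)
  tracts <- vector("list", n_adm_hap)
  for (h in seq_len(n_adm_hap)) {
    mo <- composeWaves(config$waves, L_M, labels)
    ntr <- length(mo$starts)
    tmpl <- integer(ntr)
    tr_idx <- findInterval(site_M, mo$starts)
    for (t in seq_len(ntr)) {
      k <- match(mo$source[t], labels)
      tmpl[t] <- sample.int(config$sources$pool_size[k], 1L)
      sel <- which(tr_idx == t)
      if (length(sel)) adm[sel, h] <- pools[[k]][sel, tmpl[t]]
    }
    bp_starts <- pmin(config$chrom_length_bp,
                      floor(mo$starts * 100 / config$recomb_rate * 1e6) + 1)
    tracts[[h]] <- data.frame(
      hap = h, start_bp = bp_starts,
      end_bp = c(bp_starts[-1] - 1, config$chrom_length_bp),
      start_M = mo$starts,
      end_M = c(mo$starts[-1], L_M),
      source = mo$source)
  }

  src_mats <- vector("list", K)
  for (k in seq_len(K)) {
    nh <- 2L * config$sources$sample_n[k]
    src_mats[[k]] <- matrix(rbinom(n * nh, 1L, afs$sources[, k]), nrow = n)
  }

  al <- cbind(adm, do.call(cbind, src_mats))
  samples <- c(sprintf("%s_%03d", config$target_label,
                       seq_len(config$admixed_sample_n)),
               unlist(lapply(seq_len(K), function(k)
                 sprintf("%s_%03d", labels[k],
                         seq_len(config$sources$sample_n[k])))))
  pops <- c(rep(config$target_label, config$admixed_sample_n),
            rep(labels, config$sources$sample_n))
  gr <- GRanges(config$chrom, IRanges(pos, width = 1L),
                id = sprintf("snv%06d", seq_len(n)),
                ref = "A", alt = "C", anc = "A")
  panel <- HaplotypePanel(gr, al, samples, setNames(pops, samples),
                          metadata = list(seed = config$seed))
  truth <- structure(list(
    anc_afs = afs$anc, source_afs = afs$sources,
    tracts = do.call(rbind, tracts),
    selected = data.frame(site = integer(), pos = integer(), s = numeric(),
                          G = numeric(), target_freq = numeric(),
                          realized_freq = numeric(), span_bp = numeric()),
    config = config), class = "SimTruth")
  list(panel = panel, truth = truth,
       map = uniformGeneticMap(config$chrom, config$chrom_length_bp,
                               config$recomb_rate))
}

#' Deterministic genic-selection frequency recursion
#'
#' Iterates p' = p(1+s)/(1+sp) for G generations.
#' @param p starting allele frequency
#' @param s selection coefficient (> -1)
#' @param G generations (non-negative integer)
#' @return the frequency after G generations
#' @export
selectionRecursion <- function(p, s, G) {
  for (g in seq_len(G)) p <- p * (1 + s) / (1 + s * p)
  p
}

#' Inject post-admixture hard sweeps into an admixed panel
#'
#' For each configured locus the target frequency is either given directly
#' (`target_freq`) or obtained from the genic-selection recursion applied to
#' the current admixed frequency. The sweep is realized by replacing the
#' local segment (of `span_bp` centered on the site) of randomly chosen
#' non-carrier haplotypes with a copy of one randomly chosen carrier
#' haplotype until the site frequency first reaches the target; this yields
#' both the frequency shift and the elevated haplotype homozygosity that
#' the downstream scans detect. Only the target population is modified.
#'
#' @param panel admixed [HaplotypePanel-class] (from
#'   [simulateAdmixedHaplotypes()])
#' @param truth the matching `SimTruth`
#' @param config a `SimConfig` with a non-empty `selected` table; seeds the
#'   RNG with `config$seed + 2`
#' @return list(panel, truth) with sweeps applied and truth extended
#' @export
applyPostAdmixtureSelection <- function(panel, truth, config) {
  if (!nrow(config$selected)) return(list(panel = panel, truth = truth))
  set.seed(config$seed + 2L)
  al <- haploMatrix(panel)
  pos <- start(variantInfo(panel))
  cols <- hapColumns(panel, config$target_label)
  sel_rows <- config$selected
  rec <- truth$selected
  for (i in seq_len(nrow(sel_rows))) {
    site <- sel_rows$site[i]
    s <- sel_rows$s[i]
    G <- sel_rows$G[i]
    span <- sel_rows$span_bp[i]
    p0 <- mean(al[site, cols])
    target <- if (!is.na(sel_rows$target_freq[i])) sel_rows$target_freq[i]
              else selectionRecursion(p0, s, G)
    if (target > p0 && p0 == 0)
      stop("target frequency unreachable: no carrier at site ", site)
    if (target > p0) {
      carriers <- cols[al[site, cols] == 1L]
      donor <- carriers[sample.int(length(carriers), 1L)]
      span_idx <- which(pos >= pos[site] - span / 2 & pos <= pos[site] + span / 2)
      need <- ceiling(target * length(cols)) - length(carriers)
      non <- cols[al[site, cols] == 0L]
      pick <- non[sample.int(length(non), min(need, length(non)))]
      al[span_idx, pick] <- al[span_idx, donor]
    }
    rec <- rbind(rec, data.frame(
      site = site, pos = pos[site], s = s, G = G, target_freq = target,
      realized_freq = mean(al[site, cols]), span_bp = span))
  }
  panel@alleles <- al
  validObject(panel)
  truth$selected <- rec
  list(panel = panel, truth = truth)
}

# Tile n_genes gene models of gene_length bp evenly over the chromosome.
tileGenes <- function(config) {
  n <- config$n_genes
  len <- config$gene_length
  starts <- floor(seq(1, config$chrom_length_bp - len, length.out = n))
  GRanges(config$chrom, IRanges(starts, width = len),
          gene_id = sprintf("gene%04d", seq_len(n)))
}

# Random gene sets plus one set spiked with sweep-overlapping genes.
makeGeneSets <- function(config, genes, truth) {
  set.seed(config$seed + 3L)
  ids <- mcols(genes)$gene_id
  sets <- lapply(seq_len(config$n_sets), function(i)
    sample(ids, min(config$set_size, length(ids))))
  names(sets) <- sprintf("random_set_%02d", seq_len(config$n_sets))
  if (nrow(truth$selected)) {
    sw <- GRanges(config$chrom,
                  IRanges(pmax(1, truth$selected$pos - truth$selected$span_bp / 2),
                          pmin(config$chrom_length_bp,
                               truth$selected$pos + truth$selected$span_bp / 2)))
    hit <- unique(ids[unique(queryHits(findOverlaps(genes, sw)))])
    pad <- setdiff(ids, hit)
    if (length(hit) < 5L)
      hit <- c(hit, sample(pad, 5L - length(hit)))
    sets$spiked_sweep_set <- hit
  }
  sets
}

#' Generate a complete synthetic dataset
#'
#' Runs [drawSourceAFs()], [simulateAdmixedHaplotypes()] and
#' [applyPostAdmixtureSelection()] under the config seed and attaches tiled
#' gene models and gene sets (one spiked with sweep-overlapping genes when
#' sweeps are configured).
#'
#' @param config a `SimConfig`
#' @return list(panel, truth, map, genes, geneSets, spec)
#' @export
simulateDataset <- function(config) {
  afs <- drawSourceAFs(config)
  sim <- simulateAdmixedHaplotypes(config, afs)
  sim <- c(applyPostAdmixtureSelection(sim$panel, sim$truth, config),
           list(map = sim$map))
  genes <- tileGenes(config)
  sets <- makeGeneSets(config, genes, sim$truth)
  list(panel = sim$panel, truth = sim$truth, map = sim$map,
       genes = genes, geneSets = sets, spec = simAdmixtureSpec(config))
}

#' Write a simulated dataset to disk
#'
#' Emits the panel VCF, sample TSV, plink-style genetic map, gene BED, GMT
#' gene sets and a truth JSON (config, seed, realized sweeps, tract count).
#'
#' @param sim result of [simulateDataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeSimDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePanel(sim$panel, file.path(dir, "panel.vcf"))
  writeSampleMap(sim$panel, file.path(dir, "samples.tsv"))
  writeGeneticMap(sim$map, file.path(dir, "genetic.map"))
  writeGenesBed(sim$genes, file.path(dir, "genes.bed"))
  writeGeneSets(sim$geneSets, file.path(dir, "gene_sets.gmt"))
  cfg <- sim$truth$config
  jsonlite::write_json(list(
    seed = cfg$seed,
    config = cfg[c("n_sites", "chrom_length_bp", "recomb_rate", "T_gen",
                   "admixed_sample_n", "target_label", "chrom")],
    weights = as.list(cfg$weights),
    selected = sim$truth$selected,
    n_tracts = nrow(sim$truth$tracts)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Choose a sweep site from a config's deterministic frequency draw
#'
#' Sweep injections reference a site index, but which sites are usefully
#' polymorphic depends on the (seed-deterministic) frequency draw. This
#' helper replays [drawSourceAFs()] for the config and returns the site
#' whose expected admixed frequency (weighted source average) lies inside
#' `af_range` and whose index is closest to `near_frac` of the chromosome.
#'
#' @param config a `SimConfig`
#' @param af_range admissible expected-frequency range
#' @param near_frac target relative position in (0,1)
#' @return a site index
#' @export
chooseSweepSite <- function(config, af_range = c(0.35, 0.6),
                            near_frac = 0.5) {
  afs <- drawSourceAFs(config)
  p_exp <- as.vector(afs$sources %*% config$weights)
  ok <- which(p_exp >= af_range[1] & p_exp <= af_range[2])
  if (!length(ok)) stop("no site with expected AF in range")
  ok[which.min(abs(ok - near_frac * config$n_sites))]
}

#' Matched drift-style variance options for [afdeScan()] on simulated data
#'
#' The admixed haplotypes of the generator copy alleles from finite template
#' pools; the pool-frequency fluctuation adds variance
#' sum_k w_k^2 p_k(1-p_k)/M_k on top of the sampling terms, exactly the role
#' of the drift term in the AFd_e z-test. This helper returns the (G, Ne)
#' pair whose drift term p(1-p) G/(2 Ne) matches that pool term, so the
#' generative null is calibrated.
#'
#' @param config a `SimConfig`
#' @return list(G = 1, Ne = ...) suitable for `drift_opts`
#' @export
matchedDriftOpts <- function(config) {
  rate <- sum(config$weights^2 / config$sources$pool_size)
  list(G = 1, Ne = 1 / (2 * rate))
}
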