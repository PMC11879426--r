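pipelineStages <- c("simulate", "diversity", "afde", "selection", "cms",
                    "mgsea", "date")

# Dependency closure over the stage graph.
stageClosure <- function(stages) {
  deps <- list(diversity = "simulate", afde = "simulate",
               selection = "simulate", cms = c("afde", "selection"),
               mgsea = "cms", date = "simulate")
  out <- stages
  repeat {
    add <- setdiff(unlist(deps[out]), out)
    if (!length(add)) break
    out <- c(out, add)
  }
  intersect(pipelineStages, out)
}

writeStage <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full admixture-aware selection analysis from one configuration
#'
#' Executes the requested stages in dependency order on a simulated dataset
#' (an `input` block pointing at VCF/TSV/map/BED/GMT files is also
#' accepted), writing one TSV per stage plus a JSON manifest carrying the
#' config hash, seed, package version and per-stage row counts. Stages are
#' resumable: an existing stage output is reused (and recorded as cached in
#' the manifest) unless `force = TRUE`. Reruns with an identical config and
#' seed into a fresh directory are bit-identical.
#'
#' @param config a list (or path to a YAML file) with components
#'   `seed` (mandatory), and either `simulate` (arguments for
#'   [simConfig()]) or `input` (paths: `vcf`, `samples`, `map`,
#'   `genes_bed`, `gene_sets_gmt`, plus `target`, `sources`, `weights`);
#'   optional `stages` (default: all) and `params` (per-stage options:
#'   `alpha`, `window_size`, `window_step`, `mgsea_B`, `flank`,
#'   `date_sources`)
#' @param out_dir output directory
#' @param force recompute stages whose outputs already exist
#' @return named list of stage result objects (invisibly includes the
#'   manifest)
#' @export
runPipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default

  stages <- stageClosure(if (!is.null(config$stages)) config$stages
                         else pipelineStages)
  cfg_file <- tempfile()
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   package = as.character(utils::packageVersion("admixscan")),
                   r_version = R.version.string, stages = list())
  results <- list()
  note <- function(stage, how, n) {
    manifest$stages[[stage]] <<- list(status = how, rows = n)
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
  }

  data_dir <- file.path(out_dir, "data")
  if ("simulate" %in% stages) {
    if (!is.null(config$input)) {
      inp <- config$input
      run("simulate", {
        panel <- readPanel(inp$vcf, inp$samples)
        sim <- list(panel = panel,
                    map = readGeneticMap(inp$map),
                    genes = readGenesBed(inp$genes_bed),
                    geneSets = readGeneSets(inp$gene_sets_gmt),
                    spec = AdmixtureSpec(inp$sources,
                                         unlist(inp$weights)),
                    truth = NULL)
        results$simulate <- sim
        note("simulate", "loaded", nVariants(panel))
      })
      target <- inp$target
      drift <- NULL
    } else {
      sc_args <- config$simulate
      sc_args$seed <- config$seed
      if (!is.null(sc_args$sources))
        sc_args$sources <- as.data.frame(sc_args$sources)
      if (!is.null(sc_args$selected))
        sc_args$selected <- as.data.frame(sc_args$selected)
      if (!is.null(sc_args$weights))
        sc_args$weights <- unlist(sc_args$weights)
      sc <- run("simulate", do.call(simConfig, sc_args))
      if (!force && file.exists(file.path(data_dir, "panel.vcf"))) {
        run("simulate", {
          results$simulate <- list(
            panel = readPanel(file.path(data_dir, "panel.vcf"),
                              file.path(data_dir, "samples.tsv")),
            map = readGeneticMap(file.path(data_dir, "genetic.map")),
            genes = readGenesBed(file.path(data_dir, "genes.bed")),
            geneSets = readGeneSets(file.path(data_dir, "gene_sets.gmt")),
            spec = simAdmixtureSpec(sc), truth = NULL)
          note("simulate", "cached", nVariants(results$simulate$panel))
        })
      } else {
        run("simulate", {
          results$simulate <- simulateDataset(sc)
          writeSimDataset(results$simulate, data_dir)
          note("simulate", "computed", nVariants(results$simulate$panel))
        })
      }
      target <- sc$target_label
      drift <- matchedDriftOpts(sc)
    }
  }
  sim <- results$simulate
  chrom <- as.character(seqnames(variantInfo(sim$panel)))[1]
  chrom_len <- max(end(variantInfo(sim$panel)))

  cached <- function(stage, file, compute, reader = NULL) {
    path <- file.path(out_dir, file)
    if (!force && file.exists(path) && !is.null(reader)) {
      obj <- reader(path)
      note(stage, "cached", nrow(obj))
      obj
    } else {
      obj <- run(stage, compute())
      writeStage(obj, path)
      note(stage, "computed", nrow(obj))
      obj
    }
  }
  readTsv <- function(path) read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)

  if ("diversity" %in% stages) {
    results$diversity <- cached("diversity", "diversity.tsv", function() {
      wins <- genomeWindows(chrom, chrom_len,
                            p("window_size", 50000), p("window_step", 25000))
      do.call(rbind, lapply(c(target, specSources(sim$spec)), function(pp) {
        d <- windowDiversity(sim$panel, pp, wins)
        cbind(population = pp, d)
      }))
    }, readTsv)
    results$heterozygosity <- cached("diversity", "heterozygosity.tsv",
      function() sampleHeterozygosity(sim$panel, target), readTsv)
  }

  if ("afde" %in% stages) {
    results$afde <- cached("afde", "afde.tsv", function()
      afdeScan(sim$panel, target, sim$spec, alpha = p("alpha", 0.001),
               drift_opts = drift), readTsv)
    results$gene_afde <- cached("afde", "gene_afde.tsv", function()
      geneAfdeRanking(results$afde, sim$genes, flank = p("flank", 0)),
      readTsv)
  }

  if ("selection" %in% stages) {
    ref <- specSources(sim$spec)[which.max(specWeights(sim$spec))]
    results$ihs <- cached("selection", "ihs.tsv", function()
      ihsScan(sim$panel, target, sim$map), readTsv)
    results$xpehh <- cached("selection", "xpehh.tsv", function()
      xpehhScan(sim$panel, target, ref, sim$map), readTsv)
    results$fst <- cached("selection", "fst.tsv", function()
      fstScan(sim$panel, target, ref), readTsv)
  }

  if ("cms" %in% stages) {
    results$cms <- cached("cms", "cms.tsv", function()
      cmsScan(buildSiteStats(afde = results$afde, ihs = results$ihs,
                             xpehh = results$xpehh, fst = results$fst)),
      readTsv)
    results$gene_cms <- cached("cms", "gene_cms.tsv", function()
      geneCmsPvalues(results$cms, sim$genes, chrom,
                     flank = p("flank", 0)), readTsv)
  }

  if ("mgsea" %in% stages) {
    results$mgsea <- cached("mgsea", "mgsea.tsv", function() {
      scores <- setNames(results$gene_cms$max_cms, results$gene_cms$gene_id)
      runMgsea(scores, sim$geneSets, B = p("mgsea_B", 500),
               seed = config$seed)
    }, readTsv)
  }

  if ("date" %in% stages) {
    results$date <- cached("date", "date.tsv", function() {
      ds <- p("date_sources",
              specSources(sim$spec)[order(-specWeights(sim$spec))][1:2])
      dt <- dateAdmixtureLD(sim$panel, target, ds[1], ds[2], sim$map,
                            bin_cm = p("date_bin_cm", 0.5),
                            d_range = unlist(p("date_range_cm",
                                               c(0.5, 30))),
                            n_boot = p("date_boot", 50),
                            seed = config$seed)
      data.frame(T_gen = dt$T, amplitude = dt$amplitude, c = dt$c,
                 ci_lo = dt$ci[1], ci_hi = dt$ci[2], flagged = dt$flagged)
    }, readTsv)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  summary_lines <- c(
    sprintf("admixscan pipeline (seed %s, config %s)", config$seed,
            cfg_hash),
    vapply(names(manifest$stages), function(s)
      sprintf("  %-10s %-9s %6d rows", s, manifest$stages[[s]]$status,
              manifest$stages[[s]]$rows), character(1)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  results$manifest <- manifest
  invisible(results)
}
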