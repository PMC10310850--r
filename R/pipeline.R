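#' Pipeline configuration
#'
#' Bundles all thresholds, sizes and the seed of the end-to-end synthetic
#' workflow: design construction, count simulation, layered differential
#' expression, enrichment + network summarization, differential exon
#' usage, metabolite quantification and the spatio-temporal permutation
#' grid.
#'
#' @param outDir report directory (created on run).
#' @param seed master seed; every stage derives its own seed from it.
#' @param nGenes gene universe of the count simulation.
#' @param dgeFactors factors analysed at level I.
#' @param nCausal,causalLfc planted level-I effect genes per factor and
#'   their log2 fold change.
#' @param padjThreshold DGE significance threshold.
#' @param gseaFdr enrichment FDR threshold for network nodes.
#' @param networkCutoff similarity cutoff for network edges.
#' @param nPerm GSEA permutations.
#' @param deu logical; run the exon-usage stage.
#' @param deuGenes,deuSwitchFrac exon-stage size and planted usage
#'   fraction.
#' @param deuThresholds list(padj, baseMean, lfc): the DEU calling triple.
#' @param metab logical; run the metabolite stage.
#' @param spatiotemporal logical; run the region/period grid.
#' @param stB spatio-temporal permutation count.
#' @param baseMeanBackground expressed-gene floor of the ORA background.
#' @return a validated list of class "PipelineConfig".
#' @export
pipelineConfig <- function(outDir = tempfile("ffed_report_"), seed = 1L,
                           nGenes = 2000L, dgeFactors = "Pb",
                           nCausal = 100L, causalLfc = 1,
                           padjThreshold = 0.05, gseaFdr = 0.05,
                           networkCutoff = 0.375, nPerm = 500L,
                           deu = TRUE, deuGenes = 30L, deuSwitchFrac = 0.3,
                           deuThresholds = list(padj = 0.05, baseMean = 10,
                                                lfc = 1.5),
                           metab = TRUE, spatiotemporal = TRUE, stB = 1000L,
                           baseMeanBackground = 20) {
  stopifnot(padjThreshold > 0, padjThreshold <= 1,
            gseaFdr > 0, gseaFdr <= 1,
            networkCutoff >= 0, networkCutoff <= 1,
            nPerm >= 10, stB >= 10, nGenes >= 100,
            deuThresholds$padj > 0, deuThresholds$padj <= 1,
            deuThresholds$baseMean >= 0, deuThresholds$lfc >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "outDir")], f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic workflow
#'
#' Executes design -> simulation -> level-I differential expression per
#' factor -> preranked enrichment, similarity network and metrics ->
#' differential exon usage -> metabolite quantification/testing -> the
#' spatio-temporal permutation grid, writing a provenance-stamped report
#' directory (every file carries the config hash and seed). With
#' `dryRun = TRUE` the configuration is validated and the planned stages
#' listed without computing anything.
#'
#' @param config a [pipelineConfig()].
#' @param dryRun validate only.
#' @return invisible list of per-stage summaries (or the stage plan when
#'   dry-running).
#' @export
runPipeline <- function(config = pipelineConfig(), dryRun = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  stages <- c("design", "simulate", "dge", "enrich",
              if (config$deu) "deu", if (config$metab) "metab",
              if (config$spatiotemporal) "spatiotemporal")
  if (dryRun) return(invisible(list(stages = stages, config = config)))
  hash <- configHash(config)
  hdr <- provenanceHeader(hash, config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  summary <- list(configHash = hash, seed = config$seed)

  design <- assignFactors(buildL8())
  sheet <- ffedStudySheet(design)
  writeDesign(design, out("design.csv"))
  writeSampleSheet(sheet, out("sample_sheet.csv"), hdr)

  causal <- list()
  gpool <- geneIds(config$nGenes)
  set.seed(config$seed)
  for (i in seq_along(config$dgeFactors)) {
    causal[[config$dgeFactors[i]]] <- list(
      genes = sample(gpool, config$nCausal),
      lfc = rep(config$causalLfc, config$nCausal))
  }
  sim <- simulateCounts(simConfig(nGenes = config$nGenes,
                                  causalSets = causal,
                                  seed = config$seed), sheet, design)
  writeCounts(SummarizedExperiment::assay(sim$se), out("counts.tsv"), hdr)

  dgeSummaries <- list()
  collection <- NULL
  for (f in config$dgeFactors) {
    res <- runLevel(sim$se, "I", f, design = design)
    tab <- dgeTable(res)
    writeTableWithHeader(tab, out(sprintf("dge_levelI_%s.tsv", f)), "\t", hdr)
    ranked <- rankedList(res)
    writeRNK(ranked, out(sprintf("ranked_%s.rnk", f)))

    truthGenes <- causal[[f]]$genes
    sig <- tab$gene[!is.na(tab$padj) & tab$padj < config$padjThreshold]
    dgeSummaries[[f]] <- list(
      nSignificant = length(sig),
      planted = length(truthGenes),
      recovered = sum(truthGenes %in% sig))

    # gene sets: the planted set plus size-matched random sets
    set.seed(config$seed + 17L)
    collection <- c(stats::setNames(list(truthGenes),
                                    paste0("planted_", f)),
                    stats::setNames(lapply(1:9, function(i)
                      sample(gpool, length(truthGenes))),
                      paste0("random_", f, "_", 1:9)))
    enr <- gseaSignificance(ranked, collection, nPerm = config$nPerm,
                            seed = config$seed + 23L)
    writeTableWithHeader(enr, out(sprintf("gsea_%s.tsv", f)), "\t", hdr)
    net <- buildSimilarityNetwork(enr, collection,
                                  qThreshold = config$gseaFdr,
                                  cutoff = config$networkCutoff)
    metrics <- networkMetrics(net)
    yaml::write_yaml(c(list(configHash = hash, seed = config$seed), metrics),
                     out(sprintf("network_metrics_%s.yaml", f)))
    dgeSummaries[[f]]$enrichment <- enr[enr$set == paste0("planted_", f), ]
    dgeSummaries[[f]]$networkMetrics <- metrics
  }
  summary$dge <- dgeSummaries

  if (config$deu) {
    f <- config$dgeFactors[1]
    swGenes <- geneIds(config$deuGenes)[1:10]
    ex <- simulateExonCounts(
      simConfig(nGenes = config$deuGenes, seed = config$seed + 31L), sheet,
      design, usageSwitches = stats::setNames(list(list(
        genes = swGenes, from = 1L, to = 2L,
        fraction = config$deuSwitchFrac)), f))
    deuRes <- testDEU(ex$bins, sheet, "I", f, design = design)
    calls <- callDEUGenes(deuRes, config$deuThresholds$padj,
                          config$deuThresholds$baseMean,
                          config$deuThresholds$lfc)
    writeTableWithHeader(deuRes, out("deu_bins.tsv"), "\t", hdr)
    writeTableWithHeader(calls, out("deu_calls.tsv"), "\t", hdr)
    summary$deu <- list(called = sum(calls$called),
                        plantedCalled = sum(calls$called[calls$gene %in% swGenes]))
  }

  if (config$metab) {
    msheet <- metabSheet()
    met <- simulateMetabolites(sheet = msheet, seed = config$seed + 41L)
    conc <- quantifyFeatures(met$features, met$isMap)
    writeFeatureTable(conc, out("metab_concentrations.csv"), hdr)
    mres <- testMetabolites(conc, msheet, "global")
    writeTableWithHeader(mres, out("metab_global.tsv"), "\t", hdr)
    truly <- met$truth$feature[met$truth$trueRatio != 1]
    summary$metab <- list(
      nSignificant = sum(mres$padj < 0.05),
      plantedDetected = sum(mres$padj[mres$feature %in% truly] < 0.05))
  }

  if (config$spatiotemporal) {
    st <- simulateSpatiotemporal(
      nGenes = 800L,
      enrichedGroup = list(genes = geneIds(800L)[1:40],
                           regions = c("FC", "TC"), periods = paste0("P", 1:3),
                           shift = 2),
      seed = config$seed + 53L)
    filt <- filterSamples(st$expr, st$meta)
    grid <- permutationEnrichment(filt$expr, filt$meta, geneIds(800L)[1:40],
                                  B = config$stB, seed = config$seed + 59L)
    gridDf <- data.frame(region = rep(rownames(gridP(grid)),
                                      ncol(gridP(grid))),
                         period = rep(colnames(gridP(grid)),
                                      each = nrow(gridP(grid))),
                         observed = as.vector(gridObserved(grid)),
                         p = as.vector(gridP(grid)),
                         padj = as.vector(gridPadj(grid)))
    writeTableWithHeader(gridDf, out("spatiotemporal_grid.tsv"), "\t", hdr)
    summary$spatiotemporal <- list(
      cellsSignificant = sum(gridPadj(grid) < 0.05, na.rm = TRUE))
  }

  yaml::write_yaml(list(configHash = hash, seed = config$seed,
                        stages = stages), out("provenance.yaml"))
  invisible(summary)
}
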