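#' Simulation configuration
#'
#' Collects every parameter of the synthetic count generator. Defaults
#' emulate the study's structure at desk scale: a modest gene universe,
#' cell-line baselines that dominate the variance (genetic background is the
#' main driver of between-sample differences), sparse exposure main effects,
#' and interaction effects confined to declared gene subsets.
#'
#' Effect sizes are treated-vs-control log2 fold changes; internally each
#' effect is split symmetrically (+beta/2 on treated runs, -beta/2 on
#' control runs) so the baseline stays the grand mean.
#'
#' @param nGenes gene universe size.
#' @param baselineLog2Mean,baselineLog2Sd normal parameters of the per-gene
#'   baseline log2 mean count.
#' @param dispA0,dispA1 mean-dispersion trend alpha(mu) = dispA0/mu + dispA1
#'   (NB variance mu + alpha mu^2).
#' @param dispNoiseSd lognormal sd of per-gene dispersion noise around the
#'   trend.
#' @param cellLineEffectSd sd (log2 units) of per-gene cell-line baseline
#'   offsets; the default is large so lines dominate variance.
#' @param librarySizeRange range of uniform per-sample library size factors.
#' @param causalSets named list factor -> list(genes, lfc): true main
#'   effects.
#' @param interactionEffects named list "A:B" -> list(genes, lfc): true
#'   interaction effects.
#' @param seed integer; all generators are pure functions of (config, seed).
#' @return a list of class "SimConfig".
#' @export
simConfig <- function(nGenes = 2000L, baselineLog2Mean = 5, baselineLog2Sd = 2,
                      dispA0 = 4, dispA1 = 0.05, dispNoiseSd = 0.25,
                      cellLineEffectSd = 1.0, librarySizeRange = c(0.5, 2),
                      causalSets = list(), interactionEffects = list(),
                      seed = 1L) {
  stopifnot(nGenes >= 1, baselineLog2Sd >= 0, dispA0 >= 0, dispA1 >= 0,
            dispNoiseSd >= 0, cellLineEffectSd >= 0,
            length(librarySizeRange) == 2L, all(librarySizeRange > 0))
  cfg <- list(nGenes = as.integer(nGenes),
              baselineLog2Mean = baselineLog2Mean,
              baselineLog2Sd = baselineLog2Sd,
              dispA0 = dispA0, dispA1 = dispA1, dispNoiseSd = dispNoiseSd,
              cellLineEffectSd = cellLineEffectSd,
              librarySizeRange = librarySizeRange,
              causalSets = causalSets,
              interactionEffects = interactionEffects,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

geneIds <- function(n) sprintf("g%04d", seq_len(n))

effectMatrix <- function(effects, genes, colNames) {
  m <- matrix(0, length(genes), length(colNames),
              dimnames = list(genes, colNames))
  for (nm in names(effects)) {
    e <- effects[[nm]]
    if (!all(e$genes %in% genes))
      stop("causal set for ", nm, " contains genes outside the universe")
    m[e$genes, nm] <- e$lfc
  }
  m
}

#' Simulate gene-level counts under the exposure design
#'
#' Draws negative-binomial counts with mean
#' mu_ij = s_j * 2^(b_i + l_i(line_j) + sum_f (x_jf/2) beta_if +
#' sum_fg (x_jf x_jg / 2) gamma_ifg) and variance mu + alpha_i mu^2, where
#' x is the -1/+1 exposure coding from the design, beta are the declared
#' main-effect log2 fold changes and gamma the interaction log2 fold
#' changes. The ground truth is returned alongside the counts.
#'
#' @param config a [simConfig()].
#' @param sheet a sample sheet from [makeSampleSheet()].
#' @param design the assigned \linkS4class{DesignTable} the sheet came from.
#' @return list with elements `se` (a
#'   \link[SummarizedExperiment]{SummarizedExperiment}: counts assay, the
#'   sheet as colData, true dispersion and baseline in rowData) and `truth`
#'   (list of matrices `main` genes x factors and `interaction`
#'   genes x pairs of true log2 fold changes).
#' @export
simulateCounts <- function(config, sheet, design = assignFactors(buildL8())) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  g <- geneIds(config$nGenes)
  ns <- nrow(sheet)
  x <- exposureCoding(sheet, design)
  factors <- colnames(x)

  b <- stats::rnorm(config$nGenes, config$baselineLog2Mean, config$baselineLog2Sd)
  lines <- unique(sheet$cellLine)
  lineEff <- matrix(stats::rnorm(config$nGenes * length(lines),
                                 0, config$cellLineEffectSd),
                    config$nGenes, length(lines),
                    dimnames = list(g, lines))
  beta <- effectMatrix(config$causalSets, g, factors)
  pairNames <- names(config$interactionEffects)
  gamma <- effectMatrix(config$interactionEffects, g,
                        if (length(pairNames)) pairNames else character(0))

  s <- stats::runif(ns, config$librarySizeRange[1], config$librarySizeRange[2])
  log2mu <- matrix(b, config$nGenes, ns) +
    lineEff[, sheet$cellLine, drop = FALSE] +
    beta %*% t(x / 2)
  if (length(pairNames)) {
    xx <- vapply(strsplit(pairNames, ":", fixed = TRUE),
                 function(p) x[, p[1]] * x[, p[2]], numeric(ns))
    log2mu <- log2mu + gamma %*% t(xx / 2)
  }
  mu <- sweep(2^log2mu, 2L, s, `*`)

  muBase <- 2^b
  alpha <- (config$dispA0 / muBase + config$dispA1) *
    stats::rlnorm(config$nGenes, 0, config$dispNoiseSd)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / alpha, ns)),
                   config$nGenes, ns, dimnames = list(g, sheet$sampleId))
  storage.mode(counts) <- "integer"

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sheet, row.names = sheet$sampleId),
    rowData = S4Vectors::DataFrame(baselineLog2 = b, dispersion = alpha,
                                   row.names = g))
  S4Vectors::metadata(se)$seed <- config$seed
  S4Vectors::metadata(se)$sizeFactorTruth <- s
  list(se = se, truth = list(main = beta, interaction = gamma))
}

#' Simulate exon-bin counts with usage switches
#'
#' Gene totals are negative-binomial as in [simulateCounts()] (no gene-level
#' exposure effects unless declared); bin counts are a multinomial split of
#' each gene's total. A declared usage switch moves `fraction` of the
#' gene's total reads from a dominant source bin (base share 0.50) into a
#' minor sink bin (base share 0.05) on samples at the treated level of the
#' switching factor; `lineSwitches` do the same per cell line regardless of
#' exposure (to exercise blocking).
#'
#' @param config a [simConfig()]; `nGenes` here is the number of multi-bin
#'   genes.
#' @param sheet,design as in [simulateCounts()].
#' @param nBins exon bins per gene.
#' @param usageSwitches named list factor -> list(genes, from, to, fraction).
#' @param lineSwitches named list cellLine -> list(genes, from, to, fraction).
#' @return list with `bins` (data.frame gene, bin, then one count column per
#'   sample), `sheet`, `truth` (data.frame gene, switchedBy) and
#'   `geneTotals` (the simulated gene-level totals the bins partition).
#' @export
simulateExonCounts <- function(config, sheet,
                               design = assignFactors(buildL8()),
                               nBins = 4L, usageSwitches = list(),
                               lineSwitches = list()) {
  stopifnot(inherits(config, "SimConfig"), nBins >= 2L)
  set.seed(config$seed + 1L)
  g <- geneIds(config$nGenes)
  ns <- nrow(sheet)
  x <- exposureCoding(sheet, design)

  b <- stats::rnorm(config$nGenes, config$baselineLog2Mean, config$baselineLog2Sd)
  muBase <- 2^b
  alpha <- (config$dispA0 / muBase + config$dispA1) *
    stats::rlnorm(config$nGenes, 0, config$dispNoiseSd)
  s <- stats::runif(ns, config$librarySizeRange[1], config$librarySizeRange[2])
  totals <- matrix(stats::rnbinom(config$nGenes * ns,
                                  mu = outer(muBase, s),
                                  size = rep(1 / alpha, ns)),
                   config$nGenes, ns, dimnames = list(g, sheet$sampleId))

  baseProp <- matrix(0, config$nGenes, nBins, dimnames = list(g, NULL))
  for (i in seq_len(config$nGenes)) {
    p <- stats::rgamma(nBins, shape = 5, rate = 1)
    baseProp[i, ] <- p / sum(p)
  }
  # switch genes get a defined profile: a dominant source bin and a minor
  # sink bin, so moving `fraction` of the gene's reads is well defined and
  # produces a clear usage fold change on the sink
  fixProfile <- function(genes, from, to) {
    rest <- setdiff(seq_len(nBins), c(from, to))
    baseProp[genes, ] <<- matrix(0.45 / max(length(rest), 1L),
                                 length(genes), nBins)
    baseProp[genes, from] <<- 0.50
    baseProp[genes, to] <<- 0.05
  }
  for (sw in usageSwitches) fixProfile(sw$genes, sw$from, sw$to)
  for (sw in lineSwitches) fixProfile(sw$genes, sw$from, sw$to)

  moveReads <- function(prop, genes, from, to, fraction) {
    shift <- pmin(fraction, prop[genes, from])
    prop[genes, to] <- prop[genes, to] + shift
    prop[genes, from] <- prop[genes, from] - shift
    prop
  }
  switchedBy <- stats::setNames(rep("", config$nGenes), g)
  counts <- array(0L, dim = c(config$nGenes, nBins, ns))
  for (j in seq_len(ns)) {
    prop <- baseProp
    for (f in names(usageSwitches)) {
      sw <- usageSwitches[[f]]
      if (x[j, f] > 0)
        prop <- moveReads(prop, sw$genes, sw$from, sw$to, sw$fraction)
      switchedBy[sw$genes] <- f
    }
    for (cl in names(lineSwitches)) {
      sw <- lineSwitches[[cl]]
      if (sheet$cellLine[j] == cl)
        prop <- moveReads(prop, sw$genes, sw$from, sw$to, sw$fraction)
    }
    for (i in seq_len(config$nGenes)) {
      counts[i, , j] <- stats::rmultinom(1L, totals[i, j], prop[i, ])
    }
  }

  bins <- data.frame(gene = rep(g, each = nBins),
                     bin = sprintf("E%03d", rep(seq_len(nBins), config$nGenes)),
                     stringsAsFactors = FALSE)
  cm <- matrix(aperm(counts, c(2, 1, 3)), config$nGenes * nBins, ns)
  colnames(cm) <- sheet$sampleId
  bins <- cbind(bins, as.data.frame(cm))
  list(bins = bins, sheet = sheet,
       truth = data.frame(gene = g, switchedBy = unname(switchedBy),
                          stringsAsFactors = FALSE),
       geneTotals = totals)
}

#' Sample layout of the metabolomics arm
#'
#' Three technical replicates for treated and untreated groups in each of
#' the four cell lines (24 samples), matching the direct-infusion ESI-MS
#' arm of the study.
#'
#' @param cellLines data.frame as [ffedCellLines()].
#' @param nReplicates technical replicates per group.
#' @param factorName exposure factor (the study profiled fluoxetine, FH).
#' @return data.frame sampleId, cellLine, clinicalBackground, replicate and
#'   one exposure column with values "control"/"treated".
#' @export
metabSheet <- function(cellLines = ffedCellLines(), nReplicates = 3L,
                       factorName = "FH") {
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      exposure = c("control", "treated"),
                      cellLine = cellLines$cellLine,
                      stringsAsFactors = FALSE)
  grid$clinicalBackground <-
    cellLines$clinicalBackground[match(grid$cellLine, cellLines$cellLine)]
  grid[[factorName]] <- grid$exposure
  grid$exposure <- NULL
  grid$sampleId <- sprintf("%s_%s_%d", grid$cellLine, grid[[factorName]],
                           grid$replicate)
  grid[, c("sampleId", "cellLine", "clinicalBackground", "replicate",
           factorName)]
}

#' Simulate a metabolite feature table with internal standards
#'
#' Lognormal feature intensities; one internal-standard channel per lipid
#' class at fixed, known concentration and stable intensity; responsive
#' features multiplied by `foldChange` on samples at the treated level of
#' `factorName`.
#'
#' @param nFeatures endogenous features (split evenly over `classes`).
#' @param sheet a [metabSheet()].
#' @param classes lipid class labels; one internal standard each.
#' @param responsive indices (into the feature vector) of truly responsive
#'   features.
#' @param foldChange true concentration ratio treated/control.
#' @param cvNoise lognormal sdlog of measurement noise.
#' @param factorName exposure column of `sheet`.
#' @param isConc known internal-standard concentration (uM).
#' @param seed integer seed.
#' @return list: `features` data.frame (feature, class, intensity per
#'   sample), `isMap` data.frame (feature -> isFeature, isConc), `truth`
#'   data.frame (feature, trueRatio).
#' @export
simulateMetabolites <- function(nFeatures = 40L, sheet = metabSheet(),
                                classes = c("FA", "PC", "TG", "SM"),
                                responsive = 1:4, foldChange = 1.5,
                                cvNoise = 0.15, factorName = "FH",
                                isConc = 2, seed = 1L) {
  set.seed(seed)
  ns <- nrow(sheet)
  feat <- sprintf("%s %d:%d", rep(classes, length.out = nFeatures),
                  10 + seq_len(nFeatures), seq_len(nFeatures) %% 5)
  cls <- rep(classes, length.out = nFeatures)
  baseConc <- stats::rlnorm(nFeatures, log(5), 0.8)  # uM
  treated <- sheet[[factorName]] == "treated"

  conc <- matrix(baseConc, nFeatures, ns)
  conc[responsive, treated] <- conc[responsive, treated] * foldChange
  # instrument response: per-class gain maps concentration to intensity
  gain <- stats::setNames(stats::rlnorm(length(classes), log(1e4), 0.3), classes)
  intensity <- conc * gain[cls] *
    matrix(stats::rlnorm(nFeatures * ns, 0, cvNoise), nFeatures, ns)

  isFeat <- sprintf("IS_%s", classes)
  isInt <- matrix(isConc * gain[classes], length(classes), ns) *
    matrix(stats::rlnorm(length(classes) * ns, 0, cvNoise / 2),
           length(classes), ns)

  features <- data.frame(feature = c(feat, isFeat),
                         class = c(cls, classes), stringsAsFactors = FALSE)
  m <- rbind(intensity, isInt)
  colnames(m) <- sheet$sampleId
  features <- cbind(features, as.data.frame(m))
  isMap <- data.frame(feature = feat, isFeature = paste0("IS_", cls),
                      isConc = isConc, stringsAsFactors = FALSE)
  truth <- data.frame(feature = feat,
                      trueRatio = ifelse(seq_len(nFeatures) %in% responsive,
                                         foldChange, 1),
                      stringsAsFactors = FALSE)
  list(features = features, isMap = isMap, truth = truth)
}

#' Simulate a region-by-period expression matrix
#'
#' Lognormal FPKM-like values over samples labelled by brain region and
#' developmental period, with an enriched gene group elevated by `shift`
#' (log2 units) in the stated region/period cells. A few samples receive
#' RIN below 9 to exercise quality filtering.
#'
#' @param nGenes gene universe size.
#' @param regions,periods label vectors (defaults: 4 regions, 8 periods).
#' @param nPerCell samples per region x period cell.
#' @param enrichedGroup list(genes, regions, periods, shift) or NULL.
#' @param lowRinFrac fraction of samples drawn with RIN < 9.
#' @param seed integer seed.
#' @return list: `expr` matrix genes x samples, `meta` data.frame (sample,
#'   region, period, RIN), `truth` the enrichedGroup used.
#' @export
simulateSpatiotemporal <- function(nGenes = 1000L,
                                   regions = c("FC", "TC", "PC", "OC"),
                                   periods = paste0("P", 1:8),
                                   nPerCell = 3L, enrichedGroup = NULL,
                                   lowRinFrac = 0.05, seed = 1L) {
  set.seed(seed)
  meta <- expand.grid(rep = seq_len(nPerCell), region = regions,
                      period = periods, stringsAsFactors = FALSE)
  ns <- nrow(meta)
  meta$sample <- sprintf("%s_%s_%d", meta$region, meta$period, meta$rep)
  meta$RIN <- round(stats::runif(ns, 9, 10), 1)
  low <- stats::runif(ns) < lowRinFrac
  meta$RIN[low] <- round(stats::runif(sum(low), 6, 8.9), 1)

  g <- geneIds(nGenes)
  baseLog2 <- stats::rnorm(nGenes, 3, 1.5)
  expr <- 2^(matrix(baseLog2, nGenes, ns) +
             matrix(stats::rnorm(nGenes * ns, 0, 0.8), nGenes, ns))
  dimnames(expr) <- list(g, meta$sample)
  if (!is.null(enrichedGroup)) {
    hit <- meta$region %in% enrichedGroup$regions &
      meta$period %in% enrichedGroup$periods
    expr[enrichedGroup$genes, hit] <-
      expr[enrichedGroup$genes, hit] * 2^enrichedGroup$shift
  }
  list(expr = expr,
       meta = meta[, c("sample", "region", "period", "RIN")],
       truth = enrichedGroup)
}
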