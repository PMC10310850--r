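test_that("count simulation is a pure function of config and seed", {
  d <- l8Design(); sheet <- studySheet()
  cfg <- simConfig(nGenes = 150, seed = 5)
  a <- simulateCounts(cfg, sheet, d)
  b <- simulateCounts(cfg, sheet, d)
  expect_identical(SummarizedExperiment::assay(a$se),
                   SummarizedExperiment::assay(b$se))
  c2 <- simulateCounts(simConfig(nGenes = 150, seed = 6), sheet, d)
  expect_false(identical(SummarizedExperiment::assay(a$se),
                         SummarizedExperiment::assay(c2$se)))
})

test_that("a null config yields zero truth and baseline-consistent means", {
  d <- l8Design(); sheet <- studySheet()
  sim <- simulateCounts(simConfig(nGenes = 400, cellLineEffectSd = 0,
                                  seed = 2), sheet, d)
  expect_true(all(sim$truth$main == 0))
  counts <- SummarizedExperiment::assay(sim$se)
  s <- S4Vectors::metadata(sim$se)$sizeFactorTruth
  q <- sweep(counts, 2, s, "/")
  b <- SummarizedExperiment::rowData(sim$se)$baselineLog2
  alpha <- SummarizedExperiment::rowData(sim$se)$dispersion
  mu <- 2^b
  seMean <- sqrt((mu / ncol(q) + alpha * mu^2 / ncol(q)))
  dev <- abs(rowMeans(q) - mu) / seMean
  expect_lt(mean(dev > 3), 0.02)
})

test_that("a spiked factor effect doubles treated counts in expectation", {
  d <- l8Design(); sheet <- studySheet()
  genes <- sprintf("g%04d", 1:100)
  cfg <- simConfig(nGenes = 500, cellLineEffectSd = 0,
                   causalSets = list(Pb = list(genes = genes,
                                               lfc = rep(1, 100))),
                   seed = 3)
  sim <- simulateCounts(cfg, sheet, d)
  counts <- SummarizedExperiment::assay(sim$se)
  q <- sweep(counts, 2, S4Vectors::metadata(sim$se)$sizeFactorTruth, "/")
  treated <- exposureCoding(sheet, d)[, "Pb"] > 0
  ratio <- rowMeans(q[genes, treated]) / rowMeans(q[genes, !treated])
  expect_equal(mean(log2(ratio)), 1, tolerance = 0.1)
  nullRatio <- rowMeans(q[-(1:100), treated]) / rowMeans(q[-(1:100), !treated])
  expect_equal(mean(log2(nullRatio)), 0, tolerance = 0.1)
})

test_that("cell-line baselines dominate the variance over exposure effects", {
  d <- l8Design(); sheet <- studySheet()
  genes <- sprintf("g%04d", 1:50)
  cfg <- simConfig(nGenes = 300,
                   causalSets = list(Pb = list(genes = genes,
                                               lfc = rep(1, 50))),
                   seed = 4)
  sim <- simulateCounts(cfg, sheet, d)
  lcounts <- log2(SummarizedExperiment::assay(sim$se) + 1)
  lineVar <- median(apply(lcounts, 1, function(y)
    stats::anova(stats::lm(y ~ sheet$cellLine))[1, "Mean Sq"]))
  treated <- exposureCoding(sheet, d)[, "Pb"] > 0
  expoVar <- median(apply(lcounts, 1, function(y)
    stats::anova(stats::lm(y ~ treated))[1, "Mean Sq"]))
  expect_gt(lineVar, expoVar)
})

test_that("exon simulation conserves gene totals and plants usage switches", {
  d <- l8Design(); sheet <- studySheet()
  sw <- list(BPA = list(genes = c("g0001", "g0002"), from = 1L, to = 2L,
                        fraction = 0.25))
  ex <- simulateExonCounts(simConfig(nGenes = 10, baselineLog2Mean = 8,
                                     seed = 6), sheet, d,
                           usageSwitches = sw)
  counts <- as.matrix(ex$bins[, sheet$sampleId])
  sums <- rowsum(counts, ex$bins$gene)
  expect_equal(unname(sums), unname(ex$geneTotals))
  expect_setequal(ex$truth$gene[ex$truth$switchedBy == "BPA"],
                  c("g0001", "g0002"))
  # sink-bin share rises by about the moved fraction under treatment
  treated <- exposureCoding(sheet, d)[, "BPA"] > 0
  bin2 <- counts[ex$bins$gene == "g0001" & ex$bins$bin == "E002", ]
  tot <- ex$geneTotals["g0001", ]
  shareT <- sum(bin2[treated]) / sum(tot[treated])
  shareC <- sum(bin2[!treated]) / sum(tot[!treated])
  expect_equal(shareT - shareC, 0.25, tolerance = 0.05)
  ex2 <- simulateExonCounts(simConfig(nGenes = 10, baselineLog2Mean = 8,
                                      seed = 6), sheet, d,
                            usageSwitches = sw)
  expect_identical(ex$bins, ex2$bins)
})

test_that("metabolite simulation plants recoverable concentration ratios", {
  ms <- metabSheet()
  expect_equal(nrow(ms), 24L)
  met <- simulateMetabolites(sheet = ms, responsive = 1:3, foldChange = 1.5,
                             seed = 8)
  conc <- quantifyFeatures(met$features, met$isMap)
  m <- as.matrix(conc[, ms$sampleId])
  rownames(m) <- conc$feature
  treated <- ms$FH == "treated"
  hot <- met$truth$feature[met$truth$trueRatio != 1]
  ratios <- rowMeans(m[hot, treated, drop = FALSE]) /
    rowMeans(m[hot, !treated, drop = FALSE])
  expect_equal(unname(ratios), rep(1.5, length(hot)), tolerance = 0.15)
  met2 <- simulateMetabolites(sheet = ms, responsive = 1:3, foldChange = 1.5,
                              seed = 8)
  expect_identical(met$features, met2$features)
})

test_that("spatio-temporal simulation elevates the target cells by the shift", {
  grp <- list(genes = sprintf("g%04d", 1:30), regions = c("FC", "TC"),
              periods = c("P1", "P2", "P3"), shift = 2)
  st <- simulateSpatiotemporal(nGenes = 400, enrichedGroup = grp, seed = 9)
  expect_true(any(st$meta$RIN < 9) && any(st$meta$RIN >= 9))
  hit <- st$meta$region %in% grp$regions & st$meta$period %in% grp$periods
  lg <- log2(st$expr)
  delta <- mean(lg[grp$genes, hit]) - mean(lg[grp$genes, !hit])
  expect_equal(delta, 2, tolerance = 0.2)
  st0 <- simulateSpatiotemporal(nGenes = 400, enrichedGroup = NULL, seed = 9)
  expect_null(st0$truth)
  st2 <- simulateSpatiotemporal(nGenes = 400, enrichedGroup = grp, seed = 9)
  expect_identical(st$expr, st2$expr)
})
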