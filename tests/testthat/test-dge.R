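test_that("median-of-ratios size factors satisfy their contracts", {
  set.seed(1)
  base <- matrix(rpois(50 * 6, 60), 50, 6)
  same <- base[, c(1, 1, 1, 1)]
  expect_equal(sizeFactorsMoR(same), rep(1, 4))
  doubled <- cbind(base[, 1], 2L * base[, 1])
  s <- sizeFactorsMoR(doubled)
  expect_equal(s[2] / s[1], 2)
  # independent direct implementation of the median-of-ratios formula
  geo <- exp(rowMeans(log(base)))
  oracle <- apply(sweep(base, 1, geo, "/"), 2, median)
  expect_equal(sizeFactorsMoR(base), unname(oracle))
})

test_that("size factors fall back when no gene covers every sample", {
  set.seed(2)
  m <- matrix(rpois(40 * 4, 20), 40, 4)
  for (i in seq_len(nrow(m))) m[i, sample(4, 1)] <- 0L
  expect_message(s <- sizeFactorsMoR(m), "falling back")
  expect_true(all(s > 0))
})

test_that("dispersion estimation recovers the generating value and the floor", {
  X <- cbind(1, rep(0:1, each = 8))
  set.seed(3)
  nb <- matrix(rnbinom(800 * 16, mu = 100, size = 1 / 0.2), 800, 16)
  rownames(nb) <- sprintf("g%03d", 1:800)
  aNB <- estimateDispersion(nb, X, rep(1, 16))
  expect_lt(abs(median(aNB) - 0.2), 0.05)
  pois <- matrix(rpois(800 * 16, 100), 800, 16)
  rownames(pois) <- rownames(nb)
  aP <- estimateDispersion(pois, X, rep(1, 16))
  expect_lt(median(aP), 0.01)
  expect_true(all(aP >= 1e-8))
})

test_that("the NB GLM reduces to the log ratio of group means as alpha -> 0", {
  set.seed(4)
  y <- rpois(12, 50)
  grp <- rep(0:1, each = 6)
  X <- cbind(`(Intercept)` = 1, exposure = grp)
  fit <- fitNBGLM(y, X, 1e-12, rep(1, 12))
  expect_equal(unname(fit$coefficients["exposure"]),
               log(mean(y[grp == 1]) / mean(y[grp == 0])), tolerance = 1e-6)
  # with size factors, the closed form uses normalized means
  s <- runif(12, 0.5, 2)
  fit2 <- fitNBGLM(y, X, 1e-12, s)
  q <- y / s
  expect_equal(unname(fit2$coefficients["exposure"]),
               log(sum(y[grp == 1]) / sum(s[grp == 1])) -
                 log(sum(y[grp == 0]) / sum(s[grp == 0])), tolerance = 1e-6)
})

test_that("IRLS maximizes the NB likelihood (generic-optimizer oracle)", {
  set.seed(5)
  n <- 16
  X <- cbind(1, rep(0:1, each = n / 2), rnorm(n, 0, 0.3))
  colnames(X) <- c("(Intercept)", "grp", "cov")
  s <- runif(n, 0.6, 1.6)
  for (i in 1:20) {
    alpha <- runif(1, 0.05, 0.5)
    beta <- c(log(runif(1, 20, 200)), rnorm(1, 0, 0.7), rnorm(1, 0, 0.4))
    mu <- s * exp(drop(X %*% beta))
    y <- rnbinom(n, mu = mu, size = 1 / alpha)
    if (all(y == 0)) next
    fit <- fitNBGLM(y, X, alpha, s)
    nll <- function(b) -nbLogLik(y, s * exp(pmin(drop(X %*% b), 30)), alpha)
    opt <- optim(fit$coefficients, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    # also try an independent start to guard against a shared local optimum
    opt2 <- optim(c(log(mean(y) + 0.5), 0, 0), nll, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-14))
    best <- if (opt2$value < opt$value) opt2 else opt
    expect_equal(unname(fit$coefficients), unname(best$par), tolerance = 1e-4)
  }
})

test_that("rank-deficient model matrices are rejected with the collinear terms named", {
  set.seed(6)
  y <- rpois(8, 30)
  X <- cbind(`(Intercept)` = rep(1, 8), a = rep(0:1, 4), b = rep(0:1, 4))
  expect_error(fitNBGLM(y, X, 0.1), "rank deficient.*b")
})

test_that("level subsets, filtering and the result object are coherent", {
  d <- l8Design(); sheet <- studySheet()
  genes <- sprintf("g%04d", 1:40)
  cfg <- simConfig(nGenes = 300, cellLineEffectSd = 0.5,
                   causalSets = list(FH = list(genes = genes,
                                               lfc = rep(1.5, 40))),
                   seed = 7)
  sim <- simulateCounts(cfg, sheet, d)
  res <- runLevel(sim$se, "II", "FH", background = "ASD", design = d)
  expect_s4_class(res, "DGEResult")
  expect_equal(res@nSamples, 16L)
  tab <- dgeTable(res)
  ok <- !is.na(tab$padj)
  expect_true(all(tab$padj[ok] >= tab$pvalue[ok]))
  expect_true(all(is.na(tab$padj[tab$baseMean < 5])))
  resIII <- runLevel(sim$se, "III", "FH", cellLine = "CTRL_Male", design = d)
  expect_equal(resIII@nSamples, 16L)
  expect_error(runLevel(sim$se, "III", "FH", design = d), "cell line")
  expect_error(runLevel(sim$se, "II", "FH", design = d), "background")
})

test_that("BH adjustment matches the brute-force step-up exactly", {
  set.seed(8)
  p <- c(runif(40), runif(5, 0, 1e-3), rep(0.02, 3))  # include ties
  expect_equal(p.adjust(p, method = "BH"), bruteBH(p))
  d <- l8Design(); sheet <- studySheet()
  sim <- simulateCounts(simConfig(nGenes = 120, seed = 9), sheet, d)
  tab <- dgeTable(runLevel(sim$se, "I", "Pb", design = d))
  tested <- !is.na(tab$padj)
  expect_equal(tab$padj[tested], bruteBH(tab$pvalue[tested]))
})

test_that("orthogonal factors give uncorrelated main-effect estimates under the null", {
  d <- l8Design(); sheet <- studySheet()
  # equal sequencing depth: unequal depths reweight samples identically for
  # every gene, which leaves a small but systematic correlation between
  # contrasts; the design-orthogonality property is stated at equal depth
  sim <- simulateCounts(simConfig(nGenes = 2000, cellLineEffectSd = 0,
                                  librarySizeRange = c(1, 1),
                                  seed = 10), sheet, d)
  lfcs <- sapply(c("Pb", "VPA", "BPA"), function(f)
    dgeTable(runLevel(sim$se, "I", f, design = d))$log2FC)
  cors <- cor(lfcs, use = "pairwise.complete.obs")
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)
})

test_that("level IV on a single-replicate sheet is rank deficient, with replicates estimable", {
  d <- l8Design()
  single <- makeSampleSheet(d, ffedCellLines())
  sim <- simulateCounts(simConfig(nGenes = 60, seed = 11), single, d)
  expect_error(runLevel(sim$se, "IV", "Pb:Zn-", design = d),
               "rank deficient.*replicate")
  # with the study sheet (two full replicates for one line) it runs
  full <- studySheet()
  simF <- simulateCounts(simConfig(nGenes = 60, seed = 11), full, d)
  resIV <- runLevel(simF$se, "IV", "Pb:Zn-", design = d)
  expect_s4_class(resIV, "DGEResult")
  expect_error(runLevel(simF$se, "IV", "Pb", design = d), "factor pair")
})

test_that("level IV recovers a planted interaction effect", {
  d <- l8Design(); sheet <- studySheet()
  genes <- sprintf("g%04d", 1:30)
  cfg <- simConfig(nGenes = 250, cellLineEffectSd = 0.5,
                   interactionEffects = list(`Pb:Zn-` = list(
                     genes = genes, lfc = rep(1.5, 30))),
                   seed = 12)
  sim <- simulateCounts(cfg, sheet, d)
  tab <- dgeTable(runLevel(sim$se, "IV", "Pb:Zn-", design = d))
  sp <- tab[tab$gene %in% genes, ]
  expect_equal(mean(sp$log2FC), 1.5, tolerance = 0.2)
  expect_gt(mean(sp$padj < 0.05, na.rm = TRUE), 0.5)
})

test_that("all-zero genes are reported untestable and ranked lists exclude them", {
  d <- l8Design(); sheet <- studySheet()
  sim <- simulateCounts(simConfig(nGenes = 80, seed = 13), sheet, d)
  counts <- SummarizedExperiment::assay(sim$se)
  counts[1:3, ] <- 0L
  res <- runLevel(counts, "I", "Pb", sheet = sheet, design = d)
  tab <- dgeTable(res)
  expect_true(all(is.na(tab$pvalue[1:3])))
  rl <- rankedList(res)
  expect_false(any(sprintf("g%04d", 1:3) %in% rl$gene))
  expect_true(all(diff(rl$score) <= 0))
})
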