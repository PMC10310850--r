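test_that("RIN filtering removes exactly the low-quality samples", {
  st <- simulateSpatiotemporal(nGenes = 50, seed = 1)
  f <- filterSamples(st$expr, st$meta)
  expect_equal(ncol(f$expr), sum(st$meta$RIN >= 9))
  expect_true(all(f$meta$RIN >= 9))
  allHigh <- filterSamples(st$expr, transform(st$meta, RIN = 9.5))
  expect_equal(ncol(allHigh$expr), ncol(st$expr))
  expect_warning(filterSamples(st$expr, transform(st$meta, RIN = 5)),
                 "no sample passes")
})

test_that("the gene filter applies the expression and variability rules", {
  expr <- rbind(
    zero = rep(0, 10),                      # never expressed: removed
    high = c(10, 12, 8, 11, 9, 10, 14, 9, 10, 12),  # ubiquitous: kept
    rareFlat = c(0.4, 0.41, 0.39, 0.4, 0, 0, 0, 0, 0, 0),
    rareVar = c(9, 0.5, 4, 0, 0, 0, 0, 0, 0, 0))
  # manual application: zero fails expression; rareFlat is rare (4/10
  # positive) with CV < 0.25 only if computed on its values... check by rule
  kept <- filterGenes(expr, minFpkm = 0.3, minSamples = 2)
  expect_false("zero" %in% rownames(kept))
  expect_true("high" %in% rownames(kept))
  expect_true("rareVar" %in% rownames(kept))  # rare but variable: kept
  cvRareFlat <- sd(expr["rareFlat", ]) / mean(expr["rareFlat", ])
  expect_gt(cvRareFlat, 0.25)  # CV over all samples keeps it too
  expect_true("rareFlat" %in% rownames(kept))
  # under the disjunctive reading the rare gene goes regardless of CV
  strict <- filterGenes(expr, minFpkm = 0.3, minSamples = 2,
                        requireBoth = FALSE)
  expect_false("rareFlat" %in% rownames(strict))
})

test_that("identical profiles co-cluster and opposite profiles separate", {
  st <- simulateSpatiotemporal(nGenes = 60, seed = 2)
  expr <- st$expr
  cells <- cellMeans(expr, st$meta)
  # construct two mirrored groups on top of the simulated backdrop
  up <- seq(1, 2, length.out = ncol(cells))
  expr["g0001", ] <- 2^(up[match(paste(st$meta$region, st$meta$period,
                                       sep = "|"), colnames(cells))] * 3)
  expr["g0002", ] <- expr["g0001", ] * 1.7
  expr["g0003", ] <- 1 / expr["g0001", ]
  cl <- clusterGeneList(expr, st$meta, c("g0001", "g0002", "g0003"), k = 2)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[1] == cl$cluster[3])
})

test_that("average-linkage merges follow the brute-force nearest-pair oracle", {
  set.seed(3)
  st <- simulateSpatiotemporal(nGenes = 30, seed = 3)
  genes <- rownames(st$expr)[1:6]
  prof <- cellMeans(st$expr[genes, ], st$meta)
  z <- t(scale(t(prof)))
  D <- 1 - cor(t(z))
  # naive agglomeration with average linkage over the 6 items, recording
  # the partition after each merge
  clusters <- as.list(1:6)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dd < bestd) { bestd <- dd; best <- c(j, i) }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, sort)
  }
  hc <- hclust(as.dist(D), method = "average")
  canonical <- function(part) {
    paste(sort(vapply(part, paste, "", collapse = ",")), collapse = "|")
  }
  for (k in 2:5) {
    ct <- cutree(hc, k = k)
    hcPart <- unname(split(seq_len(6), ct))
    expect_equal(canonical(hcPart),
                 canonical(partitions[[6 - k]]), info = paste("k =", k))
  }
})

test_that("permutation p-values match complete enumeration on a 5-gene universe", {
  # universe of 5 genes, group of 2: the null has choose(5,2) = 10 subsets
  meta <- data.frame(sample = c("s1", "s2"), region = c("R1", "R2"),
                     period = c("P1", "P1"), RIN = 10)
  expr <- matrix(c(10, 1,
                   8, 2,
                   6, 3,
                   4, 4,
                   2, 5), 5, 2, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), meta$sample))
  group <- c("g1", "g2")  # observed mean in R1|P1 = 9
  combos <- combn(5, 2)
  nullMeans <- apply(combos, 2, function(ix) mean(expr[ix, 1]))
  pExact <- mean(nullMeans >= 9)  # 1/10: only {g1,g2} reaches 9
  grid <- permutationEnrichment(expr, meta, group, B = 20000, seed = 5)
  pHat <- gridP(grid)["R1", "P1"]
  expect_lt(abs(pHat - pExact), 0.01)
  # cell R2: group mean 1.5 is the smallest; all 10 subsets reach it
  expect_gt(gridP(grid)["R2", "P1"], 0.95)
})

test_that("a maximal group attains the smallest attainable p everywhere", {
  set.seed(6)
  meta <- expand.grid(rep = 1:2, region = c("R1", "R2"),
                      period = c("P1", "P2"), stringsAsFactors = FALSE)
  meta$sample <- sprintf("s%02d", seq_len(nrow(meta)))
  meta$RIN <- 10
  expr <- matrix(rlnorm(50 * nrow(meta)), 50,
                 dimnames = list(sprintf("g%02d", 1:50), meta$sample))
  expr[1:5, ] <- expr[1:5, ] + 1000  # dominates every cell
  grid <- permutationEnrichment(expr, meta, sprintf("g%02d", 1:5),
                                B = 999, seed = 7)
  expect_true(all(gridP(grid) == 1 / 1000))
})

test_that("null grids stay quiet after BH adjustment", {
  st <- simulateSpatiotemporal(nGenes = 400, seed = 8)
  f <- filterSamples(st$expr, st$meta)
  grid <- permutationEnrichment(f$expr, f$meta,
                                rownames(f$expr)[1:25], B = 1000, seed = 9)
  expect_lte(sum(gridPadj(grid) < 0.05), 1)
  expect_gt(mean(gridP(grid) > 0.3), 0.4)
  expect_error(permutationEnrichment(f$expr, f$meta, c("nope"), B = 10),
               "missing from the expression matrix")
})
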