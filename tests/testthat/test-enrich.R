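test_that("the unweighted ES matches exhaustive evaluation on tiny lists", {
  ranked <- data.frame(gene = c("a", "b", "c", "d", "e"),
                       score = c(3, 2, 1, -1, -2))
  for (set in list(c("a", "b"), c("a", "e"), c("d", "e"), c("b", "d"),
                   c("c"))) {
    es <- gseaES(ranked, set, exponent = 0)$ES
    expect_equal(es, bruteES(ranked$gene, set), info = paste(set, collapse = ","))
  }
})

test_that("a set made of the top genes peaks at their last rank", {
  ranked <- data.frame(gene = sprintf("g%02d", 1:20),
                       score = seq(10, 0.5, length.out = 20))
  res <- gseaES(ranked, sprintf("g%02d", 1:5))
  expect_gt(res$ES, 0)
  expect_equal(which.max(res$runningSum), 5L)
})

test_that("reversing the ranking negates the exponent-0 ES and scaling leaves it fixed", {
  ranked <- data.frame(gene = letters[1:10], score = c(5:1, -(1:5)))
  set <- c("a", "b", "i")
  es <- gseaES(ranked, set, exponent = 0)$ES
  rev <- ranked[nrow(ranked):1, ]
  rev$score <- -rev$score
  expect_equal(gseaES(rev, set, exponent = 0)$ES, -es)
  scaled <- ranked
  scaled$score <- scaled$score * 7.3
  expect_equal(gseaES(scaled, set, exponent = 0)$ES, es)
  expect_error(gseaES(ranked, c("zz")), "empty intersection")
})

test_that("the weighted ES agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(20)
  scores <- sort(rnorm(100), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("g%03d", 1:100), score = scores)
  for (i in 1:5) {
    idx <- sort(sample(100, 12))
    mine <- gseaES(ranked, ranked$gene[idx], exponent = 1)$ES
    ref <- fgsea::calcGseaStat(scores, selectedStats = idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("permutation significance flags a planted set and is seeded", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:300)
  scores <- sort(rnorm(300), decreasing = TRUE)
  ranked <- data.frame(gene = genes, score = scores)
  coll <- c(list(planted = genes[1:20]),
            setNames(lapply(1:6, function(i) sample(genes, 20)),
                     paste0("rand", 1:6)))
  res <- gseaSignificance(ranked, coll, nPerm = 1000, seed = 3)
  expect_lt(res$qvalue[res$set == "planted"], 0.05)
  expect_equal(res$direction[res$set == "planted"], "up")
  expect_true(all(sign(res$NES) == sign(res$ES)))
  expect_true(all(res$qvalue >= 0 & res$qvalue <= 1))
  res2 <- gseaSignificance(ranked, coll, nPerm = 1000, seed = 3)
  expect_identical(res, res2)
})

test_that("permutation p-values are roughly uniform for random sets", {
  set.seed(22)
  genes <- sprintf("g%03d", 1:200)
  ranked <- data.frame(gene = genes,
                       score = sort(rnorm(200), decreasing = TRUE))
  coll <- setNames(lapply(1:40, function(i) sample(genes, 15)),
                   paste0("s", 1:40))
  res <- gseaSignificance(ranked, coll, nPerm = 200, seed = 4)
  expect_lt(mean(res$pvalue < 0.05), 0.2)
  expect_gt(mean(res$pvalue > 0.5), 0.2)
})

test_that("set similarity combines Jaccard and overlap as printed", {
  a <- c("g1", "g2", "g3", "g4")
  b <- c("g3", "g4", "g5")
  # |int| = 2, |union| = 5, min size = 3
  expect_equal(setSimilarity(a, b), 0.5 * 2 / 5 + 0.5 * 2 / 3)
  expect_equal(setSimilarity(a, a), 1)
  expect_equal(setSimilarity(a, c("x", "y")), 0)
  c3 <- c("g1", "g2")
  expect_equal(setSimilarity(a, c3), 0.5 * 2 / 4 + 0.5 * 1)  # subset: overlap 1
})

test_that("similarity networks respect thresholds and report empty results", {
  coll <- list(A = sprintf("g%02d", 1:10), B = sprintf("g%02d", 3:12),
               C = sprintf("g%02d", 40:50))
  res <- data.frame(set = c("A", "B", "C"), qvalue = c(0.01, 0.02, 0.03),
                    direction = "up")
  net <- buildSimilarityNetwork(res, coll)
  expect_equal(nrow(networkNodes(net)), 3L)
  expect_equal(igraph::ecount(networkGraph(net)), 1L)  # only A-B passes 0.375
  none <- buildSimilarityNetwork(
    data.frame(set = "A", qvalue = 0.9, direction = "up"), coll)
  expect_equal(nrow(networkNodes(none)), 0L)
  expect_output(show(none), "no network")
  down <- buildSimilarityNetwork(res, coll, direction = "down")
  expect_equal(nrow(networkNodes(down)), 0L)
})

test_that("network metrics match closed forms on canonical graphs", {
  tri <- adjToPathwayNetwork(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  m <- networkMetrics(tri)
  expect_equal(m$diameter, 1)
  expect_equal(m$clusteringCoefficient, 1)
  expect_equal(m$averageDegree, 2)
  expect_equal(m$density, 1)
  path <- adjToPathwayNetwork(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  mp <- networkMetrics(path)
  expect_equal(mp$diameter, 2)
  expect_equal(mp$clusteringCoefficient, 0)
})

test_that("network metrics equal the all-pairs-BFS / triangle-count oracle", {
  for (seed in 1:3) {
    adj <- randomGraphAdj(30, 0.12, seed)
    mine <- networkMetrics(adjToPathwayNetwork(adj))
    oracle <- bruteMetrics(adj)
    for (k in names(oracle)) {
      expect_equal(mine[[k]], oracle[[k]], info = paste(seed, k))
    }
  }
})

test_that("cluster summaries follow connected components deterministically", {
  adj <- matrix(0L, 6, 6)
  adj[1:3, 1:3] <- 1L; adj[4:6, 4:6] <- 1L; diag(adj) <- 0L
  net <- adjToPathwayNetwork(adj)
  cl <- summarizeClusters(net)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$size, c(3L, 3L))
  empty <- buildSimilarityNetwork(
    data.frame(set = character(0), qvalue = numeric(0),
               direction = character(0)), list())
  expect_equal(nrow(summarizeClusters(empty)), 0L)
})

test_that("hypergeometric p equals complete enumeration on small universes", {
  bg <- sprintf("g%02d", 1:18)
  target <- bg[1:6]
  hits <- bg[c(1, 2, 3, 10)]
  h <- hypergeomEnrichment(hits, target, bg)
  expect_equal(h$p, bruteHyper(3, 6, 4, 18), tolerance = 1e-12)
  # all hits inside the target
  h2 <- hypergeomEnrichment(bg[1:3], target, bg)
  expect_equal(h2$p, bruteHyper(3, 6, 3, 18), tolerance = 1e-12)
  expect_equal(hypergeomEnrichment(hits, c("zz1", "zz2"), bg)$p, 1)
  expect_equal(hypergeomEnrichment(bg, bg[1:5], bg)$p, 1)
  expect_error(hypergeomEnrichment(c("nope"), target, bg),
               "background misspecification")
})

test_that("ORA across curated lists applies BH over the lists", {
  bg <- sprintf("g%03d", 1:100)
  targets <- list(big = bg[1:30], none = c("x1", "x2"), small = bg[1:5])
  res <- oraTest(bg[1:10], targets, bg)
  expect_equal(nrow(res), 3L)
  expect_equal(res$padj, bruteBH(res$pvalue))
  expect_equal(res$pvalue[res$list == "none"], 1)
})
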