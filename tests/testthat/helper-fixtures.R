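# shared fixtures and independent brute-force oracles

l8Design <- function() assignFactors(buildL8())

studySheet <- function() ffedStudySheet(l8Design())

# all permutations of a vector, one per row
colsPermutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- colsPermutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# brute-force Benjamini-Hochberg step-up
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# brute-force global network metrics: all-pairs BFS and triangle counting
# on an adjacency matrix
bruteMetrics <- function(adj) {
  n <- nrow(adj)
  e <- sum(adj) / 2
  bfs <- function(s) {
    dist <- rep(Inf, n); dist[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
      }
    }
    dist
  }
  dmat <- t(vapply(seq_len(n), bfs, numeric(n)))
  comp <- rep(NA_integer_, n); k <- 0
  for (v in seq_len(n)) if (is.na(comp[v])) {
    k <- k + 1; comp[is.finite(dmat[v, ])] <- k
  }
  big <- which(comp == which.max(tabulate(comp)))
  diam <- if (length(big) > 1) max(dmat[big, big]) else 0
  localCC <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  list(nodes = n, edges = e, diameter = diam,
       density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
       clusteringCoefficient = mean(localCC), averageDegree = 2 * e / n)
}

# exhaustive unweighted KS walk over a printed ranking
bruteES <- function(genes, geneSet) {
  hit <- genes %in% geneSet
  nh <- sum(hit)
  step <- ifelse(hit, 1 / nh, -1 / (length(genes) - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

# exact hypergeometric upper tail by complete enumeration of subsets
bruteHyper <- function(k, K, n, N) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / total
}

randomGraphAdj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

adjToPathwayNetwork <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::set_vertex_attr(g, "name",
                               value = paste0("set", seq_len(nrow(adj))))
  new("PathwayNetwork", graph = g,
      nodes = data.frame(set = paste0("set", seq_len(nrow(adj))),
                         q = 0.01, direction = "up"),
      cutoff = 0.375)
}
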