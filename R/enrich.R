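#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing by the hit's
#' |score|^exponent (normalized so hits sum to 1) at member genes and
#' decrementing by 1/(N - set size) elsewhere. The enrichment score is the
#' running-sum extremum of largest absolute value; its sign indicates the
#' end of the list where the set concentrates.
#'
#' @param ranked data.frame (gene, score) in descending score order, or a
#'   named numeric vector of scores.
#' @param geneSet character vector of member gene ids.
#' @param exponent hit weighting exponent (0 = classic unweighted KS walk).
#' @return list: ES, runningSum (length N), hitIndex.
#' @export
gseaES <- function(ranked, geneSet, exponent = 1) {
  if (is.numeric(ranked)) {
    ranked <- data.frame(gene = names(ranked), score = unname(ranked),
                         stringsAsFactors = FALSE)
    ranked <- ranked[order(-ranked$score, ranked$gene), ]
  }
  genes <- ranked$gene
  scores <- ranked$score
  N <- length(genes)
  hit <- genes %in% geneSet
  Nh <- sum(hit)
  if (Nh == 0L) stop("gene set has empty intersection with the ranked list")
  w <- abs(scores)^exponent
  w[!hit] <- 0
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else as.numeric(hit) / Nh  # all-zero scores: flat weights
  dec <- rep(1 / (N - Nh), N)
  dec[hit] <- 0
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  list(ES = es, runningSum = running, hitIndex = which(hit))
}

#' Permutation significance for preranked enrichment
#'
#' A gene-permutation null: for each set, `nPerm` random gene sets of
#' matched size are scored on the same ranking. The nominal p-value is the
#' add-one-corrected tail proportion among same-sign null scores, NES is
#' the observed ES divided by the mean same-sign null ES, and the FDR q is
#' the GSEA-style ratio of null to observed NES tail frequencies, clipped
#' to [0, 1].
#'
#' @param ranked data.frame (gene, score), descending.
#' @param collection named list of gene-id vectors.
#' @param nPerm permutations per set (default 1000).
#' @param exponent hit weighting exponent.
#' @param seed integer seed.
#' @return data.frame: set, size, ES, NES, pvalue, qvalue, direction.
#' @export
gseaSignificance <- function(ranked, collection, nPerm = 1000L, exponent = 1,
                             seed = 1L) {
  stopifnot(length(collection) > 0L, !is.null(names(collection)))
  set.seed(seed)
  genes <- ranked$gene
  N <- length(genes)
  obs <- vapply(collection, function(s) gseaES(ranked, s, exponent)$ES,
                numeric(1))
  sizes <- vapply(collection, function(s) sum(genes %in% s), integer(1))

  nullES <- matrix(NA_real_, nPerm, length(collection))
  for (j in seq_along(collection)) {
    k <- sizes[j]
    for (b in seq_len(nPerm)) {
      nullES[b, j] <- gseaES(ranked, sample(genes, k), exponent)$ES
    }
  }

  p <- nes <- numeric(length(collection))
  nullNES <- nullES
  for (j in seq_along(collection)) {
    nu <- nullES[, j]
    posMean <- mean(nu[nu >= 0])
    negMean <- mean(abs(nu[nu < 0]))
    nullNES[, j] <- ifelse(nu >= 0,
                           nu / ifelse(is.nan(posMean), 1, posMean),
                           nu / ifelse(is.nan(negMean), 1, negMean))
    if (obs[j] >= 0) {
      same <- nu[nu >= 0]
      p[j] <- (1 + sum(same >= obs[j])) / (1 + length(same))
      nes[j] <- obs[j] / ifelse(is.nan(posMean) || posMean == 0, 1, posMean)
    } else {
      same <- nu[nu < 0]
      p[j] <- (1 + sum(same <= obs[j])) / (1 + length(same))
      nes[j] <- -abs(obs[j]) / ifelse(is.nan(negMean) || negMean == 0, 1, negMean)
    }
  }

  allNull <- as.vector(nullNES)
  q <- numeric(length(collection))
  for (j in seq_along(collection)) {
    if (nes[j] >= 0) {
      nullTail <- sum(allNull >= nes[j]) / max(sum(allNull >= 0), 1L)
      obsTail <- sum(nes >= nes[j]) / max(sum(nes >= 0), 1L)
    } else {
      nullTail <- sum(allNull <= nes[j]) / max(sum(allNull < 0), 1L)
      obsTail <- sum(nes <= nes[j]) / max(sum(nes < 0), 1L)
    }
    q[j] <- min(max(nullTail / max(obsTail, .Machine$double.eps), 0), 1)
  }

  data.frame(set = names(collection), size = sizes, ES = unname(obs),
             NES = nes, pvalue = p, qvalue = q,
             direction = ifelse(obs >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combined set-similarity coefficient
#'
#' The enrichment-map similarity: 0.5 x Jaccard + 0.5 x overlap
#' coefficient.
#'
#' @param a,b gene-id vectors.
#' @return similarity in [0, 1].
#' @export
setSimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  if (i == 0L) return(0)
  0.5 * i / length(union(a, b)) + 0.5 * i / min(length(a), length(b))
}

#' Build a gene-set similarity network from enrichment results
#'
#' Nodes are the gene sets passing the FDR threshold (optionally split by
#' direction); edges join pairs whose combined Jaccard/overlap similarity
#' reaches `cutoff`. When no set passes, an explicit empty "no network"
#' object is returned (the study's ASD downregulation contrast is exactly
#' this case).
#'
#' @param results data.frame from [gseaSignificance()].
#' @param collection the gene-set collection the results refer to.
#' @param qThreshold FDR threshold for node inclusion (default 0.05).
#' @param cutoff similarity cutoff for edges (default 0.375, the
#'   EnrichmentMap default).
#' @param direction "up", "down" or "both".
#' @return a \linkS4class{PathwayNetwork}.
#' @export
buildSimilarityNetwork <- function(results, collection, qThreshold = 0.05,
                                   cutoff = 0.375, direction = "both") {
  keep <- results$qvalue < qThreshold
  if (direction != "both") keep <- keep & results$direction == direction
  nodes <- results[keep, c("set", "qvalue", "direction")]
  names(nodes) <- c("set", "q", "direction")
  rownames(nodes) <- NULL
  if (nrow(nodes) == 0L) {
    return(new("PathwayNetwork", graph = igraph::make_empty_graph(0),
               nodes = nodes, cutoff = cutoff))
  }
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$set)
  if (nrow(nodes) > 1L) {
    pairs <- utils::combn(nrow(nodes), 2L)
    sims <- apply(pairs, 2L, function(ij)
      setSimilarity(collection[[nodes$set[ij[1]]]],
                    collection[[nodes$set[ij[2]]]]))
    sel <- sims >= cutoff
    if (any(sel)) {
      g <- igraph::add_edges(g, as.vector(pairs[, sel, drop = FALSE]))
      g <- igraph::set_edge_attr(g, "similarity", value = sims[sel])
    }
  }
  new("PathwayNetwork", graph = g, nodes = nodes, cutoff = cutoff)
}

#' Global network metrics
#'
#' Total nodes, total edges, diameter (longest shortest path on the largest
#' connected component), density 2E/(N(N-1)), clustering coefficient
#' (mean local by default; set `clustering = "global"` for transitivity)
#' and average degree 2E/N.
#'
#' @param net a \linkS4class{PathwayNetwork} or an igraph object.
#' @param clustering "local" (mean local coefficient, isolated and
#'   degree-1 nodes counting 0) or "global" (transitivity).
#' @return named list of the six metrics.
#' @export
networkMetrics <- function(net, clustering = c("local", "global")) {
  clustering <- match.arg(clustering)
  g <- if (is(net, "PathwayNetwork")) networkGraph(net) else net
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    return(list(nodes = 0L, edges = 0L, diameter = NA_real_, density = NA_real_,
                clusteringCoefficient = NA_real_, averageDegree = NA_real_))
  }
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comp$membership ==
                                           which.max(comp$csize)))
  diam <- if (igraph::vcount(big) > 1L)
    igraph::diameter(big, directed = FALSE, unconnected = FALSE) else 0
  cc <- if (clustering == "local") {
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    lc[is.na(lc)] <- 0
    mean(lc)
  } else {
    tc <- igraph::transitivity(g, type = "global")
    if (is.nan(tc)) 0 else tc
  }
  list(nodes = n, edges = e, diameter = as.numeric(diam),
       density = if (n > 1L) 2 * e / (n * (n - 1)) else 0,
       clusteringCoefficient = cc, averageDegree = 2 * e / n)
}

tokenStopwords <- c("of", "the", "and", "to", "in", "a", "by", "via",
                    "process", "regulation", "positive", "negative")

#' Deterministic cluster summary of a pathway network
#'
#' Clusters by connected components (default) or greedy modularity and
#' labels each cluster with the most frequent non-stopword tokens of its
#' member set names. Fully deterministic.
#'
#' @param net a \linkS4class{PathwayNetwork}.
#' @param method "components" or "modularity".
#' @param nTokens tokens per label.
#' @return data.frame: cluster, label, size, members (";"-joined).
#' @export
summarizeClusters <- function(net, method = c("components", "modularity"),
                              nTokens = 3L) {
  method <- match.arg(method)
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0L) {
    return(data.frame(cluster = integer(0), label = character(0),
                      size = integer(0), members = character(0)))
  }
  membership <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    igraph::membership(igraph::cluster_fast_greedy(g))
  }
  sets <- igraph::vertex_attr(g, "name")
  out <- lapply(sort(unique(membership)), function(k) {
    mem <- sort(sets[membership == k])
    toks <- tolower(unlist(strsplit(gsub("[^[:alnum:] ]", " ", mem), "\\s+")))
    toks <- toks[nzchar(toks) & !toks %in% tokenStopwords]
    tab <- sort(table(toks), decreasing = TRUE)
    lab <- paste(utils::head(names(tab)[order(-tab, names(tab))], nTokens),
                 collapse = " ")
    data.frame(cluster = k, label = lab, size = length(mem),
               members = paste(mem, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability P(X >= k) of drawing k target
#' genes in a hit list of size n from a background of size N containing K
#' target genes. The target list is intersected with the background first;
#' hits outside the background are an error (a misspecified background).
#'
#' @param hits character vector of hit gene ids (must be within
#'   `background`).
#' @param target character vector, the curated list tested against.
#' @param background character vector, the expressed-gene universe (the
#'   study used genes with base mean > 20).
#' @return list: p, k, K, n, N.
#' @export
hypergeomEnrichment <- function(hits, target, background) {
  hits <- unique(hits); target <- unique(target); background <- unique(background)
  if (!all(hits %in% background))
    stop("hits are not a subset of the background (background misspecification)")
  N <- length(background)
  K <- length(intersect(target, background))
  n <- length(hits)
  k <- length(intersect(hits, target))
  p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = min(p, 1), k = k, K = K, n = n, N = N)
}

#' Over-representation across several curated lists
#'
#' Runs [hypergeomEnrichment()] for each target list and BH-adjusts across
#' lists.
#'
#' @param hits,background as in [hypergeomEnrichment()].
#' @param targets named list of curated gene lists.
#' @return data.frame: list, k, K, n, N, pvalue, padj.
#' @export
oraTest <- function(hits, targets, background) {
  stopifnot(length(targets) > 0L, !is.null(names(targets)))
  rows <- lapply(names(targets), function(nm) {
    h <- hypergeomEnrichment(hits, targets[[nm]], background)
    data.frame(list = nm, k = h$k, K = h$K, n = h$n, N = h$N, pvalue = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out
}
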