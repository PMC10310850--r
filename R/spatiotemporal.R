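#' Remove low-quality samples by RNA integrity
#'
#' @param expr genes x samples matrix.
#' @param meta data.frame with columns sample, region, period, RIN matching
#'   the matrix columns.
#' @param rinMin samples with RIN below this are dropped (default 9.0).
#' @return list(expr, meta) with low-RIN samples removed; warns when
#'   nothing survives.
#' @export
filterSamples <- function(expr, meta, rinMin = 9.0) {
  stopifnot(ncol(expr) == nrow(meta))
  keep <- meta$RIN >= rinMin
  if (!any(keep)) warning("no sample passes the RIN filter")
  list(expr = expr[, keep, drop = FALSE], meta = meta[keep, , drop = FALSE])
}

#' Expression and variability gene filter
#'
#' Keeps genes expressed at or above `minFpkm` in at least `minSamples`
#' samples, and removes genes that are both rarely detected (positive in
#' fewer than `presenceFrac` of samples) and weakly variable (coefficient
#' of variation below `cvMin`).
#'
#' @param expr genes x samples matrix (FPKM scale).
#' @param minFpkm,minSamples expression floor and required sample count.
#' @param presenceFrac detection fraction under which a gene is "rare".
#' @param cvMin CV (sd/mean) floor for rare genes.
#' @param requireBoth if FALSE, the rare-and-flat clause alone decides
#'   removal (the filter sentence is ambiguous; the conjunctive reading is
#'   the default).
#' @return the filtered matrix.
#' @export
filterGenes <- function(expr, minFpkm = 1, minSamples = 2,
                        presenceFrac = 0.5, cvMin = 0.25,
                        requireBoth = TRUE) {
  expressed <- rowSums(expr >= minFpkm) >= minSamples
  rare <- rowMeans(expr > 0) < presenceFrac
  cv <- apply(expr, 1L, function(x) {
    m <- mean(x)
    if (m == 0) 0 else stats::sd(x) / m
  })
  flat <- cv < cvMin
  drop <- if (requireBoth) rare & flat else rare | flat
  expr[expressed & !drop, , drop = FALSE]
}

#' Mean expression per region-by-period cell
#'
#' @param expr genes x samples matrix.
#' @param meta sample metadata (sample, region, period).
#' @return genes x cells matrix; cell columns named "region|period".
#' @export
cellMeans <- function(expr, meta) {
  cellKey <- paste(meta$region, meta$period, sep = "|")
  keys <- unique(cellKey)
  m <- vapply(keys, function(k)
    rowMeans(expr[, cellKey == k, drop = FALSE]), numeric(nrow(expr)))
  dimnames(m) <- list(rownames(expr), keys)
  m
}

#' Two-cluster grouping of a gene list by spatio-temporal profile
#'
#' Each gene's mean expression per region-by-period cell is z-standardized
#' across cells; genes are grouped by agglomerative hierarchical clustering
#' (average linkage on correlation distance 1 - r) cut at `k`.
#'
#' @param expr,meta as in [cellMeans()].
#' @param genes gene ids to cluster (subset of rownames(expr)).
#' @param k number of clusters (default 2).
#' @return data.frame: gene, cluster.
#' @export
clusterGeneList <- function(expr, meta, genes, k = 2L) {
  stopifnot(all(genes %in% rownames(expr)))
  prof <- cellMeans(expr[genes, , drop = FALSE], meta)
  z <- t(scale(t(prof)))
  z[is.na(z)] <- 0
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  data.frame(gene = genes, cluster = stats::cutree(hc, k = k),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation enrichment of a gene group over the region-by-period grid
#'
#' For each region-by-period cell, the observed statistic is the mean
#' expression of the group's genes; the null is the mean of B random gene
#' sets of matched size drawn uniformly from the matrix. The p-value is
#' the add-one-corrected upper-tail proportion p = (1 + #\{null >=
#' observed\}) / (B + 1) (ties count against enrichment), so small p means
#' the group is expressed above chance in that cell; the literal
#' higher-than-random proportion is available as `score = 1 - p`. BH
#' adjustment runs across all grid cells.
#'
#' @param expr genes x samples matrix (post filtering).
#' @param meta sample metadata (sample, region, period).
#' @param genes the gene group (must be present in the matrix).
#' @param B permutation count (the study used 10,000).
#' @param seed integer seed.
#' @return an \linkS4class{EnrichmentGrid} (regions as rows, periods as
#'   columns).
#' @export
permutationEnrichment <- function(expr, meta, genes, B = 10000L, seed = 1L) {
  if (!all(genes %in% rownames(expr)))
    stop("group genes missing from the expression matrix")
  m <- length(genes)
  if (m > nrow(expr)) stop("group larger than the gene universe")
  set.seed(seed)
  cm <- cellMeans(expr, meta)
  regions <- unique(meta$region)
  periods <- unique(meta$period)
  keyOrder <- as.vector(outer(regions, periods, paste, sep = "|"))
  keyOrder <- keyOrder[keyOrder %in% colnames(cm)]
  cm <- cm[, keyOrder, drop = FALSE]

  obs <- colMeans(cm[genes, , drop = FALSE])
  exceed <- integer(length(obs))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(cm), m)
    exceed <- exceed + as.integer(colMeans(cm[idx, , drop = FALSE]) >= obs)
  }
  p <- (1 + exceed) / (B + 1)
  padj <- stats::p.adjust(p, method = "BH")

  shape <- function(v) {
    mt <- matrix(NA_real_, length(regions), length(periods),
                 dimnames = list(regions, periods))
    for (i in seq_along(v)) {
      rp <- strsplit(names(obs)[i], "|", fixed = TRUE)[[1]]
      mt[rp[1], rp[2]] <- v[i]
    }
    mt
  }
  names(p) <- names(padj) <- names(obs)
  new("EnrichmentGrid", observed = shape(obs), p = shape(p),
      padj = shape(padj), B = as.integer(B), groupSize = as.integer(m))
}
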