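#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's counts are divided by the
#' per-gene geometric mean across samples, and the size factor is the median
#' of those ratios over reference genes (genes with all-positive counts).
#' If no gene is positive in every sample, the estimator falls back to
#' genes positive in at least half the samples, with geometric means taken
#' over their positive entries (a message is emitted).
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return positive numeric vector of length ncol(counts).
#' @export
sizeFactorsMoR <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (any(allPos)) {
    ref <- counts[allPos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    s <- apply(ref / geo, 2L, stats::median)
  } else {
    message("no gene expressed in all samples; ",
            "falling back to positive-count subset")
    keep <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(keep)) stop("no usable reference genes for size factors")
    ref <- counts[keep, , drop = FALSE]
    geo <- exp(apply(ref, 1L, function(r) mean(log(r[r > 0]))))
    rat <- ref / geo
    rat[ref == 0] <- NA
    s <- apply(rat, 2L, stats::median, na.rm = TRUE)
  }
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size factor estimation failed (nonpositive factor)")
  unname(s)
}

#' Per-gene dispersion estimation
#'
#' Method-of-moments estimate of the NB dispersion alpha (variance
#' mu + alpha mu^2) on size-factor-normalized counts, residual-df corrected
#' for the number of model coefficients, then shrunk toward a fitted
#' mean-dispersion trend alpha(mu) = a0/mu + a1 with weight
#' `trendWeight`. Estimates are floored at 1e-8.
#'
#' @param counts genes x samples integer matrix.
#' @param modelMatrix samples x p design matrix used for the gene-wise mean
#'   fit.
#' @param sizeFactors per-sample factors; computed if missing.
#' @param trendWeight blend weight of the trend (0 = raw MoM, 1 = pure
#'   trend); default 0.5.
#' @return numeric vector of per-gene dispersions.
#' @export
estimateDispersion <- function(counts, modelMatrix,
                               sizeFactors = sizeFactorsMoR(counts),
                               trendWeight = 0.5) {
  stopifnot(nrow(modelMatrix) == ncol(counts))
  q <- sweep(counts, 2L, sizeFactors, `/`)
  n <- ncol(q)
  p <- qr(modelMatrix)$rank
  if (n - p <= 0) stop("no residual degrees of freedom for dispersion")
  # gene-wise means come from a Poisson GLM pre-fit (the model is
  # multiplicative; a linear- or log-scale projection would bias the
  # residual moments); a count-scale floor keeps the moment ratio stable
  qhat <- matrix(0, nrow(counts), ncol(counts))
  for (i in seq_len(nrow(counts))) {
    fit <- tryCatch(fitNBGLM(counts[i, ], modelMatrix, 0, sizeFactors,
                             tol = 1e-4, maxit = 25L),
                    error = function(e) NULL)
    qhat[i, ] <- if (is.null(fit)) rep(mean(q[i, ]), ncol(q))
                 else fit$fitted / sizeFactors
  }
  qhat[qhat < 0.1] <- 0.1
  resid2 <- (q - qhat)^2
  # E[(q - mu)^2] = mu/s + alpha mu^2 per observation
  shot <- sweep(qhat, 2L, sizeFactors, `/`)
  alphaMoM <- rowSums((resid2 - shot) / qhat^2) / (n - p)
  alphaMoM[!is.finite(alphaMoM)] <- 0
  alphaMoM <- pmin(pmax(alphaMoM, 0), 20)

  bm <- rowMeans(q)
  use <- bm > 0
  # robust trend: per-decile medians tame the heavy right tail of the MoM
  tr <- tryCatch({
    dec <- cut(rank(bm[use], ties.method = "first"),
               breaks = 10L, labels = FALSE)
    medA <- tapply(alphaMoM[use], dec, stats::median)
    medB <- tapply(bm[use], dec, stats::median)
    fit <- stats::lm(medA ~ I(1 / medB))
    a1 <- max(unname(stats::coef(fit)[1]), 0)
    a0 <- max(unname(stats::coef(fit)[2]), 0)
    c(a0 = a0, a1 = a1)
  }, error = function(e) c(a0 = 0, a1 = stats::median(alphaMoM[use])))
  trend <- tr["a0"] / pmax(bm, 1e-8) + tr["a1"]
  alpha <- (1 - trendWeight) * alphaMoM + trendWeight * trend
  pmax(alpha, 1e-8)
}

#' Negative-binomial log-likelihood
#'
#' @param y observed counts.
#' @param mu fitted means.
#' @param alpha dispersion (variance mu + alpha mu^2); alpha -> 0 recovers
#'   the Poisson likelihood.
#' @return total log-likelihood.
#' @export
nbLogLik <- function(y, mu, alpha) {
  if (alpha < 1e-10) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Fit a log-link negative-binomial GLM for one gene
#'
#' Iteratively reweighted least squares with known dispersion and log
#' size-factor offset. Convergence when the largest coefficient change
#' falls below `tol` (default 1e-6) or after `maxit` iterations;
#' non-convergence is flagged, not fatal.
#'
#' @param y integer counts for one gene (length = samples).
#' @param X model matrix (samples x p), full column rank.
#' @param alpha NB dispersion for this gene.
#' @param sizeFactors per-sample normalization factors.
#' @param tol,maxit convergence controls.
#' @return list: coefficients (natural-log scale), cov (inverse Fisher
#'   information), converged, fitted (means), logLik.
#' @export
fitNBGLM <- function(y, X, alpha, sizeFactors = rep(1, length(y)),
                     tol = 1e-6, maxit = 100L) {
  stopifnot(length(y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("model matrix is rank deficient; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  off <- log(sizeFactors)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- qr.coef(qrX, eta - off)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    xtwx <- crossprod(X, w * X)
    newBeta <- tryCatch(solve(xtwx, crossprod(X, w * z)),
                        error = function(e) NULL)
    if (is.null(newBeta)) break
    delta <- max(abs(newBeta - beta))
    beta <- drop(newBeta)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + off
  mu <- exp(pmin(pmax(eta, -30), 30))
  w <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(crossprod(X, w * X)), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  names(beta) <- colnames(X)
  list(coefficients = beta, cov = cov, converged = converged, fitted = mu,
       logLik = nbLogLik(y, mu, alpha))
}

exposureIndicator <- function(sheet, factorName, design) {
  x <- exposureCoding(sheet, design)
  if (!factorName %in% colnames(x))
    stop("unknown factor: ", factorName)
  as.numeric(x[, factorName] > 0)
}

levelModelMatrix <- function(sheet, level, factorName, design,
                             blockCellLine = FALSE) {
  if (level %in% c("I", "II", "III")) {
    exposure <- exposureIndicator(sheet, factorName, design)
    if (length(unique(exposure)) < 2L)
      stop("exposure is constant within the analysed subset")
    if (blockCellLine && length(unique(sheet$cellLine)) > 1L) {
      X <- stats::model.matrix(~ cellLine + exposure,
                               data.frame(cellLine = factor(sheet$cellLine),
                                          exposure = exposure))
    } else {
      X <- cbind(`(Intercept)` = 1, exposure = exposure)
    }
    list(X = X, coef = "exposure")
  } else {
    pair <- strsplit(factorName, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2L)
      stop("level IV needs a factor pair \"A:B\"")
    x <- exposureCoding(sheet, design)
    inter <- as.numeric(x[, pair[1]] * x[, pair[2]] > 0)
    if (length(unique(inter)) < 2L)
      stop("interaction contrast is constant within the analysed subset")
    # term list {cell line, replicate, interaction, cell line x interaction},
    # materialized literally: a sheet with a single replicate level still
    # carries the replicate term (a constant column), which surfaces as a
    # rank-deficiency error rather than being silently dropped
    lineLev <- sort(unique(sheet$cellLine))
    repLev <- sort(unique(sheet$replicate))
    X <- cbind(`(Intercept)` = rep(1, nrow(sheet)))
    if (length(lineLev) > 1L) {
      cs <- stats::contr.sum(length(lineLev))
      lineCols <- cs[match(sheet$cellLine, lineLev), , drop = FALSE]
      colnames(lineCols) <- paste0("cellLine", seq_len(ncol(lineCols)))
      X <- cbind(X, lineCols)
    }
    if (length(repLev) > 1L) {
      repCols <- vapply(repLev[-1L], function(r)
        as.numeric(sheet$replicate == r), numeric(nrow(sheet)))
      colnames(repCols) <- paste0("replicate", repLev[-1L])
      X <- cbind(X, repCols)
    } else {
      X <- cbind(X, replicate = rep(1, nrow(sheet)))
    }
    X <- cbind(X, inter = inter)
    if (length(lineLev) > 1L) {
      cs <- stats::contr.sum(length(lineLev))
      li <- cs[match(sheet$cellLine, lineLev), , drop = FALSE] * inter
      colnames(li) <- paste0("cellLine", seq_len(ncol(li)), ":inter")
      X <- cbind(X, li)
    }
    list(X = X, coef = "inter")
  }
}

subsetForLevel <- function(sheet, level, background = NULL, cellLine = NULL) {
  if (level == "II") {
    if (is.null(background)) stop("level II requires a clinical background")
    which(sheet$clinicalBackground == background)
  } else if (level == "III") {
    if (is.null(cellLine)) stop("level III requires a cell line")
    which(sheet$cellLine == cellLine)
  } else {
    seq_len(nrow(sheet))
  }
}

#' Run one contrast of the layered differential-expression analysis
#'
#' The four levels stratify the data before fitting the NB GLM: level I
#' uses all samples and tests the exposure main effect; level II subsets to
#' one clinical background (ASD / Non-ASD); level III subsets to a single
#' cell line (model ~ exposure); level IV tests an aliased two-way
#' interaction contrast across all samples under the term list
#' \{cell line, replicate, interaction, cell line x interaction\}. Genes
#' below the independent-filtering base-mean threshold are excluded before
#' BH adjustment. Wald statistic = log2FC / SE, two-sided normal p.
#'
#' Levels I and II fit ~ exposure literally; set `blockCellLine = TRUE` to
#' add a cell-line covariate.
#'
#' @param se SummarizedExperiment with a "counts" assay and the sample
#'   sheet as colData (see [simulateCounts()]), or a counts matrix (then
#'   supply `sheet`).
#' @param level "I", "II", "III" or "IV".
#' @param factorName exposure factor; for level IV the pair "A:B".
#' @param background clinical background for level II.
#' @param cellLine cell line for level III.
#' @param sheet sample sheet if `se` is a bare matrix.
#' @param design the assigned \linkS4class{DesignTable}.
#' @param blockCellLine add a cell-line covariate at levels I/II.
#' @param minBaseMean independent-filtering threshold (default 5).
#' @return a \linkS4class{DGEResult}.
#' @examples
#' \donttest{
#' d <- assignFactors(buildL8())
#' sim <- simulateCounts(simConfig(nGenes = 200, seed = 7), ffedStudySheet(d), d)
#' res <- runLevel(sim$se, "I", "Pb", design = d)
#' head(dgeTable(res))
#' }
#' @export
runLevel <- function(se, level = c("I", "II", "III", "IV"), factorName,
                     background = NULL, cellLine = NULL, sheet = NULL,
                     design = assignFactors(buildL8()),
                     blockCellLine = FALSE, minBaseMean = 5) {
  level <- match.arg(level)
  if (is(se, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(se, "counts")
    sheet <- as.data.frame(SummarizedExperiment::colData(se))
  } else {
    counts <- se
    if (is.null(sheet)) stop("supply a sample sheet with a bare count matrix")
  }
  idx <- subsetForLevel(sheet, level, background, cellLine)
  if (!length(idx)) stop("the analysed subset is empty")
  counts <- counts[, idx, drop = FALSE]
  sub <- sheet[idx, , drop = FALSE]

  mm <- levelModelMatrix(sub, level, factorName, design, blockCellLine)
  X <- mm$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("model matrix is rank deficient; collinear terms: ",
         paste(bad, collapse = ", "))
  }

  s <- sizeFactorsMoR(counts)
  alpha <- estimateDispersion(counts, X, s)
  baseMean <- rowMeans(sweep(counts, 2L, s, `/`))
  ci <- match(mm$coef, colnames(X))

  ng <- nrow(counts)
  log2FC <- SE <- stat <- pvalue <- rep(NA_real_, ng)
  converged <- rep(NA, ng)
  for (i in seq_len(ng)) {
    y <- counts[i, ]
    if (all(y == 0)) { converged[i] <- NA; next }  # untestable
    fit <- fitNBGLM(y, X, alpha[i], s)
    b <- fit$coefficients[ci] / log(2)
    se_i <- sqrt(fit$cov[ci, ci]) / log(2)
    log2FC[i] <- b
    SE[i] <- se_i
    stat[i] <- b / se_i
    pvalue[i] <- 2 * stats::pnorm(-abs(stat[i]))
    converged[i] <- fit$converged
  }
  tested <- !is.na(pvalue) & baseMean >= minBaseMean
  padj <- rep(NA_real_, ng)
  padj[tested] <- stats::p.adjust(pvalue[tested], method = "BH")

  res <- data.frame(gene = rownames(counts), baseMean = baseMean,
                    log2FC = log2FC, SE = SE, stat = stat, pvalue = pvalue,
                    padj = padj, dispersion = alpha, converged = converged,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("DGEResult", results = res, level = level, factorName = factorName,
      subset = if (level == "II") paste("background", background)
               else if (level == "III") paste("cell line", cellLine)
               else "all samples",
      nSamples = length(idx))
}

#' Ranked list for preranked enrichment
#'
#' Exports the (gene, score) ranking used for preranked GSEA. The default
#' ranking metric is the Wald statistic.
#'
#' @param x a \linkS4class{DGEResult}.
#' @param metric result column to rank by.
#' @return data.frame (gene, score) sorted by decreasing score.
#' @export
rankedList <- function(x, metric = "stat") {
  r <- dgeTable(x)
  r <- r[!is.na(r[[metric]]), c("gene", metric)]
  names(r) <- c("gene", "score")
  r <- r[order(-r$score, r$gene), ]
  rownames(r) <- NULL
  r
}
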