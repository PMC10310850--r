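#' Flatten transcript models into disjoint exon bins
#'
#' Projects all transcript exons of each gene onto the genome and splits
#' them at every exon boundary, yielding disjoint, sorted counting bins.
#' Genes whose exons overlap another gene's exons on the same strand are
#' excluded as aggregate loci (their ids are messaged). Input coordinates
#' follow the GFF convention (1-based, inclusive); output bins are 0-based
#' half-open.
#'
#' @param geneModels data.frame with columns gene, transcript, chrom,
#'   start, end, strand (1-based inclusive exon intervals).
#' @return data.frame (gene, bin, chrom, start, end, strand) with 0-based
#'   half-open bins, bin ids "gene:E001" etc., sorted within gene.
#' @examples
#' gm <- data.frame(gene = "g1", transcript = c("t1", "t2"), chrom = "chr1",
#'                  start = c(100, 150), end = c(199, 249), strand = "+")
#' flattenAnnotation(gm)
#' @export
flattenAnnotation <- function(geneModels) {
  need <- c("gene", "transcript", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(geneModels)))
  bad <- geneModels$end < geneModels$start
  if (any(bad))
    stop("malformed intervals (end < start) at rows: ",
         paste(which(bad), collapse = ", "))

  gr <- GenomicRanges::GRanges(geneModels$chrom,
                               IRanges::IRanges(geneModels$start,
                                                geneModels$end),
                               strand = geneModels$strand,
                               gene = geneModels$gene)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  xg <- gr$gene[S4Vectors::queryHits(hits)]
  yg <- gr$gene[S4Vectors::subjectHits(hits)]
  aggregate <- sort(unique(c(xg[xg != yg], yg[xg != yg])))
  if (length(aggregate))
    message("excluding aggregate (overlapping) genes: ",
            paste(aggregate, collapse = ", "))
  keep <- !(geneModels$gene %in% aggregate)
  gm <- geneModels[keep, , drop = FALSE]
  if (!nrow(gm))
    return(data.frame(gene = character(0), bin = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))

  out <- lapply(split(gm, gm$gene), function(d) {
    ir <- IRanges::disjoin(IRanges::IRanges(d$start, d$end))
    ir <- ir[order(IRanges::start(ir))]
    data.frame(gene = d$gene[1],
               bin = sprintf("%s:E%03d", d$gene[1], seq_along(ir)),
               chrom = d$chrom[1],
               start = IRanges::start(ir) - 1L,  # 0-based half-open
               end = IRanges::end(ir),
               strand = d$strand[1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

deuModelMatrices <- function(n, exonThis, block, exposure) {
  sampleCols <- diag(n)[rep(seq_len(n), 2L), , drop = FALSE]
  colnames(sampleCols) <- paste0("sample", seq_len(n))
  X <- cbind(sampleCols, exonThis = exonThis)
  lineLev <- sort(unique(block))
  if (length(lineLev) > 1L) {
    cs <- stats::contr.sum(length(lineLev))
    bl <- cs[match(rep(block, 2L), lineLev), , drop = FALSE] * exonThis
    colnames(bl) <- paste0("line", seq_len(ncol(bl)), ":exon")
    X <- cbind(X, bl)
  }
  full <- cbind(X, `exposure:exon` = rep(exposure, 2L) * exonThis)
  list(full = full, reduced = X)
}

#' Test differential exon usage
#'
#' For each exon bin of each multi-bin gene, the bin's counts are paired
#' with the rest of the gene's counts and a negative-binomial
#' likelihood-ratio test compares the full usage model (sample + exon +
#' cell line:exon + exposure:exon) with the reduced model lacking the
#' exposure:exon term — so exposure-dependent changes in the bin's share
#' of its gene are tested while cell-line usage differences are blocked.
#' Usage log2FC is log2 of (bin fraction, treated) / (bin fraction,
#' control). Single-bin genes are skipped. BH adjustment runs across all
#' tested bins.
#'
#' Analysis levels mirror the expression analysis: "I" all samples with
#' cell line as blocking factor, "II" one clinical background (still
#' blocked), "III" a single cell line (model sample + exon +
#' exposure:exon).
#'
#' @param bins data.frame from [simulateExonCounts()] (columns gene, bin,
#'   then one count column per sample).
#' @param sheet the sample sheet.
#' @param level "I", "II" or "III".
#' @param factorName exposure factor tested.
#' @param background,cellLine subset selectors for levels II / III.
#' @param design the assigned \linkS4class{DesignTable}.
#' @return data.frame per bin: gene, bin, exonBaseMean, usageLog2FC, stat,
#'   pvalue, padj.
#' @export
testDEU <- function(bins, sheet, level = c("I", "II", "III"), factorName,
                    background = NULL, cellLine = NULL,
                    design = assignFactors(buildL8())) {
  level <- match.arg(level)
  idx <- subsetForLevel(sheet, level, background, cellLine)
  sub <- sheet[idx, , drop = FALSE]
  counts <- as.matrix(bins[, sub$sampleId, drop = FALSE])
  storage.mode(counts) <- "double"
  exposure <- exposureIndicator(sub, factorName, design)
  if (length(unique(exposure)) < 2L)
    stop("exposure is constant within the analysed subset")
  block <- if (level == "III") rep("one", nrow(sub)) else sub$cellLine
  n <- nrow(sub)

  sf <- tryCatch(sizeFactorsMoR(counts),
                 error = function(e) colSums(counts) / mean(colSums(counts)))
  exonBaseMean <- rowMeans(sweep(counts, 2L, sf, `/`))
  Xdisp <- cbind(1, exposure)
  alpha <- estimateDispersion(counts, Xdisp, sf)

  exonThis <- rep(c(1, 0), each = n)
  mm <- deuModelMatrices(n, exonThis, block, exposure)

  nb <- nrow(bins)
  stat <- pvalue <- lfc <- rep(NA_real_, nb)
  for (g in unique(bins$gene)) {
    rows <- which(bins$gene == g)
    if (length(rows) < 2L) next  # single-bin gene: no usage contrast
    tot <- colSums(counts[rows, , drop = FALSE])
    for (r in rows) {
      y <- c(counts[r, ], tot - counts[r, ])
      fitF <- tryCatch(fitNBGLM(y, mm$full, alpha[r]),
                       error = function(e) NULL)
      fitR <- tryCatch(fitNBGLM(y, mm$reduced, alpha[r]),
                       error = function(e) NULL)
      if (is.null(fitF) || is.null(fitR)) next
      lr <- max(2 * (fitF$logLik - fitR$logLik), 0)
      stat[r] <- lr
      pvalue[r] <- stats::pchisq(lr, df = 1L, lower.tail = FALSE)
      trt <- exposure == 1
      frT <- (sum(counts[r, trt]) + 0.5) / (sum(tot[trt]) + 1)
      frC <- (sum(counts[r, !trt]) + 0.5) / (sum(tot[!trt]) + 1)
      lfc[r] <- log2(frT / frC)
    }
  }
  padj <- rep(NA_real_, nb)
  tested <- !is.na(pvalue)
  padj[tested] <- stats::p.adjust(pvalue[tested], method = "BH")
  data.frame(gene = bins$gene, bin = bins$bin, exonBaseMean = exonBaseMean,
             usageLog2FC = lfc, stat = stat, pvalue = pvalue, padj = padj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call genes with differential exon usage
#'
#' A bin passes when adjusted p < `padjMax`, exon base mean >= `baseMeanMin`
#' and |usage log2FC| >= `lfcMin` (inclusive bounds on the latter two); a
#' gene is called when at least one of its bins passes.
#'
#' @param results data.frame from [testDEU()].
#' @param padjMax,baseMeanMin,lfcMin the calling thresholds (study values
#'   0.05, 10, 1.5).
#' @return data.frame: gene, called, nPassingBins.
#' @export
callDEUGenes <- function(results, padjMax = 0.05, baseMeanMin = 10,
                         lfcMin = 1.5) {
  if (!nrow(results))
    return(data.frame(gene = character(0), called = logical(0),
                      nPassingBins = integer(0)))
  pass <- !is.na(results$padj) & results$padj < padjMax &
    results$exonBaseMean >= baseMeanMin &
    abs(results$usageLog2FC) >= lfcMin
  agg <- tapply(pass, results$gene, sum)
  data.frame(gene = names(agg), called = unname(agg) >= 1L,
             nPassingBins = as.integer(unname(agg)),
             stringsAsFactors = FALSE, row.names = NULL)
}
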