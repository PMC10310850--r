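#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Two-level orthogonal-array design
#'
#' An S4 container for a two-level orthogonal array in -1/+1 coding, together
#' with the factor-to-column assignment and the factor specification table.
#' Columns carry integer labels 1..(nRuns-1) under the binary (XOR)
#' convention: the elementwise product of two columns is the column whose
#' label is the XOR of their labels.
#'
#' @slot runs integer matrix, runs x columns, entries -1 (control) / +1
#'   (treated).
#' @slot labels integer vector of column labels.
#' @slot assignment named integer vector mapping factor name to column label;
#'   empty until factors are assigned.
#' @slot factors data.frame of factor specifications (see [factorSpec()]);
#'   zero rows until factors are assigned.
#'
#' @seealso [buildL8()], [assignFactors()], [aliasStructure()]
#' @export
setClass("DesignTable",
  representation(
    runs = "matrix",
    labels = "integer",
    assignment = "integer",
    factors = "data.frame"
  )
)

setValidity("DesignTable", function(object) {
  m <- object@runs
  msg <- character()
  if (!all(m %in% c(-1L, 1L)))
    msg <- c(msg, "design entries must be -1 or +1")
  if (ncol(m) != length(object@labels))
    msg <- c(msg, "one label per column required")
  if (any(colSums(m) != 0))
    msg <- c(msg, "columns must be balanced (sum to zero)")
  d <- crossprod(m)
  if (any(d[upper.tri(d)] != 0))
    msg <- c(msg, "columns must be mutually orthogonal")
  if (anyDuplicated(apply(m, 1L, paste, collapse = ",")))
    msg <- c(msg, "runs must be distinct")
  if (length(object@assignment)) {
    if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
      msg <- c(msg, "assigned factor names must be unique")
    if (anyDuplicated(object@assignment))
      msg <- c(msg, "each factor must occupy its own column")
    if (!all(object@assignment %in% object@labels))
      msg <- c(msg, "assignment refers to unknown column labels")
  }
  if (length(msg)) msg else TRUE
})

#' Differential expression result
#'
#' Per-gene negative-binomial Wald test results for one contrast of the
#' layered analysis (level I global, II clinical background, III single cell
#' line, IV aliased interaction).
#'
#' @slot results data.frame with columns gene, baseMean, log2FC, SE, stat,
#'   pvalue, padj, dispersion, converged.
#' @slot level character, one of "I", "II", "III", "IV".
#' @slot factorName character; for level IV the pair "A:B".
#' @slot subset character description of the analysed sample subset.
#' @slot nSamples integer number of samples used.
#'
#' @export
setClass("DGEResult",
  representation(
    results = "data.frame",
    level = "character",
    factorName = "character",
    subset = "character",
    nSamples = "integer"
  )
)

setValidity("DGEResult", function(object) {
  r <- object@results
  need <- c("gene", "baseMean", "log2FC", "SE", "stat", "pvalue", "padj")
  if (!all(need %in% names(r)))
    return(paste("missing result columns:",
                 paste(setdiff(need, names(r)), collapse = ", ")))
  ok <- stats::complete.cases(r[, c("pvalue", "padj")])
  if (any(r$padj[ok] < r$pvalue[ok] - 1e-12))
    return("adjusted p-values must not fall below raw p-values")
  if (any(r$baseMean < 0)) return("base means must be nonnegative")
  TRUE
})

#' Gene-set similarity network
#'
#' Nodes are gene sets passing the enrichment FDR threshold (split by
#' direction); edges join pairs whose combined Jaccard/overlap similarity
#' reaches the cutoff. An empty node table is a legitimate "no network"
#' result.
#'
#' @slot graph an igraph object (possibly with zero vertices).
#' @slot nodes data.frame with columns set, q, direction.
#' @slot cutoff numeric similarity cutoff used for edges.
#'
#' @export
setClass("PathwayNetwork",
  representation(
    graph = "ANY",
    nodes = "data.frame",
    cutoff = "numeric"
  )
)

#' Region-by-period permutation enrichment grid
#'
#' @slot observed numeric matrix region x period of observed group means.
#' @slot p numeric matrix of permutation p-values.
#' @slot padj numeric matrix of BH-adjusted p-values.
#' @slot B integer permutation count.
#' @slot groupSize integer number of genes in the tested group.
#'
#' @export
setClass("EnrichmentGrid",
  representation(
    observed = "matrix",
    p = "matrix",
    padj = "matrix",
    B = "integer",
    groupSize = "integer"
  )
)

setValidity("EnrichmentGrid", function(object) {
  if (!identical(dim(object@p), dim(object@padj)))
    return("p and padj must have identical dimensions")
  if (isTRUE(any(object@p <= 0, na.rm = TRUE)) ||
      isTRUE(any(object@p > 1, na.rm = TRUE)))
    return("permutation p-values must lie in (0, 1]")
  if (isTRUE(any(object@padj < object@p - 1e-12, na.rm = TRUE)))
    return("adjusted p-values must not fall below raw p-values")
  TRUE
})
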