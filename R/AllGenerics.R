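#' @rdname DesignTable-class
#' @param object,x a \linkS4class{DesignTable}
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname DesignTable-class
#' @export
setGeneric("columnLabels", function(x) standardGeneric("columnLabels"))

#' @rdname DesignTable-class
#' @export
setGeneric("factorAssignment", function(x) standardGeneric("factorAssignment"))

#' @rdname DesignTable-class
#' @export
setGeneric("freeColumns", function(x) standardGeneric("freeColumns"))

#' @rdname DesignTable-class
#' @export
setGeneric("factorSpecs", function(x) standardGeneric("factorSpecs"))

#' @rdname DGEResult-class
#' @export
setGeneric("dgeTable", function(x) standardGeneric("dgeTable"))

#' @rdname DGEResult-class
#' @export
setGeneric("analysisLevel", function(x) standardGeneric("analysisLevel"))

#' @rdname EnrichmentGrid-class
#' @export
setGeneric("gridP", function(x) standardGeneric("gridP"))

#' @rdname EnrichmentGrid-class
#' @export
setGeneric("gridPadj", function(x) standardGeneric("gridPadj"))

#' @rdname EnrichmentGrid-class
#' @export
setGeneric("gridObserved", function(x) standardGeneric("gridObserved"))

#' @rdname PathwayNetwork-class
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname PathwayNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @describeIn DesignTable-class the run-by-column -1/+1 matrix with columns
#'   named by label.
setMethod("designMatrix", "DesignTable", function(x) {
  m <- x@runs
  colnames(m) <- paste0("c", x@labels)
  m
})

#' @describeIn DesignTable-class integer column labels.
setMethod("columnLabels", "DesignTable", function(x) x@labels)

#' @describeIn DesignTable-class named integer vector factor -> column label.
setMethod("factorAssignment", "DesignTable", function(x) x@assignment)

#' @describeIn DesignTable-class labels of columns carrying no factor.
setMethod("freeColumns", "DesignTable", function(x)
  setdiff(x@labels, x@assignment))

#' @describeIn DesignTable-class the factor specification table.
setMethod("factorSpecs", "DesignTable", function(x) x@factors)

setMethod("show", "DesignTable", function(object) {
  cat(sprintf("DesignTable: %d runs x %d columns (two-level orthogonal array)\n",
              nrow(object@runs), ncol(object@runs)))
  if (length(object@assignment)) {
    cat("  factors:", paste(sprintf("%s->c%d", names(object@assignment),
                                    object@assignment), collapse = " "), "\n")
    cat("  free columns:", paste0("c", freeColumns(object), collapse = " "), "\n")
  } else {
    cat("  no factors assigned\n")
  }
})

#' @describeIn DGEResult-class the per-gene result table.
setMethod("dgeTable", "DGEResult", function(x) x@results)

#' @describeIn DGEResult-class the analysis level ("I".."IV").
setMethod("analysisLevel", "DGEResult", function(x) x@level)

setMethod("show", "DGEResult", function(object) {
  r <- object@results
  nsig <- sum(r$padj < 0.05, na.rm = TRUE)
  cat(sprintf("DGEResult level %s, factor %s (%s; %d samples)\n",
              object@level, object@factorName, object@subset, object@nSamples))
  cat(sprintf("  %d genes tested, %d at adj. p < 0.05\n",
              sum(!is.na(r$pvalue)), nsig))
})

#' @describeIn EnrichmentGrid-class matrix of permutation p-values.
setMethod("gridP", "EnrichmentGrid", function(x) x@p)

#' @describeIn EnrichmentGrid-class matrix of BH-adjusted p-values.
setMethod("gridPadj", "EnrichmentGrid", function(x) x@padj)

#' @describeIn EnrichmentGrid-class matrix of observed group means.
setMethod("gridObserved", "EnrichmentGrid", function(x) x@observed)

setMethod("show", "EnrichmentGrid", function(object) {
  cat(sprintf("EnrichmentGrid: %d x %d cells, group of %d genes, B = %d\n",
              nrow(object@p), ncol(object@p), object@groupSize, object@B))
  cat(sprintf("  cells at adj. p < 0.05: %d\n",
              sum(object@padj < 0.05, na.rm = TRUE)))
})

#' @describeIn PathwayNetwork-class the underlying igraph object.
setMethod("networkGraph", "PathwayNetwork", function(x) x@graph)

#' @describeIn PathwayNetwork-class node table (set, q, direction).
setMethod("networkNodes", "PathwayNetwork", function(x) x@nodes)

setMethod("show", "PathwayNetwork", function(object) {
  if (nrow(object@nodes) == 0L) {
    cat("PathwayNetwork: no network (no gene sets passed the threshold)\n")
  } else {
    cat(sprintf("PathwayNetwork: %d nodes, %d edges (similarity cutoff %.3f)\n",
                igraph::vcount(object@graph), igraph::ecount(object@graph),
                object@cutoff))
  }
})
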