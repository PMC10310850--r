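#' One-point calibration against an internal standard
#'
#' Concentration = internal-standard concentration x (analyte intensity /
#' internal-standard intensity). Scale-invariant in instrument gain: a
#' common multiplicative factor on both intensities cancels.
#'
#' @param iMet analyte intensity (scalar or vector).
#' @param iIs internal-standard intensity (same shape); must be positive.
#' @param cIs known internal-standard concentration (uM).
#' @return concentration in uM.
#' @examples
#' quantifyOnePoint(150, 100, 2)  # 3 uM
#' @export
quantifyOnePoint <- function(iMet, iIs, cIs) {
  if (any(iIs <= 0)) stop("internal-standard intensity must be positive; ",
                          "feature is unquantifiable")
  cIs * (iMet / iIs)
}

#' Quantify a feature table by one-point calibration
#'
#' Applies [quantifyOnePoint()] per feature using its mapped internal
#' standard. Features whose standard has zero intensity in any sample are
#' dropped with a message (unquantifiable).
#'
#' @param features data.frame: feature, (optional class), then one
#'   intensity column per sample.
#' @param isMap data.frame: feature, isFeature, isConc (uM).
#' @param sampleCols which columns hold intensities; defaults to all
#'   numeric columns.
#' @return data.frame: feature, then one concentration column (uM) per
#'   sample.
#' @export
quantifyFeatures <- function(features, isMap, sampleCols = NULL) {
  if (is.null(sampleCols))
    sampleCols <- names(features)[vapply(features, is.numeric, logical(1))]
  m <- as.matrix(features[, sampleCols, drop = FALSE])
  rownames(m) <- features$feature
  missingIS <- setdiff(isMap$isFeature, features$feature)
  if (length(missingIS))
    stop("internal standards absent from the table: ",
         paste(missingIS, collapse = ", "))
  keep <- logical(nrow(isMap))
  out <- matrix(NA_real_, nrow(isMap), length(sampleCols),
                dimnames = list(isMap$feature, sampleCols))
  for (i in seq_len(nrow(isMap))) {
    isRow <- m[isMap$isFeature[i], ]
    if (any(isRow <= 0)) next
    out[i, ] <- quantifyOnePoint(m[isMap$feature[i], ], isRow,
                                 isMap$isConc[i])
    keep[i] <- TRUE
  }
  if (any(!keep))
    message("unquantifiable features (zero internal-standard intensity): ",
            paste(isMap$feature[!keep], collapse = ", "))
  data.frame(feature = isMap$feature[keep],
             as.data.frame(out[keep, , drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
}

#' Median-intensity signal filter
#'
#' Drops features whose median intensity across samples falls below the
#' threshold (the study reported 79 of >2500 signals after its threshold;
#' the value itself is instrument-specific configuration).
#'
#' @param features data.frame as in [quantifyFeatures()].
#' @param threshold minimum median intensity.
#' @param sampleCols intensity columns; defaults to all numeric columns.
#' @return the filtered feature table.
#' @export
signalFilter <- function(features, threshold, sampleCols = NULL) {
  if (is.null(sampleCols))
    sampleCols <- names(features)[vapply(features, is.numeric, logical(1))]
  med <- apply(as.matrix(features[, sampleCols, drop = FALSE]), 1L,
               stats::median)
  features[med >= threshold, , drop = FALSE]
}

#' Per-level linear-model testing of metabolite concentrations
#'
#' Fits lm(concentration ~ exposure) per feature on the complete data set
#' ("global"), on each clinical background, or on each cell line, exactly
#' as the expression analysis stratifies its levels; p comes from the
#' slope's t statistic and BH adjustment runs across features within each
#' stratum. Set `blockCellLine = TRUE` to add a cell-line covariate at the
#' global/background levels.
#'
#' @param conc data.frame from [quantifyFeatures()].
#' @param sheet a [metabSheet()]-style sample sheet.
#' @param level "global", "background" or "cellLine".
#' @param factorName exposure column of the sheet (default "FH").
#' @param blockCellLine add cell line as a covariate.
#' @return data.frame: stratum, feature, meanControl, meanTreated,
#'   estimate (concentration difference treated - control), pvalue, padj.
#' @export
testMetabolites <- function(conc, sheet,
                            level = c("global", "background", "cellLine"),
                            factorName = "FH", blockCellLine = FALSE) {
  level <- match.arg(level)
  sampleCols <- intersect(names(conc), sheet$sampleId)
  m <- as.matrix(conc[, sampleCols, drop = FALSE])
  rownames(m) <- conc$feature
  sheet <- sheet[match(sampleCols, sheet$sampleId), , drop = FALSE]

  strata <- switch(level,
    global = list(global = seq_len(nrow(sheet))),
    background = split(seq_len(nrow(sheet)), sheet$clinicalBackground),
    cellLine = split(seq_len(nrow(sheet)), sheet$cellLine))

  out <- lapply(names(strata), function(st) {
    idx <- strata[[st]]
    expo <- as.numeric(sheet[[factorName]][idx] == "treated")
    if (length(unique(expo)) < 2L)
      stop("exposure is constant within stratum ", st)
    res <- t(apply(m[, idx, drop = FALSE], 1L, function(y) {
      if (stats::sd(y) < 1e-12 * max(1, abs(mean(y))))  # constant feature
        return(c(mean(y[expo == 0]), mean(y[expo == 1]), 0, 1))
      fit <- if (blockCellLine && length(unique(sheet$cellLine[idx])) > 1L)
        stats::lm(y ~ factor(sheet$cellLine[idx]) + expo)
      else stats::lm(y ~ expo)
      sm <- summary(fit)$coefficients
      pv <- sm["expo", "Pr(>|t|)"]
      if (!is.finite(pv)) pv <- 1  # degenerate fit (constant concentrations)
      c(mean(y[expo == 0]), mean(y[expo == 1]),
        sm["expo", "Estimate"], pv)
    }))
    data.frame(stratum = st, feature = rownames(m),
               meanControl = res[, 1], meanTreated = res[, 2],
               estimate = res[, 3], pvalue = res[, 4],
               padj = stats::p.adjust(res[, 4], method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
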