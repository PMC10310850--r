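#' Specify a two-level exposure factor
#'
#' Each exposure factor has exactly two levels: a control level (coded -1)
#' and a treated level (coded +1). The dose strings carry the applied
#' concentration with its unit; for zinc deficiency the convention inverts —
#' the control medium carries the zinc supplement and the treated level is
#' its absence.
#'
#' @param name factor name, unique within a design.
#' @param controlLabel,treatedLabel level labels.
#' @param treatedDose,controlDose numeric doses.
#' @param unit dose unit string, e.g. "uM" or "mM".
#' @return one-row data.frame; rbind rows to form a factor table.
#' @examples
#' factorSpec("Pb", treatedDose = 3, unit = "uM")
#' @export
factorSpec <- function(name, controlLabel = "control", treatedLabel = "treated",
                       treatedDose = NA_real_, controlDose = 0, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  data.frame(name = name, controlLabel = controlLabel,
             treatedLabel = treatedLabel, treatedDose = treatedDose,
             controlDose = controlDose, unit = unit,
             stringsAsFactors = FALSE)
}

#' The six neurodevelopmental exposure factors
#'
#' The default factor table for the L8 exposure study: lead (Pb), valproic
#' acid (VPA), bisphenol A (BPA), ethanol (EtOH), fluoxetine hydrochloride
#' (FH) at 3 uM (EtOH at 3 mM), and zinc deficiency (Zn-), where the control
#' medium is supplemented with 1.5 uM zinc sulphate and the treated level is
#' zinc-free (dose 0).
#'
#' @return data.frame of six factor specifications, in canonical order
#'   Pb, VPA, BPA, EtOH, FH, Zn-.
#' @export
ffedFactors <- function() {
  rbind(
    factorSpec("Pb",   treatedDose = 3,   unit = "uM"),
    factorSpec("VPA",  treatedDose = 3,   unit = "uM"),
    factorSpec("BPA",  treatedDose = 3,   unit = "uM"),
    factorSpec("EtOH", treatedDose = 3,   unit = "mM"),
    factorSpec("FH",   treatedDose = 3,   unit = "uM"),
    factorSpec("Zn-", controlLabel = "supplemented", treatedLabel = "deprived",
               treatedDose = 0, controlDose = 1.5, unit = "uM")
  )
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Build the L8 orthogonal array
#'
#' Constructs the canonical 8-run, 7-column two-level orthogonal array from
#' three generator columns. Column label j (1..7) encodes in binary which
#' generators multiply to form it, so the elementwise product of columns a
#' and b is the column labelled XOR(a, b). Entry for run r in column j is
#' (-1)^popcount(bits(r-1) AND bits(j)).
#'
#' @return a \linkS4class{DesignTable} with 8 runs, 7 columns, no factors
#'   assigned.
#' @examples
#' d <- buildL8()
#' crossprod(designMatrix(d))  # diagonal: columns orthogonal
#' @export
buildL8 <- function() {
  runs <- 8L
  labels <- 1:7
  m <- vapply(labels, function(j)
    as.integer((-1L)^popcount(bitwAnd(0:(runs - 1L), j))), integer(runs))
  rownames(m) <- paste0("run", seq_len(runs))
  new("DesignTable", runs = m, labels = labels,
      assignment = integer(0), factors = factorSpec("x")[0, ])
}

#' Assign exposure factors to design columns
#'
#' Records which array column carries each factor's contrast. The default
#' map places six factors on columns 1..6 in the order given, leaving
#' column 7 free; with the canonical factor order (Pb, VPA, BPA, EtOH, FH,
#' Zn-) the three two-way interactions aliased to the free column are then
#' exactly Pb:Zn-, VPA:FH and BPA:EtOH.
#'
#' @param table a \linkS4class{DesignTable}.
#' @param factors data.frame of factor specifications (see [factorSpec()]).
#' @param columnMap optional named integer vector factor name -> column
#'   label; must be injective.
#' @return the design with assignment recorded.
#' @export
assignFactors <- function(table, factors = ffedFactors(), columnMap = NULL) {
  stopifnot(is(table, "DesignTable"), is.data.frame(factors))
  fn <- factors$name
  if (anyDuplicated(fn)) stop("factor names must be unique")
  if (length(fn) > length(table@labels))
    stop("more factors (", length(fn), ") than design columns (",
         length(table@labels), ")")
  if (is.null(columnMap)) {
    columnMap <- stats::setNames(table@labels[seq_along(fn)], fn)
  } else {
    if (!all(fn %in% names(columnMap)))
      stop("columnMap must name every factor")
    columnMap <- columnMap[fn]
    if (anyDuplicated(columnMap))
      stop("duplicate column assignment: ",
           paste(names(columnMap)[duplicated(columnMap) |
                                  duplicated(columnMap, fromLast = TRUE)],
                 collapse = ", "))
    if (!all(columnMap %in% table@labels))
      stop("columnMap refers to unknown column labels")
  }
  initialize(table, assignment = stats::setNames(as.integer(columnMap), fn),
             factors = factors)
}

#' Alias (confounding) structure of an assigned design
#'
#' Maps every main effect and every interaction up to `maxOrder` to its
#' contrast column by XOR of column labels (exact integer algebra: the
#' elementwise product of two array columns is the column labelled by the
#' XOR of their labels). Effects sharing a column are statistically
#' indistinguishable. Interactions landing on a factor's column are flagged
#' "confounded with main effect"; interactions on a free column are
#' "estimable (mutually aliased)".
#'
#' @param table an assigned \linkS4class{DesignTable}.
#' @param maxOrder highest interaction order enumerated (currently 1 or 2).
#' @return data.frame with columns column (label), effect (e.g. "Pb" or
#'   "VPA:FH"), order, status; sorted by column label.
#' @export
aliasStructure <- function(table, maxOrder = 2) {
  stopifnot(is(table, "DesignTable"))
  if (!length(table@assignment)) stop("no factors assigned to the design")
  stopifnot(maxOrder %in% 1:2)
  asg <- table@assignment
  out <- data.frame(column = unname(asg), effect = names(asg),
                    order = 1L, stringsAsFactors = FALSE)
  if (maxOrder >= 2 && length(asg) >= 2) {
    pairs <- utils::combn(names(asg), 2L)
    pcol <- bitwXor(asg[pairs[1L, ]], asg[pairs[2L, ]])
    out <- rbind(out, data.frame(
      column = unname(pcol),
      effect = paste(pairs[1L, ], pairs[2L, ], sep = ":"),
      order = 2L, stringsAsFactors = FALSE))
  }
  mainCols <- unname(asg)
  out$status <- ifelse(out$order == 1L, "main effect",
                ifelse(out$column %in% mainCols, "confounded with main effect",
                       "estimable (mutually aliased)"))
  out[order(out$column, out$order, out$effect), , drop = FALSE]
}

#' Sample count of a design strategy
#'
#' Compares the sampling cost of the fractional factorial ("ffed": one array
#' run is one condition, so runs x cell lines x replicates) against a
#' one-factor-at-a-time comparator ("ofat": one condition per factor, so
#' factors x cell lines x replicates).
#'
#' @param designKind "ffed" or "ofat".
#' @param nFactors,nRuns,nCellLines,nReplicates positive integers; `nRuns`
#'   is ignored for "ofat", `nFactors` for "ffed".
#' @return integer sample count.
#' @examples
#' sampleCount("ffed", nRuns = 8, nCellLines = 4, nReplicates = 1)  # 32
#' sampleCount("ofat", nFactors = 6, nCellLines = 4, nReplicates = 5)  # 120
#' @export
sampleCount <- function(designKind = c("ffed", "ofat"), nFactors = 6L,
                        nRuns = 8L, nCellLines = 1L, nReplicates = 1L) {
  designKind <- match.arg(designKind)
  args <- c(nFactors, nRuns, nCellLines, nReplicates)
  if (any(args <= 0) || any(args != round(args)))
    stop("all counts must be positive integers")
  as.integer(switch(designKind,
    ffed = nRuns * nCellLines * nReplicates,
    ofat = nFactors * nCellLines * nReplicates))
}

#' Build the wet-lab sample sheet for an assigned design
#'
#' Expands the design into one row per (cell line, replicate, run), filling
#' per-factor level labels and applied doses from the factor specification.
#' An extra partial replicate restricted to a run subset can be added per
#' cell line (the study collected a full extra replicate for one line and a
#' four-run partial for another). Run order is Yates (standard) order by
#' default; set `randomize = TRUE` to permute runs within each replicate
#' under `seed`.
#'
#' @param table an assigned \linkS4class{DesignTable}.
#' @param cellLines data.frame with columns cellLine, clinicalBackground
#'   (values "ASD" / "Non-ASD").
#' @param replicates named integer vector cellLine -> number of full
#'   replicates (default 1 each).
#' @param partialExtra optional named list cellLine -> integer vector of run
#'   indices forming one additional partial replicate.
#' @param randomize logical; permute run order within replicates.
#' @param seed integer seed used when `randomize = TRUE` (recorded in the
#'   returned sheet's "seed" attribute).
#' @return data.frame sample sheet: sampleId, cellLine, clinicalBackground,
#'   replicate, runIndex, then `<factor>` level and `<factor>_dose` columns.
#' @examples
#' d <- assignFactors(buildL8())
#' sheet <- makeSampleSheet(d, ffedCellLines())
#' nrow(sheet)  # 32
#' @export
makeSampleSheet <- function(table, cellLines, replicates = NULL,
                            partialExtra = NULL, randomize = FALSE,
                            seed = 1L) {
  stopifnot(is(table, "DesignTable"), is.data.frame(cellLines))
  if (!length(table@assignment)) stop("no factors assigned to the design")
  nRuns <- nrow(table@runs)
  lines <- cellLines$cellLine
  if (is.null(replicates)) replicates <- stats::setNames(rep(1L, length(lines)), lines)
  if (!is.null(partialExtra)) {
    bad <- setdiff(names(partialExtra), lines)
    if (length(bad)) stop("unknown cell line in partial map: ",
                          paste(bad, collapse = ", "))
    if (!all(unlist(partialExtra) %in% seq_len(nRuns)))
      stop("partial run subset contains invalid run indices")
  }
  fac <- table@factors
  asg <- table@assignment
  lev <- table@runs[, match(asg, table@labels), drop = FALSE]
  colnames(lev) <- names(asg)

  rows <- list()
  for (i in seq_along(lines)) {
    cl <- lines[i]
    nr <- if (cl %in% names(replicates)) replicates[[cl]] else 1L
    repRuns <- rep(list(seq_len(nRuns)), nr)
    if (!is.null(partialExtra) && cl %in% names(partialExtra))
      repRuns <- c(repRuns, list(sort(unique(partialExtra[[cl]]))))
    for (r in seq_along(repRuns)) {
      runIdx <- repRuns[[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        cellLine = cl,
        clinicalBackground = cellLines$clinicalBackground[i],
        replicate = r, runIndex = runIdx, stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, rows)
  if (randomize) {
    set.seed(seed)
    grp <- interaction(sheet$cellLine, sheet$replicate, drop = TRUE)
    sheet <- do.call(rbind, lapply(split(sheet, grp),
                                   function(d) d[sample.int(nrow(d)), ]))
    rownames(sheet) <- NULL
  }
  for (f in names(asg)) {
    x <- lev[sheet$runIndex, f]
    fr <- fac[fac$name == f, ]
    sheet[[f]] <- ifelse(x > 0, fr$treatedLabel, fr$controlLabel)
    sheet[[paste0(f, "_dose")]] <- ifelse(x > 0, fr$treatedDose, fr$controlDose)
  }
  sheet <- cbind(sampleId = sprintf("%s_rep%d_run%d", sheet$cellLine,
                                    sheet$replicate, sheet$runIndex),
                 sheet, stringsAsFactors = FALSE)
  rownames(sheet) <- NULL
  attr(sheet, "seed") <- if (randomize) seed else NA_integer_
  sheet
}

#' The study's four cell lines
#'
#' Two neurotypical iPSC-derived NES lines (CTRL_Male, CTRL_Female; Non-ASD
#' background) and two lines from autistic donors (ASD_HNRNPU, ASD_CASK).
#'
#' @return data.frame with columns cellLine, clinicalBackground.
#' @export
ffedCellLines <- function() {
  data.frame(
    cellLine = c("CTRL_Male", "CTRL_Female", "ASD_HNRNPU", "ASD_CASK"),
    clinicalBackground = c("Non-ASD", "Non-ASD", "ASD", "ASD"),
    stringsAsFactors = FALSE)
}

#' The study's 44-sample sheet
#'
#' Convenience wrapper: the full L8 across four cell lines (32 samples) plus
#' one full extra replicate for CTRL_Male (8) and a four-run partial
#' replicate for CTRL_Female (4).
#'
#' @param design an assigned \linkS4class{DesignTable}; defaults to the L8
#'   with the canonical six-factor assignment.
#' @return 44-row sample sheet (see [makeSampleSheet()]).
#' @export
ffedStudySheet <- function(design = assignFactors(buildL8())) {
  makeSampleSheet(design, ffedCellLines(),
                  replicates = c(CTRL_Male = 2L, CTRL_Female = 1L,
                                 ASD_HNRNPU = 1L, ASD_CASK = 1L),
                  partialExtra = list(CTRL_Female = 1:4))
}

#' Numeric -1/+1 exposure coding of a sample sheet
#'
#' @param sheet a sample sheet from [makeSampleSheet()].
#' @param design the assigned design the sheet was built from.
#' @return numeric matrix samples x factors with entries -1/+1.
#' @export
exposureCoding <- function(sheet, design) {
  asg <- factorAssignment(design)
  lev <- design@runs[, match(asg, columnLabels(design)), drop = FALSE]
  colnames(lev) <- names(asg)
  m <- lev[sheet$runIndex, , drop = FALSE]
  rownames(m) <- sheet$sampleId
  m
}
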