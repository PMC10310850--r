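provenanceHeader <- function(hash = NULL, seed = NULL) {
  if (is.null(hash)) return(character(0))
  sprintf("# ffedomics config=%s seed=%s", hash, as.character(seed))
}

writeTableWithHeader <- function(df, path, sep, header = character(0),
                                 rowNames = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(h, con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = rowNames, col.names = TRUE)
  invisible(path)
}

stopOnMalformed <- function(cond, path) {
  stop("malformed input in ", path, ": ", conditionMessage(cond))
}

#' Read / write gene-level counts (TSV, genes x samples)
#'
#' @param path file path.
#' @param counts integer matrix with gene rownames.
#' @param header optional provenance header lines (written as "#" comments,
#'   skipped on read).
#' @return `readCounts`: integer matrix.
#' @export
readCounts <- function(path) {
  df <- tryCatch(utils::read.delim(path, comment.char = "#",
                                   check.names = FALSE),
                 error = function(e) stopOnMalformed(e, path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0) || any(m != round(m)))
    stop("malformed input in ", path, ": counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCounts
#' @export
writeCounts <- function(counts, path, header = character(0)) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  writeTableWithHeader(df, path, "\t", header)
}

#' Read / write a sample sheet (CSV)
#'
#' @param path file path.
#' @param sheet data.frame from [makeSampleSheet()].
#' @param header optional provenance comment lines.
#' @return `readSampleSheet`: data.frame.
#' @export
readSampleSheet <- function(path) {
  tryCatch(utils::read.csv(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE),
           error = function(e) stopOnMalformed(e, path))
}

#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(h, con)
  utils::write.csv(sheet, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a design (CSV runs x factors plus YAML sidecar)
#'
#' The CSV holds one row per run with -1/+1 entries under factor-name
#' columns; the sidecar YAML (same path + ".yaml") records column labels,
#' the factor-to-column assignment and the dose table, so the design
#' round-trips exactly.
#'
#' @param design an assigned \linkS4class{DesignTable}.
#' @param path CSV path (sidecar written alongside).
#' @return `readDesign`: a \linkS4class{DesignTable}.
#' @export
writeDesign <- function(design, path) {
  asg <- factorAssignment(design)
  if (!length(asg)) stop("cannot write an unassigned design")
  m <- design@runs[, match(asg, columnLabels(design)), drop = FALSE]
  colnames(m) <- names(asg)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  side <- list(labels = as.integer(columnLabels(design)),
               assignment = as.list(asg),
               factors = lapply(seq_len(nrow(design@factors)), function(i)
                 as.list(design@factors[i, ])))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
  side <- tryCatch(yaml::read_yaml(paste0(path, ".yaml")),
                   error = function(e) stopOnMalformed(e, paste0(path, ".yaml")))
  runs <- tryCatch(as.matrix(utils::read.csv(path, check.names = FALSE)),
                   error = function(e) stopOnMalformed(e, path))
  labels <- as.integer(side$labels)
  asg <- unlist(side$assignment)
  full <- matrix(0L, nrow(runs), length(labels),
                 dimnames = list(paste0("run", seq_len(nrow(runs))), NULL))
  full[, match(asg, labels)] <- as.integer(runs)
  # free columns are reconstructed from the assigned ones by label XOR
  for (j in seq_along(labels)) {
    if (labels[j] %in% asg) next
    full[, j] <- decomposeLabel(labels[j], labels[labels %in% asg],
                                full, labels)
  }
  factors <- do.call(rbind, lapply(side$factors, function(f)
    data.frame(f, stringsAsFactors = FALSE)))
  new("DesignTable", runs = full, labels = labels,
      assignment = stats::setNames(as.integer(asg), names(asg)),
      factors = factors)
}

decomposeLabel <- function(target, assignedLabels, full, labels) {
  # express `target` as XOR of assigned labels; multiply those columns
  for (k in seq_len(min(3L, length(assignedLabels)))) {
    cmb <- utils::combn(assignedLabels, k)
    for (i in seq_len(ncol(cmb))) {
      if (Reduce(bitwXor, cmb[, i]) == target) {
        cols <- full[, match(cmb[, i], labels), drop = FALSE]
        return(as.integer(apply(cols, 1L, prod)))
      }
    }
  }
  stop("cannot reconstruct free column ", target, " from the assignment")
}

#' Read / write gene-set collections (GMT)
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @param collection named list of gene-id vectors.
#' @param descriptions optional character vector matching the collection.
#' @return `readGMT`: named list of gene-id vectors (possibly empty).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed input in ", path, ": fewer than 3 fields at line ",
         bad[1])
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1L))
}

#' @rdname readGMT
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write ranked gene lists (RNK)
#'
#' Two-column, tab-separated (gene, score), sorted by decreasing score on
#' read.
#'
#' @param path RNK path.
#' @param ranked data.frame (gene, score).
#' @return `readRNK`: data.frame (gene, score), descending.
#' @export
readRNK <- function(path) {
  df <- tryCatch(utils::read.delim(path, header = FALSE,
                                   comment.char = "#",
                                   col.names = c("gene", "score")),
                 error = function(e) stopOnMalformed(e, path))
  if (!is.numeric(df$score))
    stop("malformed input in ", path, ": non-numeric scores")
  df <- df[order(-df$score, df$gene), ]
  rownames(df) <- NULL
  df
}

#' @rdname readRNK
#' @export
writeRNK <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript exon models from GFF3
#'
#' Extracts exon features (1-based inclusive, per the GFF convention) with
#' their transcript (Parent) and gene ids into the gene-model table
#' consumed by [flattenAnnotation()]. Requires the rtracklayer package.
#'
#' @param path GFF3 path.
#' @return data.frame: gene, transcript, chrom, start, end, strand.
#' @export
readGFF3Models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(gr$type) == "exon"]
  parent <- vapply(ex$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  gene <- if (!is.null(ex$gene_id)) ex$gene_id else sub("\\..*$", "", parent)
  data.frame(gene = gene, transcript = parent,
             chrom = as.character(GenomicRanges::seqnames(ex)),
             start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
             strand = as.character(GenomicRanges::strand(ex)),
             stringsAsFactors = FALSE)
}

#' Read / write exon-bin count tables (TSV)
#'
#' @param path file path.
#' @param bins data.frame (gene, bin, then count columns).
#' @param header optional provenance comment lines.
#' @return `readExonBins`: data.frame.
#' @export
readExonBins <- function(path) {
  tryCatch(utils::read.delim(path, comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE),
           error = function(e) stopOnMalformed(e, path))
}

#' @rdname readExonBins
#' @export
writeExonBins <- function(bins, path, header = character(0)) {
  writeTableWithHeader(bins, path, "\t", header)
}

#' Read / write metabolite feature tables (CSV)
#'
#' @param path file path.
#' @param features data.frame (feature, then intensity columns).
#' @param header optional provenance comment lines.
#' @return `readFeatureTable`: data.frame.
#' @export
readFeatureTable <- function(path) {
  tryCatch(utils::read.csv(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE),
           error = function(e) stopOnMalformed(e, path))
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(features, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(h, con)
  utils::write.csv(features, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an expression matrix with sample metadata
#'
#' The matrix travels as TSV (genes x samples); region/period/RIN metadata
#' as a companion CSV.
#'
#' @param path TSV path; metadata at `metaPath`.
#' @param expr numeric matrix; `meta` data.frame (sample, region, period,
#'   RIN).
#' @param metaPath CSV path (default: `path` + ".meta.csv").
#' @param meta sample metadata.
#' @return `readExpression`: list(expr, meta).
#' @export
readExpression <- function(path, metaPath = paste0(path, ".meta.csv")) {
  df <- tryCatch(utils::read.delim(path, comment.char = "#",
                                   check.names = FALSE),
                 error = function(e) stopOnMalformed(e, path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- tryCatch(utils::read.csv(metaPath, comment.char = "#",
                                   stringsAsFactors = FALSE),
                   error = function(e) stopOnMalformed(e, metaPath))
  list(expr = m, meta = meta)
}

#' @rdname readExpression
#' @export
writeExpression <- function(expr, meta, path,
                            metaPath = paste0(path, ".meta.csv"),
                            header = character(0)) {
  writeTableWithHeader(data.frame(gene = rownames(expr), expr,
                                  check.names = FALSE), path, "\t", header)
  writeSampleSheet(meta, metaPath, header)
  invisible(path)
}

#' Export a pathway network as GraphML and edge list
#'
#' @param net a \linkS4class{PathwayNetwork}.
#' @param path GraphML path; the edge list TSV goes to `path` + ".edges.tsv".
#' @return the path, invisibly.
#' @export
writeGraphML <- function(net, path) {
  g <- networkGraph(net)
  igraph::write_graph(g, path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(el, paste0(path, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
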