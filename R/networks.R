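# Cytokine production and receptor maps, ligand-response and
# ligand-receptor interactomes, and the abundance-production correlation.

# mean normalized expression per (gene, cell type) over all conditions
.meanByCellType <- function(x, genes) {
  genes <- intersect(genes, rownames(x))
  m <- .expr(x)[genes, , drop = FALSE]
  cts <- sort(unique(cellTypes(x)))
  out <- sapply(cts, function(ct)
    Matrix::rowMeans(m[, cellTypes(x) == ct, drop = FALSE]))
  matrix(out, nrow = length(genes), dimnames = list(genes, cts))
}

#' Cytokine production map
#'
#' For each catalog cytokine, the mean normalized expression of its ligand
#' gene(s) per cell type, averaged over all conditions (baseline plus
#' stimulated, to capture induced expression). Genes detected in fewer
#' than \code{minCells} cells are dropped; per gene, cell-type means are
#' capped at \code{cap} expression units and then normalized to the
#' maximum cell type. A cytokine's value in a cell type is the maximum
#' over its (retained) ligand genes, so a heteromer counts as expressed
#' when at least one subunit is expressed. A cytokine is flagged expressed
#' where the normalized value exceeds \code{exprThreshold}.
#'
#' @param x normalized compendium spanning all conditions.
#' @param catalog a \linkS4class{CytokineCatalog}.
#' @param minCells detection floor per gene (default 50 cells).
#' @param cap expression cap before row normalization (default 1).
#' @param exprThreshold expressed-flag cutoff on the normalized value
#'   (strictly greater; default 0.1).
#' @return list of class \code{"ProductionMap"} with matrices \code{raw}
#'   (mean expression of the best ligand gene), \code{norm},
#'   \code{expressed}, vector \code{nCellsDetected} and \code{multimeric}
#'   flags.
#' @export
productionMap <- function(x, catalog, minCells = 50, cap = 1,
                          exprThreshold = 0.1) {
  allGenes <- unique(unlist(ligandGenes(catalog)))
  present <- intersect(allGenes, rownames(x))
  counts <- Matrix::rowSums(.expr(x)[present, , drop = FALSE] > 0)
  kept <- present[counts >= minCells]
  mu <- .meanByCellType(x, kept)
  cts <- sort(unique(cellTypes(x)))
  nms <- cytokineNames(catalog)
  raw <- norm <- matrix(NA_real_, length(nms), length(cts),
                        dimnames = list(nms, cts))
  nDet <- stats::setNames(rep(0L, length(nms)), nms)
  keep <- rep(FALSE, length(nms))
  for (i in seq_along(nms)) {
    lg <- ligandGenes(catalog, nms[i])
    if (!all(lg %in% present)) {
      miss <- setdiff(lg, present)
      if (length(miss) == length(lg)) {
        warning("cytokine ", nms[i], " skipped: ligand gene(s) ",
                paste(miss, collapse = ", "), " absent from the matrix")
        next
      }
    }
    lg <- intersect(lg, kept)
    if (!length(lg)) next
    gm <- mu[lg, , drop = FALSE]
    gm <- pmin(gm, cap)
    gn <- gm / apply(gm, 1, max)
    gn[is.nan(gn)] <- 0
    raw[i, ] <- apply(mu[lg, , drop = FALSE], 2, max)
    norm[i, ] <- apply(gn, 2, max)
    nDet[i] <- max(counts[lg])
    keep[i] <- TRUE
  }
  raw <- raw[keep, , drop = FALSE]
  norm <- norm[keep, , drop = FALSE]
  structure(list(raw = raw, norm = norm,
                 expressed = norm > exprThreshold,
                 nCellsDetected = nDet[keep],
                 multimeric = isMultimeric(catalog)[rownames(raw)],
                 exprThreshold = exprThreshold),
            class = "ProductionMap")
}

#' @export
print.ProductionMap <- function(x, ...) {
  cat("ProductionMap:", nrow(x$norm), "cytokines x", ncol(x$norm),
      "cell types;", sum(x$expressed), "expressed entries (threshold >",
      x$exprThreshold, ")\n")
  invisible(x)
}

#' Receptor expression map
#'
#' A receptor complex is expressed in a cell type only when every
#' component gene's mean normalized expression (all conditions) exceeds
#' \code{threshold}; a cytokine is receptor-positive when any of its
#' receptor options is expressed.
#'
#' @param x normalized compendium.
#' @param catalog a \linkS4class{CytokineCatalog}.
#' @param threshold per-component expression cutoff in expression units
#'   (default 0.1).
#' @return logical cytokines x cell types matrix (FALSE where a cytokine
#'   has no receptor option with all components present).
#' @export
receptorMap <- function(x, catalog, threshold = 0.1) {
  allGenes <- unique(unlist(lapply(receptorOptions(catalog), unlist)))
  mu <- .meanByCellType(x, allGenes)
  cts <- sort(unique(cellTypes(x)))
  nms <- cytokineNames(catalog)
  out <- matrix(FALSE, length(nms), length(cts),
                dimnames = list(nms, cts))
  for (i in seq_along(nms)) {
    for (opt in receptorOptions(catalog, nms[i])) {
      if (!all(opt %in% rownames(mu))) next
      out[i, ] <- out[i, ] |
        apply(mu[opt, , drop = FALSE] > threshold, 2, all)
    }
  }
  out
}

# normalize signature input to a (cytokine, cell_type, n_degs) table
.degCounts <- function(signatures) {
  if (is.data.frame(signatures)) {
    stopifnot(all(c("cytokine", "cell_type", "n_degs") %in%
                  colnames(signatures)))
    return(signatures[, c("cytokine", "cell_type", "n_degs")])
  }
  do.call(rbind, lapply(signatures, function(s)
    data.frame(cytokine = s@cytokine, cell_type = s@cellType,
               n_degs = nrow(s@entries), stringsAsFactors = FALSE)))
}

.emptyEdges <- function() {
  data.frame(source = character(), cytokine = character(),
             multimeric = logical(), target = character(),
             evidence = character(), annotation = numeric(),
             stringsAsFactors = FALSE)
}

#' Ligand-response interactome
#'
#' Edge source -> cytokine -> target whenever the source cell type
#' expresses the cytokine (production map flag) and the target's signature
#' for that cytokine holds more than \code{minDegs} DEGs (strict).
#' Heteromeric cytokines carry a \code{multimeric} flag (asterisk in
#' exports).
#'
#' @param production a \code{\link{productionMap}} result.
#' @param signatures list of \linkS4class{CytokineSignature} or a
#'   data.frame with \code{cytokine}, \code{cell_type}, \code{n_degs}.
#' @param minDegs responsiveness cutoff (strictly greater; default 10).
#' @return data.frame of edges (source, cytokine, multimeric, target,
#'   evidence, annotation = n_degs).
#' @export
responseInteractome <- function(production, signatures, minDegs = 10) {
  degs <- .degCounts(signatures)
  edges <- list()
  for (cyt in rownames(production$norm)) {
    sources <- colnames(production$expressed)[production$expressed[cyt, ]]
    if (!length(sources)) next
    hits <- degs[degs$cytokine == cyt & degs$n_degs > minDegs, ,
                 drop = FALSE]
    for (src in sources) for (j in seq_len(nrow(hits)))
      edges[[length(edges) + 1L]] <- data.frame(
        source = src, cytokine = cyt,
        multimeric = unname(production$multimeric[cyt]),
        target = hits$cell_type[j], evidence = "response",
        annotation = hits$n_degs[j], stringsAsFactors = FALSE)
  }
  if (!length(edges)) return(.emptyEdges())
  do.call(rbind, edges)
}

#' Ligand-receptor interactome
#'
#' Edge source -> cytokine -> target whenever the source expresses the
#' cytokine (same production side as the ligand-response interactome) and
#' the target is receptor-positive for it.
#'
#' @param production a \code{\link{productionMap}} result.
#' @param receptors a \code{\link{receptorMap}} matrix on the same
#'   cell-type vocabulary.
#' @return data.frame of edges (annotation = 1 for receptor evidence).
#' @export
receptorInteractome <- function(production, receptors) {
  edges <- list()
  common <- intersect(rownames(production$norm), rownames(receptors))
  for (cyt in common) {
    sources <- colnames(production$expressed)[production$expressed[cyt, ]]
    targets <- colnames(receptors)[receptors[cyt, ]]
    for (src in sources) for (tg in targets)
      edges[[length(edges) + 1L]] <- data.frame(
        source = src, cytokine = cyt,
        multimeric = unname(production$multimeric[cyt]),
        target = tg, evidence = "receptor", annotation = 1,
        stringsAsFactors = FALSE)
  }
  if (!length(edges)) return(.emptyEdges())
  do.call(rbind, edges)
}

#' Compare two interactomes
#'
#' Exact partition of edges keyed by (source, cytokine, target).
#'
#' @param a,b edge data.frames.
#' @return list with \code{common}, \code{onlyA}, \code{onlyB} edge keys.
#' @export
compareInteractomes <- function(a, b) {
  key <- function(e) if (!nrow(e)) character() else
    paste(e$source, e$cytokine, e$target, sep = "|")
  ka <- unique(key(a)); kb <- unique(key(b))
  list(common = intersect(ka, kb),
       onlyA = setdiff(ka, kb),
       onlyB = setdiff(kb, ka))
}

#' Correlation between cell-type abundance and cytokine production breadth
#'
#' x = log10 abundance of each cell type among PBS control cells; y =
#' number of catalog cytokines detected in an equal-size sample of the
#' cell type's cells (any ligand gene with mean normalized expression
#' above \code{detectionThreshold}). Pearson r with its two-sided t-test
#' p-value.
#'
#' @param x normalized compendium.
#' @param catalog a \linkS4class{CytokineCatalog}.
#' @param nCellsPerType equal sample size per cell type (default: size of
#'   the smallest cell type).
#' @param detectionThreshold detection cutoff (default 0.1).
#' @param seed sampling seed.
#' @return list with \code{r}, \code{p}, and the per-type table.
#' @export
abundanceProductionCorrelation <- function(x, catalog,
                                           nCellsPerType = NULL,
                                           detectionThreshold = 0.1,
                                           seed = 1) {
  cts <- sort(unique(cellTypes(x)))
  abun <- vapply(cts, function(ct)
    sum(cellTypes(x) == ct & cellConditions(x) == .PBS), 0)
  if (any(abun == 0)) {
    warning("cell type(s) without PBS cells dropped: ",
            paste(cts[abun == 0], collapse = ", "))
    cts <- cts[abun > 0]; abun <- abun[abun > 0]
  }
  sizes <- vapply(cts, function(ct) sum(cellTypes(x) == ct), 0)
  if (is.null(nCellsPerType)) nCellsPerType <- min(sizes)
  allGenes <- intersect(unique(unlist(ligandGenes(catalog))), rownames(x))
  m <- .expr(x)[allGenes, , drop = FALSE]
  lg <- ligandGenes(catalog)
  nCyt <- .withSeed(seed, vapply(cts, function(ct) {
    idx <- which(cellTypes(x) == ct)
    idx <- sample(idx, min(nCellsPerType, length(idx)))
    mu <- Matrix::rowMeans(m[, idx, drop = FALSE])
    sum(vapply(lg, function(g)
      any(mu[intersect(g, allGenes)] > detectionThreshold), TRUE))
  }, 0))
  tab <- data.frame(cell_type = cts, abundance = abun,
                    log10_abundance = log10(abun),
                    n_cytokines_detected = nCyt,
                    stringsAsFactors = FALSE)
  if (length(cts) < 3L || stats::sd(nCyt) == 0 ||
      stats::sd(tab$log10_abundance) == 0) {
    if (length(cts) >= 2L && stats::sd(nCyt) == 0)
      warning("cytokine counts are constant; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, table = tab))
  }
  ct <- cor.test(tab$log10_abundance, tab$n_cytokines_detected)
  list(r = unname(ct$estimate), p = ct$p.value, table = tab)
}

#' Write an interactome edge list as TSV
#'
#' @param edges edge data.frame; the multimeric flag is rendered as an
#'   asterisk column.
#' @param path output path.
#' @export
writeInteractome <- function(edges, path) {
  out <- edges
  out$asterisk <- ifelse(out$multimeric, "*", "")
  out$multimeric <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
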