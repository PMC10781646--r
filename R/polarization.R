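# Cytokine-driven polarization states: discriminating genes, graph
# subclustering, hypergeometric state calling, markers, cross-state
# similarity and canonical naming.

#' Jaccard similarity of two sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; 1 when both sets are empty (identical),
#' per the convention that the diagonal of a Jaccard matrix is 1.
#'
#' @param a,b character vectors.
#' @return similarity in \[0, 1\].
#' @examples
#' jaccardIndex(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccardIndex <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Genes discriminating cytokine responses within a cell type
#'
#' Genes whose |log2FC| versus PBS exceeds \code{fcThreshold} under at
#' least one cytokine, after removing dissociation-stress, cell-cycle,
#' mitochondrial and ribosomal genes.
#'
#' @param x normalized compendium.
#' @param cellType cell type to analyse.
#' @param fcThreshold absolute log2FC cutoff, typically in \[0.75, 1.5\]
#'   depending on cell type (default 0.75).
#' @param policy exclusion policy (defaults to the polarization policy:
#'   dissociation + cell cycle on, unlabelled off, no detection filter).
#' @return character vector of genes; errors (advising a lower threshold)
#'   when empty.
#' @export
discriminatingGenes <- function(x, cellType, fcThreshold = 0.75,
                                policy = exclusionPolicy(
                                  unlabelled = FALSE, dissociation = TRUE,
                                  cellCycle = TRUE,
                                  minCellsExpressed = 0)) {
  m <- .expr(x)
  ic <- .cellsOf(x, cellType, .PBS)
  if (!length(ic)) stop("no PBS cells for ", cellType)
  ctrlMean <- expm1(m[, ic, drop = FALSE])
  ctrlMean <- Matrix::rowMeans(ctrlMean)
  maxAbs <- rep(0, nrow(m))
  for (cyt in cytokineConditions(x)) {
    it <- .cellsOf(x, cellType, cyt)
    if (!length(it)) next
    tm <- Matrix::rowMeans(expm1(m[, it, drop = FALSE]))
    fc <- abs(log2((tm + 1) / (ctrlMean + 1)))
    maxAbs <- pmax(maxAbs, fc)
  }
  genes <- rownames(m)[maxAbs > fcThreshold]
  genes <- suppressMessages(applyExclusions(genes, policy))
  if (!length(genes))
    stop("no discriminating genes at |log2FC| > ", fcThreshold,
         "; try a lower threshold")
  genes
}

#' Graph-based subclustering of cells
#'
#' PCA on the selected genes followed by Louvain community detection on a
#' k-nearest-neighbour graph of the principal components. Deterministic
#' for a fixed seed; singleton clusters are merged into the cluster with
#' the nearest centroid.
#'
#' @param x normalized compendium (or any genes x cells matrix).
#' @param genes genes to cluster on (matrix rows used when \code{x} is a
#'   matrix and \code{genes} is NULL).
#' @param cells optional cell subset (column names or indices).
#' @param nPcs number of principal components (default 10, reduced to the
#'   available rank).
#' @param kNeighbours neighbours per cell in the graph (default 20).
#' @param resolution Louvain resolution (default 0.5).
#' @param seed clustering seed.
#' @return integer cluster labels named by cell.
#' @export
subcluster <- function(x, genes = NULL, cells = NULL, nPcs = 10,
                       kNeighbours = 20, resolution = 0.5, seed = 1) {
  m <- if (is(x, "CytokineCompendium")) .expr(x) else x
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  n <- ncol(m)
  if (n <= nPcs)
    stop("need more cells (", n, ") than principal components (", nPcs, ")")
  X <- t(as.matrix(m))
  sds <- apply(X, 2, stats::sd)
  X <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  nPcs <- min(nPcs, n - 1L, ncol(X))
  pcs <- prcomp(X, rank. = nPcs, center = FALSE, scale. = FALSE)$x
  d <- as.matrix(dist(pcs))
  diag(d) <- Inf
  k <- min(kNeighbours, n - 1L)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- .withSeed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  labels <- igraph::membership(comm)
  # merge singleton clusters into the nearest cluster by centroid distance
  tab <- table(labels)
  singletons <- as.integer(names(tab)[tab == 1L])
  for (s in singletons) {
    i <- which(labels == s)
    others <- setdiff(unique(labels), s)
    if (!length(others)) break
    centDist <- vapply(others, function(cl) {
      idx <- which(labels == cl)
      sqrt(sum((colMeans(pcs[idx, , drop = FALSE]) - pcs[i, ])^2))
    }, 0)
    labels[i] <- others[which.min(centDist)]
  }
  labels <- as.integer(factor(labels))
  stats::setNames(labels, colnames(m))
}

#' Call polarization states from cluster composition
#'
#' For every (cluster, cytokine) pair, an upper-tail hypergeometric test of
#' the cytokine's cells in the cluster (population: all cells supplied;
#' successes: that cytokine's cells; draws: the cluster). BH FDR is applied
#' across all pairs; clusters with any driver at FDR < \code{alpha} become
#' states, with drivers sorted by FDR.
#'
#' @param labels named integer cluster labels (from
#'   \code{\link{subcluster}}).
#' @param conditionLabels per-cell condition (cytokine or \code{"PBS"}),
#'   aligned with \code{labels}.
#' @param cellType cell type annotation stored on the states.
#' @param alpha driver FDR threshold (default 0.01).
#' @return list of \linkS4class{PolarizationState} (possibly empty).
#' @export
callStates <- function(labels, conditionLabels, cellType = "cells",
                       alpha = 0.01) {
  stopifnot(length(labels) == length(conditionLabels))
  N <- length(labels)
  cyts <- setdiff(unique(conditionLabels), .PBS)
  rows <- list()
  for (cl in sort(unique(labels))) {
    inCl <- labels == cl
    for (cyt in cyts) {
      K <- sum(conditionLabels == cyt)
      k <- sum(inCl & conditionLabels == cyt)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, cytokine = cyt, k = k,
        p = hypergeometricTest(k, N, K, sum(inCl)),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$fdr <- p.adjust(tab$p, method = "BH")
  states <- list()
  for (cl in sort(unique(labels))) {
    drv <- tab[tab$cluster == cl & tab$fdr < alpha, , drop = FALSE]
    if (!nrow(drv)) next
    drv <- drv[order(drv$fdr, drv$p), c("cytokine", "k", "p", "fdr")]
    rownames(drv) <- NULL
    states[[length(states) + 1L]] <- new(
      "PolarizationState", id = "", cellType = cellType,
      cells = names(labels)[labels == cl], drivers = drv,
      markers = data.frame(), profile = numeric())
  }
  states
}

#' Marker genes of a polarization state
#'
#' Rank-sum differential expression between the state's cells and all
#' other cells of the same cell type; returns significantly overexpressed
#' genes sorted by descending log2FC.
#'
#' @param state a \linkS4class{PolarizationState}.
#' @param x normalized compendium.
#' @param fdrMax significance cutoff (default 0.05).
#' @return the state with its \code{markers} slot filled (data.frame with
#'   gene, log2fc, p, fdr).
#' @export
stateMarkers <- function(state, x, fdrMax = 0.05) {
  ctCells <- colnames(x)[cellTypes(x) == state@cellType]
  inState <- ctCells %in% state@cells
  if (all(inState)) stop("state contains every cell of the cell type")
  if (sum(inState) < 2L || sum(!inState) < 2L)
    stop("need >= 2 cells inside and outside the state")
  m <- as.matrix(.expr(x)[, ctCells, drop = FALSE])
  rs <- .rankSumRows(m, which(inState), which(!inState))
  lfc <- .rowLog2Fc(m[, inState, drop = FALSE],
                    m[, !inState, drop = FALSE])
  tab <- data.frame(gene = rownames(m), log2fc = lfc, p = rs$p,
                    fdr = p.adjust(rs$p, "BH"), row.names = NULL,
                    stringsAsFactors = FALSE)
  tab <- tab[tab$fdr < fdrMax & tab$log2fc > 0, , drop = FALSE]
  tab <- tab[order(-tab$log2fc), , drop = FALSE]
  rownames(tab) <- NULL
  state@markers <- tab
  state
}

# differential profile (state mean - PBS mean, log space) and fold-change
# vector of a state versus PBS cells of its cell type
.stateProfile <- function(state, x) {
  m <- .expr(x)
  ic <- .cellsOf(x, state@cellType, .PBS)
  si <- match(state@cells, colnames(x))
  diffLog <- Matrix::rowMeans(m[, si, drop = FALSE]) -
    Matrix::rowMeans(m[, ic, drop = FALSE])
  fc <- .rowLog2Fc(m[, si, drop = FALSE], m[, ic, drop = FALSE])
  list(diff = diffLog, fc = fc)
}

#' Cross-state similarity, uniqueness and dendrogram
#'
#' Pearson correlation between PBS-subtracted state profiles; Jaccard
#' similarity of the up- and downregulated gene sets (|log2FC| >
#' \code{fcCut} versus PBS, up and down computed separately); uniqueness
#' of each state as the inverse of its mean off-diagonal Jaccard
#' similarity (up and down averaged); and an average-linkage dendrogram on
#' the Euclidean distances between rows of the Pearson matrix.
#'
#' @param states list of \linkS4class{PolarizationState} (>= 2), named or
#'   not (ids are used when present).
#' @param x normalized compendium providing PBS profiles.
#' @param fcCut fold-change cutoff for the Jaccard gene sets.
#' @return list with \code{pearson}, \code{jaccardUp}, \code{jaccardDown},
#'   \code{uniqueness}, \code{hclust}.
#' @export
stateSimilarity <- function(states, x, fcCut = 0.5) {
  if (length(states) < 2L) stop("need at least 2 states")
  ids <- vapply(seq_along(states), function(i) {
    s <- states[[i]]
    if (nzchar(s@id)) s@id else paste0("state", i)
  }, "")
  prof <- lapply(states, .stateProfile, x = x)
  D <- sapply(prof, `[[`, "diff")
  colnames(D) <- ids
  zeroVar <- apply(D, 2, stats::sd) == 0
  P <- suppressWarnings(cor(D))
  P[zeroVar, ] <- NA; P[, zeroVar] <- NA
  ups <- lapply(prof, function(p) names(p$fc)[p$fc > fcCut])
  downs <- lapply(prof, function(p) names(p$fc)[p$fc < -fcCut])
  n <- length(states)
  JU <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    jaccardIndex(ups[[i]], ups[[j]])))
  JD <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    jaccardIndex(downs[[i]], downs[[j]])))
  dimnames(JU) <- dimnames(JD) <- list(ids, ids)
  # uniqueness from the signed combined response sets, so states without
  # downregulated genes are not penalized by an empty-set convention
  signed <- lapply(seq_len(n), function(i)
    c(paste0("+", ups[[i]], recycle0 = TRUE),
      paste0("-", downs[[i]], recycle0 = TRUE)))
  JS <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    jaccardIndex(signed[[i]], signed[[j]])))
  offMean <- vapply(seq_len(n), function(i) mean(JS[i, -i]), 0)
  uniq <- ifelse(offMean > 0, 1 / offMean, Inf)
  hc <- if (all(!zeroVar))
    hclust(dist(P), method = "average") else NULL
  list(pearson = P, jaccardUp = JU, jaccardDown = JD,
       uniqueness = stats::setNames(uniq, ids), hclust = hc)
}

#' Export a state dendrogram as Newick
#'
#' @param similarity result of \code{\link{stateSimilarity}}.
#' @param path output file.
#' @export
writeStateTree <- function(similarity, path) {
  if (is.null(similarity$hclust)) stop("no dendrogram available")
  ape::write.tree(ape::as.phylo(similarity$hclust), file = path)
  invisible(path)
}

# cytokine -> reserved-letter class, from catalog families / names
.driverClass <- function(cytokine, catalog) {
  fam <- cytokineFamilies(catalog)
  f <- if (cytokine %in% names(fam)) fam[[cytokine]] else ""
  if (f == "Interferon-I") return("a")
  if (f == "Interferon-II") return("b")
  if (cytokine %in% c("IL-1a", "IL-1b")) return("c")
  if (cytokine == "TNF") return("d")
  ""
}

#' Assign canonical state identifiers
#'
#' Convention "<cell-type-abbrev>-<letters>": the letters a-d are reserved
#' for states whose top driver is a type I interferon, type II interferon,
#' IL-1a/IL-1b, or TNF respectively (largest state wins when several states
#' share a class); remaining states receive e, f, ... in order of
#' decreasing size (two-letter suffixes aa, ab, ... beyond z).
#'
#' @param states list of \linkS4class{PolarizationState}.
#' @param abbrev cell-type abbreviation used as the prefix.
#' @param catalog catalog providing interferon family assignments.
#' @return the states with \code{id} filled.
#' @export
nameStates <- function(states, abbrev, catalog = defaultCatalog()) {
  if (!length(states)) return(states)
  sizes <- vapply(states, function(s) length(s@cells), 0L)
  topDriver <- vapply(states, function(s)
    if (nrow(s@drivers)) s@drivers$cytokine[1L] else "", "")
  letter <- rep(NA_character_, length(states))
  for (cls in c("a", "b", "c", "d")) {
    cand <- which(vapply(topDriver, .driverClass, "",
                         catalog = catalog) == cls & is.na(letter))
    if (length(cand))
      letter[cand[which.max(sizes[cand])]] <- cls
  }
  suffixes <- c(letters, as.vector(t(outer(letters, letters, paste0))))
  # a-d are reserved for the four driver classes even when unused
  pool <- setdiff(suffixes[-(1:4)], letter[!is.na(letter)])
  rest <- which(is.na(letter))
  rest <- rest[order(-sizes[rest])]
  letter[rest] <- pool[seq_along(rest)]
  for (i in seq_along(states))
    states[[i]]@id <- paste0(abbrev, "-", letter[i])
  states
}

#' End-to-end polarization-state calling for one cell type
#'
#' Convenience pipeline: discriminating genes, subclustering, state
#' calling, marker derivation, profile computation and naming. When no
#' gene discriminates at the threshold the data are treated as unpolarized
#' and an empty state list is returned with a warning.
#'
#' @param x normalized compendium.
#' @param cellType cell type to analyse.
#' @param abbrev abbreviation for state ids (default: the cell type
#'   itself).
#' @param fcThreshold,nPcs,kNeighbours,resolution,alpha,seed forwarded to
#'   the stages.
#' @param catalog catalog for reserved-letter naming.
#' @param markers whether to fill state markers (rank-sum per state; the
#'   slowest step).
#' @return named list of \linkS4class{PolarizationState}.
#' @export
callPolarizationStates <- function(x, cellType, abbrev = cellType,
                                   fcThreshold = 0.75, nPcs = 10,
                                   kNeighbours = 20, resolution = 0.5,
                                   alpha = 0.01, seed = 1,
                                   catalog = defaultCatalog(),
                                   markers = FALSE) {
  genes <- tryCatch(discriminatingGenes(x, cellType, fcThreshold),
                    error = function(e) character())
  if (!length(genes)) {
    warning("no discriminating genes for ", cellType,
            "; returning no states")
    return(list())
  }
  cells <- colnames(x)[cellTypes(x) == cellType]
  labels <- subcluster(x, genes = genes, cells = cells, nPcs = nPcs,
                       kNeighbours = kNeighbours, resolution = resolution,
                       seed = seed)
  cond <- cellConditions(x)[match(names(labels), colnames(x))]
  states <- callStates(labels, cond, cellType = cellType, alpha = alpha)
  if (!length(states)) return(list())
  states <- lapply(states, function(s) {
    if (markers) s <- stateMarkers(s, x)
    s@profile <- .stateProfile(s, x)$diff
    s
  })
  states <- nameStates(states, abbrev, catalog)
  stats::setNames(states, vapply(states, function(s) s@id, ""))
}
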