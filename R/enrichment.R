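# Scoring user expression data against the reference: cytokine response
# enrichment (gene-set and transcriptome modes), polarization enrichment,
# cell-cell communication networks, and homolog mapping.

# normalize a user genes x cells matrix to 10,000-unit log1p values
.normalizeUserMatrix <- function(m) {
  m <- as.matrix(m)
  tot <- colSums(m)
  if (any(tot == 0)) stop("all-zero column(s) in user matrix")
  log1p(sweep(m, 2, 1e4 / tot, `*`))
}

# cosine projection of a differential vector onto PBS-centred reference
# cell profiles; zero-norm vectors project to 0
.projectionScores <- function(refMat, centre, d) {
  C <- as.matrix(refMat) - centre
  num <- as.vector(crossprod(C, d))
  den <- sqrt(colSums(C^2)) * sqrt(sum(d^2))
  out <- ifelse(den > 0, num / den, 0)
  stats::setNames(out, colnames(refMat))
}

#' Cytokine response enrichment of a gene set
#'
#' Score mode: per cell of the chosen reference cell type, the gene-set
#' score (sum of normalized expression over the set); per cytokine, a
#' two-sided rank-sum test of treated versus PBS scores with the mean
#' score difference as effect size; BH FDR across all cytokines.
#' Hypergeometric mode: upper-tail overlap of the set with each cytokine's
#' significant DEGs (FDR < \code{degFdr}), universe = all tested genes.
#'
#' @param geneSet non-empty character vector.
#' @param reference a normalized \linkS4class{CytokineCompendium}.
#' @param cellType reference cell type to compare against.
#' @param mode \code{"score"} or \code{"hypergeometric"}.
#' @param degFdr DEG cutoff for hypergeometric mode (default 0.01).
#' @return data.frame with one row per cytokine: \code{cytokine},
#'   \code{effect_size}, \code{p}, \code{fdr}, \code{direction} (score
#'   mode) or \code{overlap}, \code{signature_size}, \code{p}, \code{fdr}
#'   (hypergeometric mode), sorted by p.
#' @export
enrichGeneSet <- function(geneSet, reference, cellType,
                          mode = c("score", "hypergeometric"),
                          degFdr = 0.01) {
  mode <- match.arg(mode)
  if (!length(geneSet)) stop("empty gene set")
  if (!cellType %in% cellTypes(reference))
    stop("unknown cell type: ", cellType)
  cyts <- cytokineConditions(reference)
  if (mode == "score") {
    scores <- suppressWarnings(geneSetScore(reference, geneSet))
    ic <- .cellsOf(reference, cellType, .PBS)
    rows <- lapply(cyts, function(cyt) {
      it <- .cellsOf(reference, cellType, cyt)
      if (length(it) < 2L || length(ic) < 2L)
        return(data.frame(cytokine = cyt, effect_size = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      rs <- rankSumTest(scores[it], scores[ic])
      data.frame(cytokine = cyt,
                 effect_size = mean(scores[it]) - mean(scores[ic]),
                 p = rs$p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- p.adjust(out$p, method = "BH")
    out$direction <- ifelse(out$effect_size >= 0, "condition", "control")
  } else {
    universe <- rownames(reference)
    q <- intersect(geneSet, universe)
    rows <- lapply(cyts, function(cyt) {
      de <- tryCatch(differentialExpression(reference, cellType, cyt),
                     error = function(e) NULL)
      if (is.null(de))
        return(data.frame(cytokine = cyt, overlap = NA_integer_,
                          signature_size = NA_integer_, p = NA_real_,
                          stringsAsFactors = FALSE))
      sig <- de$gene[de$fdr < degFdr]
      k <- length(intersect(q, sig))
      data.frame(cytokine = cyt, overlap = k,
                 signature_size = length(sig),
                 p = hypergeometricTest(k, length(universe),
                                        length(sig), length(q)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- p.adjust(out$p, method = "BH")
  }
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cytokine response enrichment of an expression matrix pair
#'
#' The user's condition/control matrices are library-size normalized to
#' 10,000 units and log1p-transformed (unless already normalized) and
#' reduced to a single differential vector (mean condition minus mean
#' control). Genes are restricted to those shared with the reference whose
#' average reference expression in the cell type exceeds \code{minExpr}.
#' Every reference cell of the cell type is centred by the PBS mean and
#' the cosine similarity between the user differential vector and the
#' centred profile is the cell's projection score. Per cytokine, a
#' two-sided rank-sum test of projection scores (treated versus PBS) with
#' the mean difference as effect size; BH FDR across all cytokines.
#'
#' Per-gene contribution weights (product of the user differential and the
#' cytokine's mean reference differential) are attached as attribute
#' \code{"contributions"} (top genes per cytokine).
#'
#' @param userCondition,userControl genes x cells matrices (or vectors for
#'   a pseudobulk pair).
#' @param reference normalized \linkS4class{CytokineCompendium}.
#' @param cellType reference cell type.
#' @param minExpr reference mean-expression floor (default 0.25).
#' @param userNormalized set \code{TRUE} when the user matrices already
#'   hold log1p-normalized values.
#' @param catalog optional catalog for the receptor-expressed flag,
#'   evaluated on the user condition cells.
#' @param receptorThreshold receptor flag threshold (default 0.05).
#' @param nContributions top contributing genes stored per cytokine.
#' @return data.frame with columns \code{cytokine}, \code{effect_size},
#'   \code{p}, \code{fdr}, \code{direction}, \code{receptor_expressed},
#'   sorted by decreasing effect size.
#' @export
enrichTranscriptome <- function(userCondition, userControl, reference,
                                cellType, minExpr = 0.25,
                                userNormalized = FALSE, catalog = NULL,
                                receptorThreshold = 0.05,
                                nContributions = 10) {
  if (is.null(dim(userCondition)))
    userCondition <- matrix(userCondition, ncol = 1,
                            dimnames = list(names(userCondition), "cond"))
  if (is.null(dim(userControl)))
    userControl <- matrix(userControl, ncol = 1,
                          dimnames = list(names(userControl), "ctrl"))
  if (!userNormalized) {
    userCondition <- .normalizeUserMatrix(userCondition)
    userControl <- .normalizeUserMatrix(userControl)
  }
  if (!cellType %in% cellTypes(reference))
    stop("unknown cell type: ", cellType)
  ctIdx <- .cellsOf(reference, cellType)
  refM <- .expr(reference)[, ctIdx, drop = FALSE]
  refMean <- Matrix::rowMeans(refM)
  shared <- intersect(rownames(userCondition), rownames(reference))
  shared <- shared[refMean[shared] > minExpr]
  if (length(shared) < 10L)
    stop("fewer than 10 shared genes above the expression floor (",
         length(shared), ")")
  d <- rowMeans(userCondition[shared, , drop = FALSE]) -
    rowMeans(userControl[shared, , drop = FALSE])
  cond <- cellConditions(reference)[ctIdx]
  pbsMean <- Matrix::rowMeans(refM[shared, cond == .PBS, drop = FALSE])
  proj <- .projectionScores(refM[shared, , drop = FALSE], pbsMean, d)
  cyts <- cytokineConditions(reference)
  contrib <- list()
  rows <- lapply(cyts, function(cyt) {
    it <- which(cond == cyt); ic <- which(cond == .PBS)
    if (length(it) < 2L || length(ic) < 2L)
      return(data.frame(cytokine = cyt, effect_size = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    rs <- rankSumTest(proj[it], proj[ic])
    refDiff <- Matrix::rowMeans(refM[shared, it, drop = FALSE]) - pbsMean
    w <- d * refDiff
    contrib[[cyt]] <<- sort(w, decreasing = TRUE)[
      seq_len(min(nContributions, length(w)))]
    data.frame(cytokine = cyt,
               effect_size = mean(proj[it]) - mean(proj[ic]),
               p = rs$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$effect_size >= 0, "condition", "control")
  out$receptor_expressed <- NA
  if (!is.null(catalog)) {
    userMean <- rowMeans(userCondition)
    out$receptor_expressed <- vapply(out$cytokine, function(cyt) {
      opts <- receptorOptions(catalog, cyt)
      any(vapply(opts, function(o)
        all(o %in% names(userMean)) &&
          all(userMean[o] > receptorThreshold), TRUE))
    }, TRUE)
  }
  out <- out[order(-out$effect_size), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contributions") <- contrib
  attr(out, "n_genes") <- length(shared)
  out
}

#' Polarization enrichment of an expression matrix pair
#'
#' Same projection machinery as \code{\link{enrichTranscriptome}}, but the
#' rank-sum test contrasts projection scores on each state's member cells
#' against the other cells of the cell type. When at least one state is
#' significant (FDR < 0.05) the positive effect sizes are normalized by
#' their maximum to \[0, 1\]; otherwise every normalized score is 0
#' (unpolarized input).
#'
#' @param userCondition,userControl user matrices as in
#'   \code{\link{enrichTranscriptome}}.
#' @param states named list of \linkS4class{PolarizationState} for the
#'   cell type.
#' @param reference normalized compendium.
#' @param cellType the cell type.
#' @param minExpr reference expression floor.
#' @param userNormalized as above.
#' @return data.frame with columns \code{state}, \code{effect_size},
#'   \code{normalized_es}, \code{p}, \code{fdr}, plus attribute
#'   \code{"polarized"}.
#' @export
enrichPolarization <- function(userCondition, userControl, states,
                               reference, cellType, minExpr = 0.25,
                               userNormalized = FALSE) {
  if (!length(states)) {
    out <- data.frame(state = character(), effect_size = numeric(),
                      normalized_es = numeric(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
    attr(out, "polarized") <- FALSE
    return(out)
  }
  if (is.null(dim(userCondition)))
    userCondition <- matrix(userCondition, ncol = 1,
                            dimnames = list(names(userCondition), "cond"))
  if (is.null(dim(userControl)))
    userControl <- matrix(userControl, ncol = 1,
                          dimnames = list(names(userControl), "ctrl"))
  if (!userNormalized) {
    userCondition <- .normalizeUserMatrix(userCondition)
    userControl <- .normalizeUserMatrix(userControl)
  }
  ctIdx <- .cellsOf(reference, cellType)
  refM <- .expr(reference)[, ctIdx, drop = FALSE]
  refMean <- Matrix::rowMeans(refM)
  shared <- intersect(rownames(userCondition), rownames(reference))
  shared <- shared[refMean[shared] > minExpr]
  if (length(shared) < 10L)
    stop("fewer than 10 shared genes above the expression floor")
  d <- rowMeans(userCondition[shared, , drop = FALSE]) -
    rowMeans(userControl[shared, , drop = FALSE])
  cond <- cellConditions(reference)[ctIdx]
  pbsMean <- Matrix::rowMeans(refM[shared, cond == .PBS, drop = FALSE])
  proj <- .projectionScores(refM[shared, , drop = FALSE], pbsMean, d)
  cellIds <- colnames(refM)
  ids <- names(states)
  if (is.null(ids)) ids <- vapply(seq_along(states), function(i) {
    s <- states[[i]]; if (nzchar(s@id)) s@id else paste0("state", i)
  }, "")
  rows <- lapply(seq_along(states), function(i) {
    inState <- cellIds %in% states[[i]]@cells
    if (sum(inState) < 2L || sum(!inState) < 2L)
      return(data.frame(state = ids[i], effect_size = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    rs <- rankSumTest(proj[inState], proj[!inState])
    data.frame(state = ids[i],
               effect_size = mean(proj[inState]) - mean(proj[!inState]),
               p = rs$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  polarized <- any(!is.na(out$fdr) & out$fdr < 0.05)
  es <- pmax(out$effect_size, 0)
  out$normalized_es <- if (polarized && max(es, na.rm = TRUE) > 0)
    es / max(es, na.rm = TRUE) else rep(0, nrow(out))
  attr(out, "polarized") <- polarized
  rownames(out) <- NULL
  out
}

#' Cell-cell communication network from enrichment results
#'
#' Producer edges (cell type -> cytokine) where the user cell type's mean
#' expression of at least one ligand subunit exceeds
#' \code{productionThreshold} (heteromers flagged multimeric); responder
#' edges (cytokine -> cell type) where the cell type's enrichment result
#' shows a positive effect at FDR < \code{respFdr}. Receptor flags at
#' \code{receptorThreshold} are carried per responder edge when present in
#' the enrichment results.
#'
#' @param enrichResults named list (by cell type) of
#'   \code{\link{enrichTranscriptome}} results.
#' @param userExpr named list (by cell type) of normalized genes x cells
#'   user matrices used for production calls.
#' @param catalog a \linkS4class{CytokineCatalog}.
#' @param productionThreshold producer cutoff (default 0.1).
#' @param respFdr responder FDR cutoff (default 0.01).
#' @return list with data.frames \code{producers} and \code{responders}.
#' @export
communicationNetwork <- function(enrichResults, userExpr, catalog,
                                 productionThreshold = 0.1,
                                 respFdr = 0.01) {
  producers <- list()
  for (ct in names(userExpr)) {
    mu <- rowMeans(as.matrix(userExpr[[ct]]))
    for (cyt in cytokineNames(catalog)) {
      lg <- intersect(ligandGenes(catalog, cyt), names(mu))
      if (length(lg) && any(mu[lg] > productionThreshold))
        producers[[length(producers) + 1L]] <- data.frame(
          cell_type = ct, cytokine = cyt,
          multimeric = unname(isMultimeric(catalog, cyt)),
          stringsAsFactors = FALSE)
    }
  }
  responders <- list()
  for (ct in names(enrichResults)) {
    r <- enrichResults[[ct]]
    hit <- !is.na(r$fdr) & r$fdr < respFdr & r$effect_size > 0
    if (any(hit))
      responders[[length(responders) + 1L]] <- data.frame(
        cytokine = r$cytokine[hit], cell_type = ct,
        effect_size = r$effect_size[hit], fdr = r$fdr[hit],
        receptor_expressed = if ("receptor_expressed" %in% colnames(r))
          r$receptor_expressed[hit] else NA,
        stringsAsFactors = FALSE)
  }
  list(producers = if (length(producers)) do.call(rbind, producers)
       else data.frame(cell_type = character(), cytokine = character(),
                       multimeric = logical()),
       responders = if (length(responders)) do.call(rbind, responders)
       else data.frame(cytokine = character(), cell_type = character(),
                       effect_size = numeric(), fdr = numeric(),
                       receptor_expressed = logical()))
}

#' Map gene symbols between mouse and human
#'
#' One-to-one mappings from a homolog table are applied; one-to-many
#' mappings are dropped with a warning; unmapped symbols are returned
#' separately. The packaged table is a small curated subset of common
#' immune genes -- supply a full table for genome-wide conversion.
#'
#' @param genes character vector of symbols.
#' @param from,to \code{"mouse"} or \code{"human"}.
#' @param table optional data.frame with columns \code{mouse},
#'   \code{human}.
#' @return list with \code{mapped} (named character vector) and
#'   \code{unmapped}.
#' @export
mapHomologs <- function(genes, from = "mouse", to = "human",
                        table = NULL) {
  if (!from %in% c("mouse", "human") || !to %in% c("mouse", "human"))
    stop("species must be 'mouse' or 'human'")
  if (from == to)
    return(list(mapped = stats::setNames(genes, genes),
                unmapped = character()))
  if (is.null(table))
    table <- read.table(system.file("extdata", "homologs_subset.tsv",
                                    package = "cytodict", mustWork = TRUE),
                        header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  src <- table[[from]]; dst <- table[[to]]
  multi <- unique(src[duplicated(src)])
  if (length(intersect(genes, multi)))
    warning(length(intersect(genes, multi)),
            " gene(s) with one-to-many homology dropped")
  ok <- !src %in% multi
  map <- stats::setNames(dst[ok], src[ok])
  hit <- genes %in% names(map)
  list(mapped = stats::setNames(unname(map[genes[hit]]), genes[hit]),
       unmapped = c(genes[!hit], intersect(genes, multi)))
}
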