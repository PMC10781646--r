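# Per-cell-type cytokine differential-expression signatures, the 0-100
# response-magnitude map, replicate concordance, gene-set scoring and the
# induced-secondary-response analysis.

#' Differential expression between a cytokine treatment and PBS control
#'
#' Two-sided Wilcoxon rank-sum test per gene on normalized expression of
#' cells of one cell type, cytokine-treated versus PBS-treated. P-values
#' are exact (full enumeration, tie-aware) when both groups have at most
#' eight cells, tie-corrected normal approximation otherwise; FDR is
#' Benjamini-Hochberg across the tested genes.
#'
#' @param x a normalized \linkS4class{CytokineCompendium}.
#' @param cellType cell type to analyse.
#' @param cytokine condition to contrast against \code{"PBS"}.
#' @param genes optional gene subset (default all genes).
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{p},
#'   \code{fdr}, \code{pct_treated}, \code{pct_control}.
#' @export
differentialExpression <- function(x, cellType, cytokine, genes = NULL) {
  if (!isNormalized(x))
    stop("differentialExpression expects a normalized compendium")
  it <- .cellsOf(x, cellType, cytokine)
  ic <- .cellsOf(x, cellType, .PBS)
  if (length(it) < 2L || length(ic) < 2L)
    stop("need >= 2 cells per group for ", cellType, "/", cytokine,
         " (treated: ", length(it), ", PBS: ", length(ic), ")")
  m <- .expr(x)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  md <- as.matrix(m[, c(it, ic), drop = FALSE])
  i1 <- seq_along(it); i2 <- length(it) + seq_along(ic)
  rs <- .rankSumRows(md, i1, i2)
  lfc <- .rowLog2Fc(md[, i1, drop = FALSE], md[, i2, drop = FALSE])
  data.frame(
    gene = rownames(md),
    log2fc = lfc,
    p = rs$p,
    fdr = p.adjust(rs$p, method = "BH"),
    pct_treated = rowMeans(md[, i1, drop = FALSE] > 0),
    pct_control = rowMeans(md[, i2, drop = FALSE] > 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

# per-replicate log2 fold changes; treated replicate r is paired with PBS
# cells of the same replicate ID when present, otherwise with all PBS cells
.perReplicateFc <- function(x, cellType, cytokine, genes) {
  m <- .expr(x)[genes, , drop = FALSE]
  it <- .cellsOf(x, cellType, cytokine)
  ic <- .cellsOf(x, cellType, .PBS)
  reps <- sort(unique(replicates(x)[it]))
  out <- sapply(reps, function(r) {
    ti <- it[replicates(x)[it] == r]
    ci <- ic[replicates(x)[ic] == r]
    if (!length(ci)) ci <- ic
    .rowLog2Fc(m[, ti, drop = FALSE], m[, ci, drop = FALSE])
  })
  matrix(out, nrow = length(genes),
         dimnames = list(genes, reps))
}

#' Build a filtered cytokine signature
#'
#' Applies, in order: FDR < \code{fdrMax}; |log2FC| > \code{minAbsLog2Fc};
#' expression in more than \code{minPct} of treated cells (upregulated) or
#' control cells (downregulated); the same fold-change threshold satisfied
#' in the pooled direction by at least \code{minReplicates} replicates; and
#' category exclusions (ribosomal, mitochondrial, unlabelled by default).
#' Attrition is logged per filter.
#'
#' @param x normalized compendium.
#' @param cellType,cytokine the contrast.
#' @param fdrMax,minAbsLog2Fc,minPct,minReplicates filter cascade
#'   thresholds (defaults 0.05, 0.25, 0.10, 2).
#' @param policy exclusion policy for the category filter (detection-count
#'   filtering is not re-applied here).
#' @param de optional precomputed \code{\link{differentialExpression}}
#'   table for this contrast, to avoid recomputation.
#' @return a \linkS4class{CytokineSignature}.
#' @export
buildSignature <- function(x, cellType, cytokine, fdrMax = 0.05,
                           minAbsLog2Fc = 0.25, minPct = 0.10,
                           minReplicates = 2,
                           policy = exclusionPolicy(minCellsExpressed = 0),
                           de = NULL) {
  if (is.null(de)) de <- differentialExpression(x, cellType, cytokine)
  n0 <- nrow(de)
  de <- de[de$fdr < fdrMax, , drop = FALSE]
  n1 <- nrow(de)
  de <- de[abs(de$log2fc) > minAbsLog2Fc, , drop = FALSE]
  n2 <- nrow(de)
  up <- de$log2fc > 0
  de <- de[(up & de$pct_treated > minPct) |
           (!up & de$pct_control > minPct), , drop = FALSE]
  n3 <- nrow(de)
  if (nrow(de)) {
    repFc <- .perReplicateFc(x, cellType, cytokine, de$gene)
    dir <- sign(de$log2fc)
    pass <- repFc * dir > minAbsLog2Fc
    de$n_replicates_passing <- rowSums(pass)
    de <- de[de$n_replicates_passing >= minReplicates, , drop = FALSE]
  } else de$n_replicates_passing <- integer(0)
  n4 <- nrow(de)
  catPolicy <- policy
  catPolicy$minCellsExpressed <- 0
  catPolicy$overabundant <- FALSE
  de <- de[de$gene %in% suppressMessages(
    applyExclusions(de$gene, catPolicy)), , drop = FALSE]
  .msg("signature ", cellType, "/", cytokine, ": ", n0, " tested -> ",
       n1, " (fdr) -> ", n2, " (fc) -> ", n3, " (pct) -> ", n4,
       " (replicates) -> ", nrow(de), " (categories)")
  de$direction <- ifelse(de$log2fc > 0, "up", "down")
  rownames(de) <- NULL
  new("CytokineSignature", cellType = cellType, cytokine = cytokine,
      entries = de)
}

#' Overall response magnitude per cytokine for one cell type
#'
#' For each cytokine with at least \code{minCells} cells of the cell type,
#' samples at most \code{maxCells} cells per condition (seeded) and
#' computes the Euclidean distance between the treated and PBS centroid
#' vectors over all genes. Across cytokines within the cell type, distances
#' above the 95th percentile (linear-interpolation quantile) are replaced
#' by that percentile, then linearly scaled so the maximum is 100.
#'
#' @param x normalized compendium.
#' @param cellType cell type to analyse.
#' @param maxCells per-condition sampling cap (default 100).
#' @param minCells minimum treated cells for a cytokine to be reported
#'   (default 5).
#' @param winsorProb percentile used for winsorization (default 0.95).
#' @param signatures optional list of \linkS4class{CytokineSignature}
#'   objects used to fill \code{n_degs}.
#' @param seed sampling seed (recorded in the output).
#' @return data.frame with columns \code{cytokine}, \code{cell_type},
#'   \code{n_cells_sampled}, \code{distance}, \code{magnitude},
#'   \code{n_degs}, plus a \code{seed} attribute.
#' @export
responseMagnitude <- function(x, cellType, maxCells = 100, minCells = 5,
                              winsorProb = 0.95, signatures = NULL,
                              seed = 1) {
  if (!cellType %in% cellTypes(x)) stop("unknown cell type: ", cellType)
  m <- .expr(x)
  ic <- .cellsOf(x, cellType, .PBS)
  rows <- list()
  .withSeed(seed, {
    ics <- if (length(ic) > maxCells) sample(ic, maxCells) else ic
    ctrlCentroid <- Matrix::rowMeans(m[, ics, drop = FALSE])
    for (cyt in cytokineConditions(x)) {
      it <- .cellsOf(x, cellType, cyt)
      if (length(it) > maxCells) it <- sample(it, maxCells)
      if (length(it) < minCells) next
      centroid <- Matrix::rowMeans(m[, it, drop = FALSE])
      rows[[cyt]] <- data.frame(
        cytokine = cyt, cell_type = cellType,
        n_cells_sampled = length(it),
        distance = sqrt(sum((centroid - ctrlCentroid)^2)),
        stringsAsFactors = FALSE)
    }
  })
  if (!length(rows))
    stop("no cytokine has >= ", minCells, " cells for ", cellType)
  out <- do.call(rbind, rows)
  out$magnitude <- winsorizedScale(out$distance, winsorProb)
  out$n_degs <- NA_integer_
  if (!is.null(signatures))
    for (s in signatures)
      if (s@cellType == cellType)
        out$n_degs[out$cytokine == s@cytokine] <- nrow(s@entries)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Winsorize at a percentile, then scale the maximum to 100
#'
#' @param d non-negative distances.
#' @param prob winsorization percentile (type-7 quantile).
#' @return values in \[0, 100\] (all zero when every distance is zero).
#' @export
winsorizedScale <- function(d, prob = 0.95) {
  cap <- quantile(d, prob, type = 7, names = FALSE)
  d <- pmin(d, cap)
  if (max(d) <= 0) return(rep(0, length(d)))
  100 * d / max(d)
}

#' Replicate concordance of a signature
#'
#' Per replicate, the signature-gene vector of mean(treated) - mean(PBS)
#' expression; returns the pairwise Pearson correlation matrix between
#' replicate vectors.
#'
#' @param x normalized compendium.
#' @param cellType,cytokine the contrast.
#' @param signature a \linkS4class{CytokineSignature} (its genes define the
#'   vectors), or a character vector of genes.
#' @return symmetric correlation matrix (0 x 0 with a warning when fewer
#'   than 2 replicates; NA entries with a warning when fewer than 2
#'   signature genes).
#' @export
replicateConcordance <- function(x, cellType, cytokine, signature) {
  genes <- if (is(signature, "CytokineSignature"))
    signature@entries$gene else signature
  it <- .cellsOf(x, cellType, cytokine)
  reps <- sort(unique(replicates(x)[it]))
  if (length(reps) < 2L) {
    warning("fewer than 2 replicates for ", cellType, "/", cytokine)
    return(matrix(numeric(0), 0, 0))
  }
  if (length(genes) < 2L) {
    warning("fewer than 2 signature genes; correlations undefined")
    out <- matrix(NA_real_, length(reps), length(reps),
                  dimnames = list(reps, reps))
    return(out)
  }
  m <- .expr(x)[genes, , drop = FALSE]
  ic <- .cellsOf(x, cellType, .PBS)
  vecs <- sapply(reps, function(r) {
    ti <- it[replicates(x)[it] == r]
    ci <- ic[replicates(x)[ic] == r]
    if (!length(ci)) ci <- ic
    Matrix::rowMeans(m[, ti, drop = FALSE]) -
      Matrix::rowMeans(m[, ci, drop = FALSE])
  })
  cor(vecs)
}

#' Per-cell gene-set score
#'
#' Sum of normalized expression over the set genes in each cell; genes
#' absent from the matrix contribute zero (with a warning).
#'
#' @param x normalized compendium.
#' @param geneSet character vector of genes (non-empty).
#' @return named numeric vector, one score per cell.
#' @export
geneSetScore <- function(x, geneSet) {
  if (!length(geneSet)) stop("empty gene set")
  present <- intersect(geneSet, rownames(x))
  absent <- setdiff(geneSet, present)
  if (length(absent))
    warning(length(absent), " set gene(s) absent from the matrix: ",
            paste(head(absent, 5), collapse = ", "))
  if (!length(present))
    return(stats::setNames(rep(0, ncol(x)), colnames(x)))
  stats::setNames(Matrix::colSums(.expr(x)[present, , drop = FALSE]),
                  colnames(x))
}

#' AUC for separating treated from control cells by score
#'
#' \eqn{P(treated > control) + P(tie)/2} by pair counting (see
#' \code{\link{pairAuc}}); used to verify that a stimulus reached a cell
#' population, e.g. with an interferon-stimulated-gene score.
#'
#' @param scoresTreated,scoresControl per-cell scores.
#' @return AUC in \[0, 1\].
#' @export
accessAuc <- function(scoresTreated, scoresControl) {
  if (!length(scoresTreated) || !length(scoresControl))
    stop("both score vectors must be non-empty")
  pairAuc(scoresTreated, scoresControl)
}

#' Secondary-response scoring against a donor cytokine's strict signature
#'
#' Builds, per cell type, the strict upregulated signature of
#' \code{donorCytokine} (FDR < \code{fdrMax} and log2FC >
#' \code{minLog2Fc}), scores every cell by the de-logged sum of expression
#' over those genes, and reports for each other cytokine treatment the
#' log2 fold change of the mean score versus PBS with a rank-sum FDR. A
#' cell type whose strict signature is empty yields NA rows.
#'
#' @param x normalized compendium.
#' @param donorCytokine the signature donor (e.g. an interferon).
#' @param fdrMax,minLog2Fc strict thresholds (defaults 0.001 and 1).
#' @return data.frame with columns \code{cell_type}, \code{cytokine},
#'   \code{score_log2fc}, \code{p}, \code{fdr}, \code{n_signature_genes}.
#' @export
secondaryResponseScore <- function(x, donorCytokine, fdrMax = 0.001,
                                   minLog2Fc = 1) {
  out <- list()
  for (ct in unique(cellTypes(x))) {
    de <- tryCatch(differentialExpression(x, ct, donorCytokine),
                   error = function(e) NULL)
    sig <- if (is.null(de)) character() else
      de$gene[de$fdr < fdrMax & de$log2fc > minLog2Fc]
    cyts <- setdiff(cytokineConditions(x), donorCytokine)
    if (!length(sig)) {
      out[[ct]] <- data.frame(cell_type = ct, cytokine = cyts,
                              score_log2fc = NA_real_, p = NA_real_,
                              fdr = NA_real_, n_signature_genes = 0L,
                              stringsAsFactors = FALSE)
      next
    }
    m <- .expr(x)[sig, , drop = FALSE]
    score <- Matrix::colSums(expm1(m))  # de-logged so doubling means FC 2
    ic <- .cellsOf(x, ct, .PBS)
    rows <- lapply(cyts, function(cyt) {
      it <- .cellsOf(x, ct, cyt)
      if (length(it) < 2L || length(ic) < 2L)
        return(data.frame(cell_type = ct, cytokine = cyt,
                          score_log2fc = NA_real_, p = NA_real_,
                          fdr = NA_real_,
                          n_signature_genes = length(sig),
                          stringsAsFactors = FALSE))
      rs <- rankSumTest(score[it], score[ic])
      data.frame(cell_type = ct, cytokine = cyt,
                 score_log2fc = log2((mean(score[it]) + 1) /
                                     (mean(score[ic]) + 1)),
                 p = rs$p, fdr = NA_real_,
                 n_signature_genes = length(sig),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- p.adjust(tab$p, method = "BH")
    out[[ct]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a signature table as TSV
#'
#' Columns: gene, log2fc, fdr, pct_treated, pct_control, direction,
#' cell_type, cytokine.
#'
#' @param signatures list of \linkS4class{CytokineSignature}.
#' @param path output path.
#' @export
writeSignatures <- function(signatures, path) {
  rows <- lapply(signatures, function(s) {
    if (!nrow(s@entries)) return(NULL)
    cbind(s@entries[, c("gene", "log2fc", "fdr", "pct_treated",
                        "pct_control", "direction")],
          cell_type = s@cellType, cytokine = s@cytokine)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
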