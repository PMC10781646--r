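# Quality control, library-size normalization and gene exclusion policies.

#' QC thresholds for cell filtering
#'
#' Defaults follow the standard droplet scRNA-seq gates: more than 500
#' detected genes, more than 1,000 UMIs and less than 10% mitochondrial
#' content, all strict inequalities.
#'
#' @param minGenes minimum detected genes (exclusive).
#' @param minUmi minimum UMI total (exclusive).
#' @param maxMitoFrac maximum mitochondrial fraction (exclusive).
#' @return a list of thresholds.
#' @export
qcThresholds <- function(minGenes = 500, minUmi = 1000, maxMitoFrac = 0.10) {
  stopifnot(minGenes > 0, minUmi > 0,
            maxMitoFrac > 0, maxMitoFrac <= 1)
  list(minGenes = minGenes, minUmi = minUmi, maxMitoFrac = maxMitoFrac)
}

#' Filter cells on QC thresholds
#'
#' Retains exactly the cells with detected genes > \code{minGenes},
#' UMI total > \code{minUmi} and mitochondrial fraction < \code{maxMitoFrac}
#' (strict inequalities). Mitochondrial genes are recognized by prefix
#' (mouse dialect \code{"mt-"} by default).
#'
#' @param x a raw-count \linkS4class{CytokineCompendium}.
#' @param thresholds see \code{\link{qcThresholds}}.
#' @param mitoPrefix gene-symbol prefix identifying mitochondrial genes.
#' @return the filtered compendium.
#' @export
qcFilter <- function(x, thresholds = qcThresholds(), mitoPrefix = "mt-") {
  if (isNormalized(x))
    stop("qcFilter expects raw counts, not a normalized compendium")
  m <- .expr(x)
  nGenes <- Matrix::colSums(m > 0)
  nUmi <- Matrix::colSums(m)
  mito <- startsWith(rownames(x), mitoPrefix)
  mitoFrac <- if (any(mito))
    Matrix::colSums(m[mito, , drop = FALSE]) / pmax(nUmi, 1)
  else rep(0, ncol(x))
  passGenes <- nGenes > thresholds$minGenes
  passUmi <- nUmi > thresholds$minUmi
  passMito <- mitoFrac < thresholds$maxMitoFrac
  keep <- passGenes & passUmi & passMito
  if (!any(keep))
    stop("no cells pass QC (failed genes: ", sum(!passGenes),
         ", failed UMI: ", sum(!passUmi),
         ", failed mito: ", sum(!passMito), ")")
  .msg("qcFilter retained ", sum(keep), "/", ncol(x), " cells")
  x[, keep]
}

#' Library-size normalize and log-transform
#'
#' Scales each cell to a total of 10,000 counts and applies the natural
#' logarithm of (scaled value + 1). The result carries the
#' \code{normalized} flag so downstream stages can verify their input.
#'
#' @param x a raw-count \linkS4class{CytokineCompendium}.
#' @param scaleFactor per-cell target total (default 10,000).
#' @return a normalized compendium.
#' @export
normalizeLog <- function(x, scaleFactor = 1e4) {
  if (isNormalized(x)) return(x)
  m <- .expr(x)
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("all-zero cell(s): ",
         paste(head(colnames(x)[tot == 0], 5), collapse = ", "))
  norm <- m %*% Matrix::Diagonal(x = scaleFactor / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  CytokineCompendium(norm, cellTypes(x), cellConditions(x), replicates(x),
                     normalized = TRUE)
}

.fixtureGenes <- function(file) {
  readLines(system.file("extdata", file, package = "cytodict",
                        mustWork = TRUE))
}

#' Gene exclusion policy
#'
#' Controls which gene categories are removed before signature, programme
#' and polarization analyses. The dissociation-stress and cell-cycle lists
#' are packaged plain-text fixtures; "unlabelled" genes are matched by
#' configurable regular expressions (predicted-model and Riken-clone style
#' symbols by default); "overabundant" removes the top \code{overabundantQ}
#' fraction of genes by total counts (off by default).
#'
#' @param ribosomal,mitochondrial,unlabelled,dissociation,cellCycle,
#'   overabundant logical switches per category.
#' @param minCellsExpressed remove genes expressed in fewer than this many
#'   cells (0 disables; requires expression when active).
#' @param unlabelledPatterns regexes defining unlabelled symbols.
#' @param mitoPrefix mitochondrial symbol prefix.
#' @param overabundantQ top fraction of total counts deemed overabundant.
#' @return a policy list consumed by \code{\link{applyExclusions}}.
#' @export
exclusionPolicy <- function(ribosomal = TRUE, mitochondrial = TRUE,
                            unlabelled = TRUE, dissociation = FALSE,
                            cellCycle = FALSE, overabundant = FALSE,
                            minCellsExpressed = 10,
                            unlabelledPatterns = c("^Gm[0-9]+$", "Rik$"),
                            mitoPrefix = "mt-", overabundantQ = 0.001) {
  list(ribosomal = ribosomal, mitochondrial = mitochondrial,
       unlabelled = unlabelled, dissociation = dissociation,
       cellCycle = cellCycle, overabundant = overabundant,
       minCellsExpressed = minCellsExpressed,
       unlabelledPatterns = unlabelledPatterns,
       mitoPrefix = mitoPrefix, overabundantQ = overabundantQ)
}

# category membership used both for exclusion and for signature filtering
.excludedCategories <- function(genes, policy) {
  out <- list()
  if (policy$ribosomal)
    out$ribosomal <- genes[grepl("^Rp[sl]", genes)]
  if (policy$mitochondrial)
    out$mitochondrial <- genes[startsWith(genes, policy$mitoPrefix)]
  if (policy$unlabelled) {
    hit <- Reduce(`|`, lapply(policy$unlabelledPatterns, grepl, x = genes),
                  rep(FALSE, length(genes)))
    out$unlabelled <- genes[hit]
  }
  if (policy$dissociation)
    out$dissociation <- intersect(genes,
                                  .fixtureGenes("dissociation_genes.txt"))
  if (policy$cellCycle)
    out$cell_cycle <- intersect(genes, .fixtureGenes("cell_cycle_genes.txt"))
  out
}

#' Apply a gene exclusion policy
#'
#' @param genes gene symbols to filter.
#' @param policy from \code{\link{exclusionPolicy}}.
#' @param expr optional genes x cells matrix (rownames covering
#'   \code{genes}); required when \code{minCellsExpressed} or
#'   \code{overabundant} is active.
#' @return the retained gene symbols; removal counts are logged per
#'   category.
#' @export
applyExclusions <- function(genes, policy = exclusionPolicy(), expr = NULL) {
  if (!length(genes)) return(character())
  drop <- .excludedCategories(genes, policy)
  if (policy$overabundant) {
    if (is.null(expr)) stop("overabundant exclusion requires expr")
    tot <- Matrix::rowSums(expr[genes, , drop = FALSE])
    nTop <- max(1L, ceiling(policy$overabundantQ * length(genes)))
    drop$overabundant <- genes[order(tot, decreasing = TRUE)[seq_len(nTop)]]
  }
  if (policy$minCellsExpressed > 0) {
    if (is.null(expr)) stop("minCellsExpressed requires expr")
    nCells <- Matrix::rowSums(expr[genes, , drop = FALSE] > 0)
    drop$low_detection <- genes[nCells < policy$minCellsExpressed]
  }
  for (cat in names(drop))
    if (length(drop[[cat]]))
      .msg("excluding ", length(drop[[cat]]), " ", cat, " gene(s)")
  keep <- setdiff(genes, unlist(drop, use.names = FALSE))
  if (!length(keep)) warning("all genes excluded by policy")
  keep
}
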