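#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' CytokineCompendium: a perturbational single-cell expression compendium
#'
#' Extends \linkS4class{SingleCellExperiment}. Columns are cells, rows are
#' genes. The column data must carry \code{cell_type}, \code{condition}
#' (a cytokine name or the reserved control token \code{"PBS"}) and
#' \code{replicate}. A metadata flag \code{normalized} records whether the
#' single assay holds log1p library-size-normalized values (per-cell
#' de-logged totals of 10,000) rather than raw counts.
#'
#' @export
setClass("CytokineCompendium", contains = "SingleCellExperiment")

setValidity("CytokineCompendium", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("cell_type", "condition", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("missing cell metadata column(s): ",
                           paste(miss, collapse = ", ")))
  else {
    for (f in need)
      if (anyNA(cd[[f]]))
        msgs <- c(msgs, paste0("NA values in metadata column ", f))
  }
  rn <- rownames(object)
  if (is.null(rn)) msgs <- c(msgs, "gene symbols (rownames) are required")
  else if (anyDuplicated(rn)) msgs <- c(msgs, "duplicate gene symbols")
  if (isTRUE(S4Vectors::metadata(object)$normalized) && ncol(object) > 0) {
    tot <- Matrix::colSums(expm1(SummarizedExperiment::assay(object)))
    bad <- abs(tot - 1e4) > 1e-6 * 1e4
    if (any(bad))
      msgs <- c(msgs, paste0(sum(bad), " cell(s) violate the 10,000-unit ",
                             "normalized total (first: ",
                             colnames(object)[which(bad)[1L]], ")"))
  }
  if (length(msgs)) msgs else TRUE
})

#' CytokineCatalog: cytokines, their encoding genes and receptors
#'
#' One entry per cytokine: a unique name, a family label, one or more
#' ligand genes (more than one only for two-subunit heteromers, which carry
#' \code{multimeric = TRUE}), and zero or more receptor options, each a
#' complex of component genes that must all be expressed for the option to
#' count as expressed.
#'
#' @slot info data.frame with columns \code{name}, \code{family},
#'   \code{multimeric}.
#' @slot ligandGenes named list of character vectors.
#' @slot receptorOptions named list; each element a list of character
#'   vectors (receptor complexes).
#' @export
setClass("CytokineCatalog",
         representation(info = "data.frame",
                        ligandGenes = "list",
                        receptorOptions = "list"))

setValidity("CytokineCatalog", function(object) {
  msgs <- character()
  nm <- object@info$name
  if (anyDuplicated(nm)) msgs <- c(msgs, "cytokine names must be unique")
  if (!identical(names(object@ligandGenes), nm) ||
      !identical(names(object@receptorOptions), nm))
    msgs <- c(msgs, "ligandGenes/receptorOptions must be named by cytokine")
  if (any(lengths(object@ligandGenes) < 1))
    msgs <- c(msgs, "every cytokine needs at least one ligand gene")
  if (!identical(unname(object@info$multimeric),
                 unname(lengths(object@ligandGenes) > 1L)))
    msgs <- c(msgs, "multimeric flag must equal (number of ligand genes > 1)")
  for (i in seq_along(object@receptorOptions))
    if (any(lengths(object@receptorOptions[[i]]) == 0L))
      msgs <- c(msgs, paste0("empty receptor complex for ", nm[i]))
  if (length(msgs)) msgs else TRUE
})

#' GeneSetCollection: named gene sets with an optional universe
#'
#' @slot sets named list of non-empty character vectors.
#' @slot universe character vector (may be empty when no universe is set).
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msgs <- c(msgs, "set names must be present and unique")
    if (any(lengths(object@sets) == 0L))
      msgs <- c(msgs, "gene sets must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' CytokineSignature: filtered differential-expression signature
#'
#' The atomic entry of the dictionary: the genes surviving the full filter
#' cascade (FDR, fold change, expression fraction, replicate consistency,
#' category exclusions) for one (cell type, cytokine) pair.
#'
#' @slot cellType,cytokine character scalars.
#' @slot entries data.frame with columns \code{gene}, \code{log2fc},
#'   \code{p}, \code{fdr}, \code{pct_treated}, \code{pct_control},
#'   \code{n_replicates_passing}, \code{direction}.
#' @export
setClass("CytokineSignature",
         representation(cellType = "character", cytokine = "character",
                        entries = "data.frame"))

#' GenePrograms: a fitted set of non-negative gene programmes
#'
#' @slot loadings non-negative genes x k matrix of gene loadings.
#' @slot cellWeights non-negative k x cells matrix of per-cell weights.
#' @slot reconError relative Frobenius reconstruction error.
#' @slot seed seed used for the fit.
#' @export
setClass("GenePrograms",
         representation(loadings = "matrix", cellWeights = "matrix",
                        reconError = "numeric", seed = "integer"))

setValidity("GenePrograms", function(object) {
  msgs <- character()
  if (any(object@loadings < 0) || any(object@cellWeights < 0))
    msgs <- c(msgs, "factors must be non-negative")
  if (ncol(object@loadings) != nrow(object@cellWeights))
    msgs <- c(msgs, "loadings and cellWeights disagree on k")
  if (length(msgs)) msgs else TRUE
})

#' PolarizationState: a cytokine-enriched subcluster of one cell type
#'
#' @slot id state identifier ("<cell-type-abbrev>-<letters>"; empty until
#'   \code{\link{nameStates}} is applied).
#' @slot cellType character scalar.
#' @slot cells member cell IDs.
#' @slot drivers data.frame with columns \code{cytokine}, \code{k},
#'   \code{p}, \code{fdr}, sorted by fdr; only drivers at fdr < alpha.
#' @slot markers data.frame of marker statistics (may be empty until
#'   \code{\link{stateMarkers}} fills it).
#' @slot profile named numeric differential profile (state mean minus PBS
#'   mean per gene; may be empty).
#' @export
setClass("PolarizationState",
         representation(id = "character", cellType = "character",
                        cells = "character", drivers = "data.frame",
                        markers = "data.frame", profile = "numeric"))

setMethod("show", "CytokineCompendium", function(object) {
  cat("CytokineCompendium:", nrow(object), "genes x", ncol(object), "cells\n")
  cat("  normalized:", isTRUE(S4Vectors::metadata(object)$normalized), "\n")
  cat("  cell types:", paste(head(unique(object$cell_type), 8),
                             collapse = ", "), "\n")
  nc <- length(setdiff(unique(object$condition), .PBS))
  cat("  conditions:", nc, "cytokine(s) +",
      sum(unique(object$condition) == .PBS), "control\n")
})

setMethod("show", "CytokineCatalog", function(object) {
  cat("CytokineCatalog with", nrow(object@info), "cytokines in",
      length(unique(object@info$family)), "families\n")
  cat("  multimeric:",
      paste(object@info$name[object@info$multimeric], collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets")
  if (length(object@universe)) cat(";", length(object@universe),
                                   "universe genes")
  cat("\n")
})

setMethod("show", "CytokineSignature", function(object) {
  cat("CytokineSignature", paste0(object@cellType, " / ", object@cytokine),
      "with", nrow(object@entries), "genes (",
      sum(object@entries$direction == "up"), "up /",
      sum(object@entries$direction == "down"), "down )\n")
})

setMethod("show", "GenePrograms", function(object) {
  cat("GenePrograms:", ncol(object@loadings), "programmes over",
      nrow(object@loadings), "genes and", ncol(object@cellWeights),
      "cells; relative reconstruction error",
      signif(object@reconError, 4), "\n")
})

setMethod("show", "PolarizationState", function(object) {
  cat("PolarizationState", if (nzchar(object@id)) object@id else "<unnamed>",
      "(", object@cellType, "):", length(object@cells), "cells; top driver",
      if (nrow(object@drivers)) object@drivers$cytokine[1L] else "none", "\n")
})
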