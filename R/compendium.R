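# Compendium construction, accessors and Matrix Market I/O.

#' Construct a CytokineCompendium
#'
#' @param counts genes x cells matrix (dense or sparse); rownames are gene
#'   symbols, colnames cell IDs.
#' @param cellType,condition,replicate per-cell metadata vectors.
#' @param normalized set \code{TRUE} when \code{counts} already holds log1p
#'   10,000-unit normalized values.
#' @param controlAliases condition labels remapped onto the reserved control
#'   token \code{"PBS"}.
#' @return a \linkS4class{CytokineCompendium}.
#' @export
CytokineCompendium <- function(counts, cellType, condition, replicate,
                               normalized = FALSE,
                               controlAliases = c("pbs", "control",
                                                  "vehicle")) {
  counts <- as(as(counts, "CsparseMatrix"), "dgCMatrix")
  if (is.null(rownames(counts)))
    stop("counts must carry gene symbols as rownames")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  condition <- as.character(condition)
  condition[condition %in% controlAliases] <- .PBS
  if (!.PBS %in% condition)
    warning("condition vocabulary does not contain the control token '",
            .PBS, "'")
  assayName <- if (normalized) "logcounts" else "counts"
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = stats::setNames(list(counts), assayName),
    colData = S4Vectors::DataFrame(cell_type = as.character(cellType),
                                   condition = condition,
                                   replicate = as.character(replicate),
                                   row.names = colnames(counts)))
  S4Vectors::metadata(sce)$normalized <- isTRUE(normalized)
  new("CytokineCompendium", sce)
}

#' @rdname CytokineCompendium
#' @param x a CytokineCompendium.
#' @export
cellTypes <- function(x) as.character(x$cell_type)

#' @rdname CytokineCompendium
#' @export
cellConditions <- function(x) as.character(x$condition)

#' @rdname CytokineCompendium
#' @export
replicates <- function(x) as.character(x$replicate)

#' @rdname CytokineCompendium
#' @export
isNormalized <- function(x) isTRUE(S4Vectors::metadata(x)$normalized)

#' @rdname CytokineCompendium
#' @export
cytokineConditions <- function(x) setdiff(unique(cellConditions(x)), .PBS)

# expression matrix of the single assay, regardless of its name
.expr <- function(x) SummarizedExperiment::assay(x, 1L)

# column indices for a (cell type, condition) group
.cellsOf <- function(x, cellType = NULL, condition = NULL) {
  keep <- rep(TRUE, ncol(x))
  if (!is.null(cellType)) keep <- keep & cellTypes(x) == cellType
  if (!is.null(condition)) keep <- keep & cellConditions(x) == condition
  which(keep)
}

#' Read a compendium from a Matrix Market bundle
#'
#' Expects a Matrix Market matrix (genes x cells), one gene symbol per line
#' in \code{genesPath}, one cell ID per line in \code{cellsPath}, and a
#' tab-separated metadata table keyed by cell ID with columns
#' \code{cell_type}, \code{condition}, \code{replicate}. Metadata rows are
#' aligned to the matrix column order; a cell without metadata is an error.
#'
#' @param matrixPath,genesPath,cellsPath,metaPath file paths.
#' @param normalized whether the matrix holds normalized log values.
#' @return a \linkS4class{CytokineCompendium}.
#' @export
readCompendium <- function(matrixPath, genesPath, cellsPath, metaPath,
                           normalized = FALSE) {
  m <- as(Matrix::readMM(matrixPath), "CsparseMatrix")
  genes <- readLines(genesPath)
  cells <- readLines(cellsPath)
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match gene/cell files (", length(genes), " x ",
         length(cells), ")")
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  dimnames(m) <- list(genes, cells)
  meta <- read.table(metaPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  idcol <- intersect(c("cell", "cell_id", "barcode"), colnames(meta))
  if (!length(idcol)) stop("metadata needs a cell/cell_id/barcode column")
  rownames(meta) <- meta[[idcol[1L]]]
  missing <- setdiff(cells, rownames(meta))
  if (length(missing))
    stop("metadata missing for cell(s): ",
         paste(head(missing, 5), collapse = ", "))
  meta <- meta[cells, , drop = FALSE]
  CytokineCompendium(m, meta$cell_type, meta$condition, meta$replicate,
                     normalized = normalized)
}

#' Write a compendium as a Matrix Market bundle
#'
#' Inverse of \code{\link{readCompendium}}: writes \code{matrix.mtx},
#' \code{genes.tsv}, \code{barcodes.tsv} and \code{metadata.tsv} into
#' \code{dir}.
#'
#' @param x a CytokineCompendium.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
writeCompendium <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(.expr(x), file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  meta <- data.frame(cell = colnames(x), cell_type = cellTypes(x),
                     condition = cellConditions(x), replicate = replicates(x))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname CytokineSignature
#' @param x a CytokineSignature.
#' @export
signatureGenes <- function(x, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  e <- x@entries
  if (direction != "both") e <- e[e$direction == direction, , drop = FALSE]
  e$gene
}

#' Accessors for CytokineSignature
#'
#' @name CytokineSignature
#' @param x a CytokineSignature.
#' @param direction restrict to up- or downregulated entries.
#' @export
signatureTable <- function(x) x@entries

#' @rdname GenePrograms
#' @param x a GenePrograms object.
#' @export
programLoadings <- function(x) x@loadings

#' Accessors for GenePrograms
#'
#' @name GenePrograms
#' @param x a GenePrograms object.
#' @export
programCellWeights <- function(x) x@cellWeights
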