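# Cytokine catalog: names, families, ligand genes, receptor complexes.
# TSV dialect: ligand_genes joins subunits with "+"; receptor_options joins
# complex components with "+" and alternative complexes with ";".

#' Construct a CytokineCatalog
#'
#' @param name,family character vectors, one entry per cytokine.
#' @param ligandGenes list of character vectors (subunit genes).
#' @param receptorOptions list of lists of character vectors (each inner
#'   vector one receptor complex).
#' @return a \linkS4class{CytokineCatalog}.
#' @export
CytokineCatalog <- function(name, family, ligandGenes, receptorOptions) {
  names(ligandGenes) <- name
  names(receptorOptions) <- name
  new("CytokineCatalog",
      info = data.frame(name = name, family = family,
                        multimeric = lengths(ligandGenes) > 1L,
                        stringsAsFactors = FALSE),
      ligandGenes = ligandGenes,
      receptorOptions = receptorOptions)
}

#' @rdname CytokineCatalog
#' @param x a CytokineCatalog.
#' @export
cytokineNames <- function(x) x@info$name

#' @rdname CytokineCatalog
#' @export
cytokineFamilies <- function(x) stats::setNames(x@info$family, x@info$name)

#' @rdname CytokineCatalog
#' @param cytokine optional cytokine name to subset to.
#' @export
ligandGenes <- function(x, cytokine = NULL) {
  if (is.null(cytokine)) return(x@ligandGenes)
  .checkCatalogName(x, cytokine)
  x@ligandGenes[[cytokine]]
}

#' @rdname CytokineCatalog
#' @export
receptorOptions <- function(x, cytokine = NULL) {
  if (is.null(cytokine)) return(x@receptorOptions)
  .checkCatalogName(x, cytokine)
  x@receptorOptions[[cytokine]]
}

#' @rdname CytokineCatalog
#' @export
isMultimeric <- function(x, cytokine = NULL) {
  out <- stats::setNames(x@info$multimeric, x@info$name)
  if (is.null(cytokine)) return(out)
  .checkCatalogName(x, cytokine)
  out[[cytokine]]
}

.checkCatalogName <- function(x, cytokine) {
  if (!cytokine %in% x@info$name)
    stop("unknown cytokine: ", cytokine)
}

.parseReceptorField <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  opts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  lapply(opts, function(o) {
    comp <- strsplit(o, "+", fixed = TRUE)[[1L]]
    comp <- comp[nzchar(comp)]
    if (!length(comp))
      stop("receptor complex referencing no genes: '", s, "'")
    comp
  })
}

#' Load a cytokine catalog from TSV or JSON
#'
#' TSV columns: \code{name}, \code{family}, \code{ligand_genes} (subunits
#' joined by \code{+}), \code{receptor_options} (complex components joined
#' by \code{+}, alternative complexes by \code{;}). JSON: an array of
#' objects with the same fields (\code{ligand_genes} an array,
#' \code{receptor_options} an array of arrays).
#'
#' @param path file path; format inferred from the extension.
#' @return a \linkS4class{CytokineCatalog}.
#' @export
loadCatalog <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!length(js)) {
      warning("empty catalog file: ", path)
      return(CytokineCatalog(character(), character(), list(), list()))
    }
    return(CytokineCatalog(
      name = vapply(js, `[[`, "", "name"),
      family = vapply(js, `[[`, "", "family"),
      ligandGenes = lapply(js, function(e) unlist(e$ligand_genes)),
      receptorOptions = lapply(js, function(e)
        lapply(e$receptor_options, unlist))))
  }
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", quote = "", fill = TRUE,
               stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) {
    warning("empty catalog file: ", path)
    return(CytokineCatalog(character(), character(), list(), list()))
  }
  CytokineCatalog(
    name = tab$name, family = tab$family,
    ligandGenes = lapply(strsplit(tab$ligand_genes, "+", fixed = TRUE),
                         function(g) g[nzchar(g)]),
    receptorOptions = lapply(tab$receptor_options, .parseReceptorField))
}

#' Write a catalog in the TSV dialect read by \code{\link{loadCatalog}}
#'
#' @param x a CytokineCatalog.
#' @param path output path.
#' @export
writeCatalog <- function(x, path) {
  tab <- data.frame(
    name = x@info$name, family = x@info$family,
    ligand_genes = vapply(x@ligandGenes, paste, "", collapse = "+"),
    receptor_options = vapply(x@receptorOptions, function(o)
      paste(vapply(o, paste, "", collapse = "+"), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 86-cytokine catalog
#'
#' A curated catalog of the 86 cytokines covered by the reference design,
#' with mouse ligand gene symbols and best-known cognate receptor
#' complexes. The five two-subunit heteromers (IL-12, IL-23, IL-27,
#' LTa1b2, LTa2b1) are flagged multimeric. Receptor listings are a curated
#' convenience, not an exhaustive registry; supply your own catalog for
#' receptor-critical analyses.
#'
#' @return a \linkS4class{CytokineCatalog} with 86 entries.
#' @export
defaultCatalog <- function() {
  loadCatalog(system.file("extdata", "cytokine_catalog.tsv",
                          package = "cytodict", mustWork = TRUE))
}
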