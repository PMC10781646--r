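# Gene set collections and GMT I/O.

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors.
#' @param universe optional character vector of background genes.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, universe = character()) {
  new("GeneSetCollection", sets = sets, universe = universe)
}

#' @rdname GeneSetCollection
#' @param x a GeneSetCollection.
#' @export
geneSets <- function(x) x@sets

#' @rdname GeneSetCollection
#' @export
setUniverse <- function(x) x@universe

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name <tab> description <tab> gene ...}. Set order is preserved.
#'
#' @param path GMT file path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line with fewer than 3 fields: '",
           substr(ln, 1, 60), "'")
    nm <- f[1L]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    sets[[nm]] <- f[-(1:2)]
  }
  GeneSetCollection(sets)
}

#' Write gene sets as GMT
#'
#' @param x a GeneSetCollection.
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @export
writeGmt <- function(x, path, descriptions = NULL) {
  nm <- names(x@sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i)
    paste(c(nm[i], descriptions[i], x@sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
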