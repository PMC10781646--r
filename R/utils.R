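#' @importFrom methods new validObject is as setValidity slot
#' @importFrom stats p.adjust pnorm phyper quantile cor cor.test prcomp
#'   rnbinom rnorm rlnorm hclust dist as.dendrogram setNames
#' @importFrom utils read.table write.table head combn
NULL

# control-condition token; aliases are remapped onto this at construction
.PBS <- "PBS"

.msg <- function(...) message("[cytodict] ", ...)

#' Log2 fold change between two groups of log-normalized expression values
#'
#' Values are de-logged (\code{expm1}), averaged per group, and the ratio of
#' pseudocount-shifted means is returned on the log2 scale:
#' \code{log2((mean(expm1(x)) + pseudo) / (mean(expm1(y)) + pseudo))}.
#' This is the common single-cell convention for fold changes computed from
#' log1p-normalized data.
#'
#' @param x,y numeric vectors of log-normalized expression for the two groups.
#' @param pseudo pseudocount added to both de-logged means (default 1).
#' @return a single numeric log2 fold change.
#' @examples
#' log2FoldChange(log1p(c(3, 3)), log1p(c(1, 1)))  # log2(4/2) = 1
#' @export
log2FoldChange <- function(x, y, pseudo = 1) {
  log2((mean(expm1(x)) + pseudo) / (mean(expm1(y)) + pseudo))
}

# row-wise version on matrices (genes x cells), same convention
.rowLog2Fc <- function(mx, my, pseudo = 1) {
  mmx <- if (is.null(dim(mx))) expm1(mx) else Matrix::rowMeans(expm1(mx))
  mmy <- if (is.null(dim(my))) expm1(my) else Matrix::rowMeans(expm1(my))
  log2((mmx + pseudo) / (mmy + pseudo))
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.checkCharacter <- function(x, what) {
  if (!is.character(x) || anyNA(x))
    stop(what, " must be a character vector without NA", call. = FALSE)
  x
}
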