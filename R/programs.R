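# Non-negative gene programmes: NMF fit (Frobenius loss, multiplicative
# updates, deterministic NNDSVD-a initialization), programme significance,
# top-gene extraction and generic over-representation.

# NNDSVD initialization (variant "a": zeros backfilled with the matrix
# mean) -- deterministic, so fits are reproducible without relying on the
# random stream.
.nndsvd <- function(A, k) {
  sv <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      sig <- nup * nvp
      if (sig > 0) {
        W[, j] <- sqrt(sv$d[j] * sig) * up / nup
        H[j, ] <- sqrt(sv$d[j] * sig) * vp / nvp
      }
    } else {
      sig <- nun * nvn
      W[, j] <- sqrt(sv$d[j] * sig) * un / nun
      H[j, ] <- sqrt(sv$d[j] * sig) * vn / nvn
    }
  }
  avg <- mean(A)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

# Frobenius multiplicative updates; error is non-increasing by construction
.nmf <- function(A, k, maxIter = 200, tol = 1e-6) {
  eps <- .Machine$double.eps
  init <- .nndsvd(A, k)
  W <- init$W; H <- init$H
  nA <- sqrt(sum(A^2))
  errPrev <- Inf
  for (iter in seq_len(maxIter)) {
    H <- H * (crossprod(W, A) / (crossprod(W, W %*% H) + eps))
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (iter %% 10 == 0 || iter == maxIter) {
      err <- sqrt(sum((A - W %*% H)^2)) / max(nA, eps)
      if (is.finite(errPrev) && errPrev - err < tol) break
      errPrev <- err
    }
  }
  err <- sqrt(sum((A - W %*% H)^2)) / max(nA, eps)
  list(W = W, H = H, err = err)
}

#' Fit non-negative gene programmes
#'
#' Factorizes the normalized expression of the selected cells into
#' \code{k} non-negative programmes (genes x k loadings, k x cells
#' weights) using Frobenius-loss multiplicative updates from a
#' deterministic NNDSVD initialization. Genes are restricted by the
#' exclusion policy; at most \code{maxCellsPerGroup} cells per (cell type,
#' condition) are sampled (seeded).
#'
#' @param x normalized compendium (already subset to the conditions of
#'   interest, or use the wrappers below).
#' @param k number of programmes; must be smaller than both matrix
#'   dimensions after filtering.
#' @param seed sampling seed (recorded on the result).
#' @param policy gene exclusion policy; defaults to the programme-analysis
#'   policy (dissociation, cell cycle, mitochondrial, ribosomal,
#'   unlabelled and <10-cell genes removed).
#' @param maxCellsPerGroup per-(cell type, condition) sampling cap.
#' @param maxIter,tol optimizer controls.
#' @return a \linkS4class{GenePrograms} object.
#' @export
fitPrograms <- function(x, k, seed = 1,
                        policy = exclusionPolicy(dissociation = TRUE,
                                                 cellCycle = TRUE),
                        maxCellsPerGroup = 100, maxIter = 200,
                        tol = 1e-6) {
  m <- .expr(x)
  keep <- .withSeed(seed, {
    grp <- paste(cellTypes(x), cellConditions(x), sep = "\r")
    unlist(lapply(split(seq_len(ncol(x)), grp), function(idx)
      if (length(idx) > maxCellsPerGroup) sample(idx, maxCellsPerGroup)
      else idx), use.names = FALSE)
  })
  keep <- sort(keep)
  genes <- suppressMessages(
    applyExclusions(rownames(x), policy, m[, keep, drop = FALSE]))
  A <- as.matrix(m[genes, keep, drop = FALSE])
  A <- A[rowSums(A) > 0, , drop = FALSE]
  if (k >= min(dim(A)))
    stop("k = ", k, " must be smaller than min(genes, cells) = ",
         min(dim(A)))
  fit <- .nmf(A, k, maxIter = maxIter, tol = tol)
  # unit-norm loadings; the scale (expression units) lives in the weights
  nrm <- sqrt(colSums(fit$W^2))
  nrm[nrm == 0] <- 1
  fit$W <- sweep(fit$W, 2, nrm, `/`)
  fit$H <- fit$H * nrm
  dimnames(fit$W) <- list(rownames(A), paste0("GP", seq_len(k)))
  dimnames(fit$H) <- list(paste0("GP", seq_len(k)), colnames(A))
  .msg("fitted ", k, " programmes on ", nrow(A), " genes x ", ncol(A),
       " cells; relative error ", signif(fit$err, 4))
  new("GenePrograms", loadings = fit$W, cellWeights = fit$H,
      reconError = fit$err, seed = as.integer(seed))
}

#' @rdname fitPrograms
#' @param cytokines one or more cytokine conditions fitted jointly with
#'   PBS controls (related pairs, e.g. the two type I interferons or the
#'   two IL-1 forms, can be passed together).
#' @param ... forwarded to \code{fitPrograms}.
#' @export
fitCytokinePrograms <- function(x, cytokines, k = 40, ...) {
  sel <- cellConditions(x) %in% c(cytokines, .PBS)
  fitPrograms(x[, sel], k = k, ...)
}

#' @rdname fitPrograms
#' @param cellType single cell type fitted across all conditions.
#' @export
fitCellTypePrograms <- function(x, cellType, k = 10, ...) {
  sel <- cellTypes(x) == cellType
  fitPrograms(x[, sel], k = k, ...)
}

#' Programme significance per cell type
#'
#' Two-sided rank-sum test of per-cell programme weights, cytokine-treated
#' versus PBS, within each cell type; effect size is the difference in
#' mean weight (display value capped at 10, raw value retained). BH FDR is
#' applied across all (programme, cell type) tests. A programme counts as
#' upregulated when any cell type shows effect size > 1 at FDR < 0.01.
#'
#' @param gp a \linkS4class{GenePrograms} object.
#' @param conditionLabels,cellTypeLabels per-cell labels aligned with the
#'   fitted cells (e.g. from the compendium restricted to
#'   \code{colnames(programCellWeights(gp))}).
#' @param displayCap cap applied to the display effect size.
#' @return data.frame with columns \code{program}, \code{cell_type},
#'   \code{effect_size}, \code{effect_size_display}, \code{p}, \code{fdr},
#'   \code{significant} (FDR < 0.05), \code{upregulated}.
#' @export
programSignificance <- function(gp, conditionLabels, cellTypeLabels,
                                displayCap = 10) {
  H <- gp@cellWeights
  stopifnot(length(conditionLabels) == ncol(H),
            length(cellTypeLabels) == ncol(H))
  rows <- list()
  for (j in seq_len(nrow(H))) for (ct in unique(cellTypeLabels)) {
    sel <- cellTypeLabels == ct
    wt <- H[j, sel & conditionLabels != .PBS]
    wc <- H[j, sel & conditionLabels == .PBS]
    if (length(wt) < 2L || length(wc) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        program = rownames(H)[j], cell_type = ct, effect_size = NA_real_,
        p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    rs <- rankSumTest(wt, wc)
    rows[[length(rows) + 1L]] <- data.frame(
      program = rownames(H)[j], cell_type = ct,
      effect_size = mean(wt) - mean(wc), p = rs$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$effect_size_display <- pmin(out$effect_size, displayCap)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < 0.05
  upProg <- unique(out$program[!is.na(out$fdr) & out$fdr < 0.01 &
                               !is.na(out$effect_size) &
                               out$effect_size > 1])
  out$upregulated <- out$program %in% upProg
  rownames(out) <- NULL
  out
}

#' Top-weighted genes of a programme
#'
#' @param gp a \linkS4class{GenePrograms} object.
#' @param program programme index or name.
#' @param n number of genes (default 30); ties at the cutoff are broken
#'   lexicographically.
#' @return character vector of at most \code{n} genes by descending
#'   loading.
#' @export
topProgramGenes <- function(gp, program, n = 30) {
  w <- gp@loadings[, program]
  ord <- order(-w, names(w))
  names(w)[ord][seq_len(min(n, length(w)))]
}

#' Over-representation of a query gene list in gene sets
#'
#' Upper-tail hypergeometric test of the overlap between the query and
#' each set, within the stated universe; BH FDR across sets.
#'
#' @param queryGenes character vector; genes outside the universe are
#'   dropped with a warning.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe background genes (default: the collection's universe).
#' @return data.frame with columns \code{set}, \code{overlap},
#'   \code{set_size}, \code{p}, \code{fdr}, sorted by p.
#' @export
overRepresentation <- function(queryGenes, collection, universe = NULL) {
  if (is.null(universe)) universe <- collection@universe
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(queryGenes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    queryGenes <- intersect(queryGenes, universe)
  }
  N <- length(universe); q <- length(queryGenes)
  rows <- lapply(names(collection@sets), function(nm) {
    s <- intersect(collection@sets[[nm]], universe)
    k <- length(intersect(queryGenes, s))
    data.frame(set = nm, overlap = k, set_size = length(s),
               p = hypergeometricTest(k, N, length(s), q),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
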